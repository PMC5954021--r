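RUN_CONDITIONS <- c("pngasef", "control")
PEAK_VARIANTS <- c("native", "deamidated", "reference")

validate_peak_table <- function(df, file = NULL) {
  need <- c("sample_id", "run_condition", "peptide", "variant", "site_id",
            "intensity")
  where <- if (is.null(file)) "peak table" else sprintf("'%s'", file)
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    abort_validation(sprintf(
      "%s must have columns %s", where, paste(need, collapse = ", ")
    ))
  }
  if (nrow(df) == 0L) abort_validation(sprintf("%s is empty", where))
  # +1 accounts for the header line when reporting file positions
  line <- function(i) if (is.null(file)) sprintf("row %d", i) else sprintf("line %d", i + 1L)
  bad <- which(!df$run_condition %in% RUN_CONDITIONS)
  if (length(bad)) {
    abort_validation(sprintf(
      "%s, %s: run_condition '%s' (expected pngasef/control)",
      where, line(bad[1]), df$run_condition[bad[1]]
    ))
  }
  bad <- which(!df$variant %in% PEAK_VARIANTS)
  if (length(bad)) {
    abort_validation(sprintf(
      "%s, %s: variant '%s' (expected native/deamidated/reference)",
      where, line(bad[1]), df$variant[bad[1]]
    ))
  }
  bad <- which(!is.finite(df$intensity) | df$intensity < 0)
  if (length(bad)) {
    abort_validation(sprintf(
      "%s, %s: intensity must be a non-negative number", where, line(bad[1])
    ))
  }
  invisible(df)
}

#' Read a peak-intensity table from CSV
#'
#' Expected columns: `sample_id`, `run_condition` (`pngasef`/`control`),
#' `peptide`, `variant` (`native`/`deamidated`/`reference`), `site_id`,
#' `intensity`. UTF-8 with a header row. Malformed rows are reported with
#' their file line number.
#'
#' @param path CSV file path.
#' @return Validated peak-table data frame.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("'%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_peak_table(df, file = path)
  df
}

#' Read a gene x sample expression matrix from TSV
#'
#' First column = gene id, remaining columns = samples, header row required.
#'
#' @param path TSV file path.
#' @param space `"raw"` (default) for non-negative expression values or
#'   `"log_ratio"` for pre-logged data.
#' @return Numeric matrix with gene rownames, sample colnames and a `space`
#'   attribute.
#' @export
read_expression_matrix <- function(path, space = c("raw", "log_ratio")) {
  space <- match.arg(space)
  if (!file.exists(path)) abort_validation(sprintf("'%s' does not exist", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) abort_validation(sprintf("'%s': need a gene column plus samples", path))
  genes <- trimws(as.character(df[[1]]))
  if (anyDuplicated(genes)) {
    abort_validation(sprintf("'%s': duplicate gene id '%s'",
                             path, genes[duplicated(genes)][1]))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort_validation(sprintf("'%s': non-numeric expression values", path))
  rownames(m) <- genes
  attr(m, "space") <- space
  if (space == "raw") validate_expression_matrix(m, space = "raw")
  m
}

#' Read an IHC score table from CSV
#'
#' Columns: `specimen_id`, `marker`, `percent_positive`, `intensity`.
#'
#' @param path CSV file path.
#' @return Data frame as read (range validation happens downstream so that
#'   out-of-range rows can be reported per row, not fatally).
#' @export
read_ihc_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("'%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "marker", "percent_positive", "intensity")
  if (!all(need %in% names(df))) {
    abort_validation(sprintf("'%s' must have columns %s", path,
                             paste(need, collapse = ", ")))
  }
  df
}

#' Read a tumor caliper-measurement table from CSV
#'
#' Columns: `animal_id`, `day`, `l_mm`, `w_mm`.
#'
#' @param path CSV file path.
#' @return Data frame as read.
#' @export
read_tumor_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("'%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "day", "l_mm", "w_mm")
  if (!all(need %in% names(df))) {
    abort_validation(sprintf("'%s' must have columns %s", path,
                             paste(need, collapse = ", ")))
  }
  df
}

#' Read peptide-ion definitions from TSV
#'
#' Columns: `site_id` (empty/NA for reference peptides), `sequence` (observed
#' sequence: deamidated rows carry D at the converted position), `charge`,
#' `variant`. The theoretical m/z is computed from the monoisotopic mass.
#'
#' @param path TSV file path.
#' @return Ion definition data frame with an added `mz` column, as consumed
#'   by [xic_quantify()].
#' @export
read_peptide_defs <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("'%s' does not exist", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "sequence", "charge", "variant")
  if (!all(need %in% names(df))) {
    abort_validation(sprintf("'%s' must have columns %s", path,
                             paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(df$variant), PEAK_VARIANTS)
  if (length(bad)) abort_validation(sprintf("unknown variant '%s'", bad[1]))
  df$mz <- vapply(seq_len(nrow(df)), function(i) {
    ion_mz(monoisotopic_mass(df$sequence[i]), df$charge[i])
  }, numeric(1))
  data.frame(
    peptide = df$sequence, variant = df$variant, charge = df$charge,
    mz = df$mz, site_id = ifelse(nzchar(df$site_id %||% ""), df$site_id, NA),
    stringsAsFactors = FALSE
  )
}

#' Read centroided spectra from an mzML file
#'
#' Loads MS1 scans through the `mzR` package into the in-memory
#' [spectrum_set()] container (retention times converted to minutes).
#'
#' @param path mzML file path.
#' @return A [spectrum_set()].
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort_validation("reading mzML requires the 'mzR' package")
  }
  if (!file.exists(path)) abort_validation(sprintf("'%s' does not exist", path))
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  ms1 <- which(hdr$msLevel == 1)
  scans <- lapply(ms1, function(i) {
    pk <- mzR::peaks(h, i)
    list(rt = hdr$retentionTime[i] / 60, mz = pk[, 1], intensity = pk[, 2])
  })
  spectrum_set(scans)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

#' Write an occupancy result table as TSV
#'
#' Percentages are printed at 1 decimal, intensities at 6 significant digits.
#'
#' @param occ Result of [occupancy_from_peak_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(occ, path) {
  out <- data.frame(
    site_id = occ$site_id, sample_id = occ$sample_id,
    IN = formatC(occ$IN, format = "g", digits = 6),
    INF = formatC(occ$INF, format = "g", digits = 6),
    IND = formatC(occ$IND, format = "g", digits = 6),
    raw_percent = fmt_num(occ$raw_percent, 1),
    occupancy_percent = fmt_num(occ$occupancy_percent, 1),
    flags = occ$flags,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run log
#'
#' Every pipeline run emits a log naming its inputs, parameters and outputs,
#' plus the package version and a hash of the physical-constants table, so
#' the run can be re-executed byte-identically.
#'
#' @param path Output JSON path.
#' @param subcommand Pipeline stage name.
#' @param inputs,params,outputs Named lists echoed into the log.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, subcommand, inputs = list(), params = list(),
                          outputs = list()) {
  log <- list(
    tool = "glycoEMT",
    version = as.character(utils::packageVersion("glycoEMT")),
    subcommand = subcommand,
    constants_hash = constants_hash(),
    inputs = inputs,
    params = params,
    outputs = outputs
  )
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
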