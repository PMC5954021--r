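#' Run the occupancy stage end-to-end
#'
#' Reads a peak-intensity CSV (or mzML spectra plus peptide definitions),
#' normalizes to the reference peptides, computes per-site occupancy, and
#' writes a TSV plus a JSON run log. Identical inputs and configuration give
#' byte-identical outputs.
#'
#' @param peak_table_file Peak-table CSV (see [read_peak_table()]); mutually
#'   exclusive with `mzml_files`.
#' @param mzml_files Named character vector of mzML paths keyed
#'   `"<sample_id>.<run_condition>"`; requires `peptide_file`.
#' @param peptide_file Peptide-definition TSV (see [read_peptide_defs()]).
#' @param output Output TSV path.
#' @param log_json Run-log JSON path; default `<output>.log.json`.
#' @param ppm XIC tolerance in ppm (default 10; only used for mzML input).
#' @param baseline_sample Normalization baseline; default first sample.
#' @param reference_sequences Reference peptide sequences.
#' @return Invisibly, a list with `status` (0), `occupancy` (the result data
#'   frame) and `outputs` (paths written). Validation problems raise a
#'   classed `glycoEMT_validation_error`; the CLI maps these to exit code 2.
#' @export
run_occupancy <- function(peak_table_file = NULL, mzml_files = NULL,
                          peptide_file = NULL, output, log_json = NULL,
                          ppm = 10, baseline_sample = NULL,
                          reference_sequences = REFERENCE_PEPTIDES$sequence) {
  log_json <- log_json %||% paste0(output, ".log.json")
  if (!is.null(peak_table_file)) {
    peaks <- read_peak_table(peak_table_file)
    input_desc <- list(peak_table = peak_table_file)
  } else if (!is.null(mzml_files)) {
    if (is.null(peptide_file)) {
      abort_validation("mzML input requires a peptide-definition file")
    }
    ions <- read_peptide_defs(peptide_file)
    spectra <- lapply(mzml_files, read_mzml)
    names(spectra) <- names(mzml_files)
    peaks <- xic_quantify(spectra, ions, ppm_tol = ppm)
    input_desc <- list(mzml = as.list(mzml_files), peptides = peptide_file)
  } else {
    abort_validation("provide either a peak table or mzML files")
  }
  occ <- occupancy_from_peak_table(
    peaks, reference_sequences = reference_sequences,
    baseline_sample = baseline_sample
  )
  write_occupancy_tsv(occ, output)
  write_run_log(
    log_json, "occupancy",
    inputs = input_desc,
    params = list(
      ppm = ppm,
      baseline_sample = baseline_sample %||% unique(peaks$sample_id)[1],
      reference_sequences = reference_sequences
    ),
    outputs = list(occupancy_tsv = output)
  )
  invisible(list(status = 0L, occupancy = occ,
                 outputs = c(output, log_json)))
}

#' Run the EMT scoring stage end-to-end
#'
#' Reads an expression TSV and a two-arm signature, log-ratio transforms raw
#' matrices, scores every sample, optionally correlates chosen genes with the
#' score and emits the heat-map color matrix, and writes TSVs plus a JSON run
#' log.
#'
#' @param matrix_file Expression TSV (first column gene id).
#' @param signature_file Signature TSV; `NULL` uses the packaged fixture
#'   ([default_emt_signature()]).
#' @param output_prefix Paths are `<prefix>_scores.tsv`,
#'   `<prefix>_correlations.tsv`, `<prefix>_colors.tsv`, `<prefix>.log.json`.
#' @param space `"raw"` (log-ratio transform applied) or `"log_ratio"`.
#' @param pseudocount Pseudocount for the log transform.
#' @param center Gene centering, `"median"` or `"mean"`.
#' @param correlate_genes Genes to correlate with the per-sample score.
#' @param write_colors Also write hex colors of each log ratio and score.
#' @param vmax_expression,vmax_score Color saturation points.
#' @return Invisibly, list with `status`, `scores`, `correlations`, `outputs`.
#' @export
run_emt <- function(matrix_file, signature_file = NULL, output_prefix,
                    space = c("raw", "log_ratio"), pseudocount = 1,
                    center = c("median", "mean"),
                    correlate_genes = character(), write_colors = FALSE,
                    vmax_expression = 3, vmax_score = 1) {
  space <- match.arg(space)
  center <- match.arg(center)
  mat <- read_expression_matrix(matrix_file, space = space)
  signature <- if (is.null(signature_file)) {
    default_emt_signature()
  } else {
    read_emt_signature(signature_file)
  }
  lr <- if (space == "raw") {
    log_ratio_transform(mat, pseudocount = pseudocount, center = center)
  } else mat
  missing_genes <- character()
  scores <- withCallingHandlers(
    emt_score(lr, signature),
    warning = function(w) {
      missing_genes <<- c(missing_genes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  cov <- attr(scores, "coverage")
  out_scores <- paste0(output_prefix, "_scores.tsv")
  write_tsv(data.frame(
    sample_id = scores$sample_id,
    emt_score = fmt_num(scores$emt_score, 4),
    coverage_mes = fmt_num(cov[["mesenchymal"]], 3),
    coverage_epi = fmt_num(cov[["epithelial"]], 3)
  ), out_scores)
  outputs <- list(scores_tsv = out_scores)
  correlations <- NULL
  if (length(correlate_genes)) {
    correlations <- correlate_with_score(lr, scores, correlate_genes)
    out_corr <- paste0(output_prefix, "_correlations.tsv")
    write_tsv(data.frame(
      gene = correlations$gene,
      r = fmt_num(correlations$r, 4),
      p = ifelse(is.na(correlations$p), "NA",
                 formatC(correlations$p, format = "g", digits = 4)),
      n = correlations$n
    ), out_corr)
    outputs$correlations_tsv <- out_corr
  }
  if (write_colors) {
    sc_cols <- heatmap_colors(scores$emt_score, "emt_score", vmax_score)
    out_colors <- paste0(output_prefix, "_colors.tsv")
    write_tsv(data.frame(
      sample_id = scores$sample_id,
      emt_score_hex = attr(sc_cols, "hex")
    ), out_colors)
    outputs$colors_tsv <- out_colors
  }
  log_json <- paste0(output_prefix, ".log.json")
  write_run_log(
    log_json, "emt",
    inputs = list(matrix = matrix_file,
                  signature = signature_file %||% "packaged fixture"),
    params = list(space = space, pseudocount = pseudocount, center = center,
                  correlate_genes = as.list(correlate_genes),
                  vmax_expression = vmax_expression, vmax_score = vmax_score,
                  warnings = as.list(missing_genes)),
    outputs = outputs
  )
  invisible(list(status = 0L, scores = scores, correlations = correlations,
                 outputs = c(unlist(outputs), log_json)))
}

#' Run the derived-metrics stage end-to-end
#'
#' Appends derived columns (IHC score, tumor volume) to the input tables,
#' reporting out-of-range rows as per-row error records rather than failing,
#' unless `strict = TRUE`.
#'
#' @param ihc_file IHC CSV (`specimen_id`, `marker`, `percent_positive`,
#'   `intensity`); optional.
#' @param tumor_file Tumor CSV (`animal_id`, `day`, `l_mm`, `w_mm`); optional.
#' @param output_prefix Paths are `<prefix>_ihc.tsv`, `<prefix>_tumor.tsv`,
#'   `<prefix>.log.json`.
#' @param strict Raise a validation error on any out-of-range row instead of
#'   flagging and excluding it.
#' @return Invisibly, list with `status`, `ihc`, `tumor`, `errors`, `outputs`.
#' @export
run_metrics <- function(ihc_file = NULL, tumor_file = NULL, output_prefix,
                        strict = FALSE) {
  if (is.null(ihc_file) && is.null(tumor_file)) {
    abort_validation("provide at least one of an IHC or a tumor table")
  }
  errors <- character()
  outputs <- list()
  ihc <- tumor <- NULL
  if (!is.null(ihc_file)) {
    ihc <- read_ihc_table(ihc_file)
    ok <- is.finite(ihc$percent_positive) & ihc$percent_positive >= 0 &
      ihc$percent_positive <= 100 & is.finite(ihc$intensity) &
      ihc$intensity %in% 0:3
    errors <- c(errors, sprintf(
      "ihc row %d: out-of-range percent_positive/intensity", which(!ok)
    ))
    ihc$score <- NA_real_
    ihc$score[ok] <- ihc_score(ihc$percent_positive[ok], ihc$intensity[ok])
    ihc$excluded <- !ok
    out_ihc <- paste0(output_prefix, "_ihc.tsv")
    write_tsv(ihc, out_ihc)
    outputs$ihc_tsv <- out_ihc
  }
  if (!is.null(tumor_file)) {
    tumor <- read_tumor_table(tumor_file)
    ok <- is.finite(tumor$l_mm) & is.finite(tumor$w_mm) &
      tumor$l_mm > 0 & tumor$w_mm > 0
    errors <- c(errors, sprintf("tumor row %d: non-positive diameter", which(!ok)))
    tumor$volume_mm3 <- NA_real_
    if (any(ok)) {
      tumor$volume_mm3[ok] <- suppressWarnings(
        tumor_volume(tumor$l_mm[ok], tumor$w_mm[ok])
      )
    }
    tumor$excluded <- !ok
    out_tumor <- paste0(output_prefix, "_tumor.tsv")
    write_tsv(tumor, out_tumor)
    outputs$tumor_tsv <- out_tumor
  }
  if (strict && length(errors)) {
    abort_validation(paste(errors, collapse = "; "))
  }
  log_json <- paste0(output_prefix, ".log.json")
  write_run_log(
    log_json, "metrics",
    inputs = list(ihc = ihc_file, tumor = tumor_file),
    params = list(strict = strict),
    outputs = c(outputs, list(row_errors = as.list(errors)))
  )
  invisible(list(status = 0L, ihc = ihc, tumor = tumor, errors = errors,
                 outputs = c(unlist(outputs), log_json)))
}
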