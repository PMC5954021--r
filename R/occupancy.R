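#' Normalize peak intensities to reference peptides
#'
#' Equalizes protein amount across samples using non-glycosylated reference
#' peptides. For each sample `s` the scale factor is
#' `f(s) = mean(reference intensities in baseline) / mean(reference intensities in s)`,
#' and every measurement of `s` (both run conditions) is multiplied by `f(s)`,
#' so the baseline sample is left unchanged.
#'
#' @param measurements Peak table data frame with columns `sample_id`,
#'   `run_condition` (`"pngasef"` or `"control"`), `peptide`, `variant`
#'   (`"native"`, `"deamidated"`, `"reference"`), `site_id`, `intensity`.
#' @param reference_sequences Character vector of reference peptide sequences;
#'   defaults to the two PD-L1 normalization peptides.
#' @param baseline_sample Sample id used as the normalization baseline;
#'   defaults to the first sample in input order.
#' @return `measurements` with a `normalized_intensity` column added.
#' @export
normalize_to_reference <- function(measurements,
                                   reference_sequences = REFERENCE_PEPTIDES$sequence,
                                   baseline_sample = NULL) {
  validate_peak_table(measurements)
  samples <- unique(measurements$sample_id)
  baseline_sample <- baseline_sample %||% samples[1]
  if (!baseline_sample %in% samples) {
    abort_invalid(sprintf("baseline sample '%s' not present", baseline_sample))
  }
  ref_mean <- vapply(samples, function(s) {
    rows <- measurements$sample_id == s & measurements$peptide %in% reference_sequences
    missing <- setdiff(reference_sequences, measurements$peptide[rows])
    if (length(missing)) {
      abort_glyco(
        sprintf("sample '%s' lacks reference peptide '%s'", s, missing[1]),
        "glycoEMT_missing_reference"
      )
    }
    mean(measurements$intensity[rows])
  }, numeric(1))
  zero <- samples[ref_mean == 0]
  if (length(zero)) {
    abort_glyco(
      sprintf("sample '%s' has zero mean reference intensity", zero[1]),
      "glycoEMT_zero_reference"
    )
  }
  f <- ref_mean[[baseline_sample]] / ref_mean
  measurements$normalized_intensity <-
    measurements$intensity * f[measurements$sample_id]
  measurements
}

#' N-glycan site occupancy from normalized intensities
#'
#' Implements the deamidation-controlled occupancy estimator
#' `raw = (INF - IND) / (IN + INF) * 100`, where `IN` is the normalized
#' intensity of the native (NxT) peptide after PNGase F, `INF` that of the
#' deamidated (DxT) peptide after PNGase F, and `IND` that of the DxT peptide
#' from the control run without PNGase F (spontaneous deamidation). The raw
#' percentage is clamped to `[0, 100]`; clamping and degenerate inputs are
#' flagged, never silently dropped. 100% occupancy corresponds to `IN = 0`
#' with no spontaneous deamidation (`IND = 0`).
#'
#' @param IN,INF,IND Non-negative normalized intensities (vectors recycled to
#'   a common length).
#' @param low_signal_floor Absolute floor on `IN + INF` below which the
#'   `low_signal` flag is raised (default 0: never).
#' @return A data frame of class `occupancy_result` with columns `IN`, `INF`,
#'   `IND`, `raw_percent`, `occupancy_percent` and `flags` (comma-separated;
#'   possible flags `negative_raw`, `zero_denominator`, `low_signal`). When
#'   the denominator is zero both percentages are `NA`.
#' @examples
#' compute_site_occupancy(IN = 0, INF = 1, IND = 0) # 100%
#' @export
compute_site_occupancy <- function(IN, INF, IND, low_signal_floor = 0) {
  check_number(IN, "IN", lower = 0)
  check_number(INF, "INF", lower = 0)
  check_number(IND, "IND", lower = 0)
  check_number(low_signal_floor, "low_signal_floor", lower = 0)
  n <- max(length(IN), length(INF), length(IND))
  IN <- rep_len(IN, n); INF <- rep_len(INF, n); IND <- rep_len(IND, n)
  denom <- IN + INF
  raw <- ifelse(denom > 0, (INF - IND) / denom * 100, NA_real_)
  occ <- pmin(pmax(raw, 0), 100)
  flags <- character(n)
  add_flag <- function(flags, which, flag) {
    ifelse(which, ifelse(nzchar(flags), paste(flags, flag, sep = ","), flag), flags)
  }
  flags <- add_flag(flags, denom == 0, "zero_denominator")
  flags <- add_flag(flags, !is.na(raw) & raw < 0, "negative_raw")
  flags <- add_flag(flags, denom > 0 & denom < low_signal_floor, "low_signal")
  structure(
    data.frame(
      IN = IN, INF = INF, IND = IND,
      raw_percent = raw, occupancy_percent = occ, flags = flags,
      stringsAsFactors = FALSE
    ),
    class = c("occupancy_result", "data.frame")
  )
}

#' Site occupancy for every glycosite and sample of a peak table
#'
#' End-to-end assembly: normalizes the table to the reference peptides, pivots
#' the native/deamidated intensities of each glycosite into `IN` (native,
#' PNGase F run), `INF` (deamidated, PNGase F run) and `IND` (deamidated,
#' control run), and applies [compute_site_occupancy()]. A measurement absent
#' from the table contributes intensity 0. Duplicate rows for the same
#' ion/run are summed.
#'
#' @inheritParams normalize_to_reference
#' @param low_signal_floor Floor on `IN + INF` for the `low_signal` flag;
#'   `NULL` (default) uses 1e-6 of the baseline sample's mean reference
#'   intensity.
#' @return Data frame with columns `site_id`, `sample_id`, `IN`, `INF`, `IND`,
#'   `raw_percent`, `occupancy_percent`, `flags`.
#' @export
occupancy_from_peak_table <- function(measurements,
                                      reference_sequences = REFERENCE_PEPTIDES$sequence,
                                      baseline_sample = NULL,
                                      low_signal_floor = NULL) {
  norm <- normalize_to_reference(measurements, reference_sequences, baseline_sample)
  baseline_sample <- baseline_sample %||% unique(norm$sample_id)[1]
  if (is.null(low_signal_floor)) {
    base_rows <- norm$sample_id == baseline_sample &
      norm$peptide %in% reference_sequences
    low_signal_floor <- 1e-6 * mean(norm$intensity[base_rows])
  }
  sites <- norm[norm$variant %in% c("native", "deamidated"), , drop = FALSE]
  if (nrow(sites) == 0L) {
    abort_validation("peak table contains no glycosite (native/deamidated) rows")
  }
  grid <- unique(sites[, c("site_id", "sample_id")])
  grid <- grid[order(grid$site_id, grid$sample_id), , drop = FALSE]
  pick <- function(site, sample, variant, run) {
    rows <- sites$site_id == site & sites$sample_id == sample &
      sites$variant == variant & sites$run_condition == run
    if (!any(rows)) 0 else sum(sites$normalized_intensity[rows])
  }
  IN <- mapply(pick, grid$site_id, grid$sample_id, "native", "pngasef")
  INF <- mapply(pick, grid$site_id, grid$sample_id, "deamidated", "pngasef")
  IND <- mapply(pick, grid$site_id, grid$sample_id, "deamidated", "control")
  res <- compute_site_occupancy(IN, INF, IND, low_signal_floor = low_signal_floor)
  out <- cbind(grid, res, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
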