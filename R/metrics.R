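#' Quantitative immunohistochemistry score
#'
#' Score = percentage of immunopositive cells (0-100) x staining intensity
#' grade (0 negative, 1 low, 2 medium, 3 high), giving an arbitrary
#' quantitative score in `[0, 300]`.
#'
#' @param percent_positive Numeric in `[0, 100]` (vectorized).
#' @param intensity Integer grade in `{0, 1, 2, 3}` (vectorized).
#' @return Numeric score(s).
#' @examples
#' ihc_score(80, 2) # 160
#' @export
ihc_score <- function(percent_positive, intensity) {
  check_number(percent_positive, "percent_positive", lower = 0, upper = 100)
  if (!is.numeric(intensity) || anyNA(intensity) ||
      any(intensity != as.integer(intensity)) ||
      any(intensity < 0) || any(intensity > 3)) {
    abort_invalid("'intensity' must be an integer grade in {0, 1, 2, 3}")
  }
  percent_positive * intensity
}

#' Ellipsoid tumor volume from caliper diameters
#'
#' Volume = l x w^2 / 2 (mm^3), l the longest and w the shortest diameter.
#' If w > l the arguments are swapped with a warning rather than failing.
#'
#' @param l,w Positive diameters in mm (vectorized).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 5) # 125
#' @export
tumor_volume <- function(l, w) {
  check_number(l, "l", lower = .Machine$double.xmin)
  check_number(w, "w", lower = .Machine$double.xmin)
  n <- max(length(l), length(w))
  l <- rep_len(l, n); w <- rep_len(w, n)
  swapped <- w > l
  if (any(swapped)) {
    warning(sprintf(
      "%d measurement(s) had w > l; diameters swapped so l is the longest",
      sum(swapped)
    ), call. = FALSE)
    tmp <- l[swapped]; l[swapped] <- w[swapped]; w[swapped] <- tmp
  }
  l * w * w / 2
}

#' Fold change of mean fluorescence intensity
#'
#' @param mfi_treated,mfi_control Positive MFI values (vectorized).
#' @return `mfi_treated / mfi_control`.
#' @export
mfi_fold_change <- function(mfi_treated, mfi_control) {
  check_number(mfi_treated, "mfi_treated", lower = .Machine$double.xmin)
  check_number(mfi_control, "mfi_control", lower = .Machine$double.xmin)
  mfi_treated / mfi_control
}

#' Correlate two IHC markers across specimens
#'
#' Pairs the derived scores of two markers by specimen id and returns their
#' Pearson correlation (delegating to [correlate()]). Rank correlation is
#' available as an alternative for ordinal-leaning score distributions.
#'
#' @param table IHC data frame with columns `specimen_id`, `marker`,
#'   `percent_positive`, `intensity` (a `score` column is recomputed if
#'   absent).
#' @param marker_a,marker_b Marker names to pair.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `correlation_result`.
#' @export
correlate_markers <- function(table, marker_a, marker_b,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  need <- c("specimen_id", "marker", "percent_positive", "intensity")
  if (!all(need %in% names(table))) {
    abort_invalid(sprintf("IHC table needs columns %s", paste(need, collapse = ", ")))
  }
  table$score <- ihc_score(table$percent_positive, table$intensity)
  a <- table[table$marker == marker_a, c("specimen_id", "score")]
  b <- table[table$marker == marker_b, c("specimen_id", "score")]
  paired <- merge(a, b, by = "specimen_id", suffixes = c("_a", "_b"))
  if (nrow(paired) < 3) {
    abort_glyco(
      sprintf("only %d specimen(s) scored for both '%s' and '%s'; need >= 3",
              nrow(paired), marker_a, marker_b),
      "glycoEMT_insufficient_data"
    )
  }
  if (method == "spearman") {
    ct <- stats::cor.test(paired$score_a, paired$score_b,
                          method = "spearman", exact = FALSE)
    structure(
      list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(paired)),
      class = "correlation_result"
    )
  } else {
    correlate(paired$score_a, paired$score_b)
  }
}
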