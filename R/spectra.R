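#' Construct a set of centroided scans
#'
#' Container for chromatographic MS1 data: an ordered list of scans, each with
#' a retention time (minutes), a sorted m/z vector and an aligned non-negative
#' intensity vector.
#'
#' @param scans List of scans; each scan is a list with elements `rt` (minutes),
#'   `mz` (numeric, sorted ascending) and `intensity` (numeric, same length,
#'   all >= 0).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(scans = list()) {
  rts <- vapply(scans, function(s) as.numeric(s$rt), numeric(1))
  if (length(rts) > 1 && any(diff(rts) <= 0)) {
    abort_invalid("scan retention times must be strictly increasing")
  }
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    if (length(s$mz) != length(s$intensity)) {
      abort_invalid(sprintf("scan %d: mz and intensity lengths differ", i))
    }
    if (length(s$intensity) && any(s$intensity < 0)) {
      abort_invalid(sprintf("scan %d: negative intensity", i))
    }
    if (length(s$mz) > 1 && is.unsorted(s$mz)) {
      o <- order(s$mz)
      scans[[i]]$mz <- s$mz[o]
      scans[[i]]$intensity <- s$intensity[o]
    }
  }
  structure(list(scans = scans), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  n <- length(x$scans)
  cat(sprintf("<spectrum_set> %d scans", n))
  if (n) {
    cat(sprintf(
      ", rt %.3f-%.3f min, %d centroids total",
      x$scans[[1]]$rt, x$scans[[n]]$rt,
      sum(vapply(x$scans, function(s) length(s$mz), integer(1)))
    ))
  }
  cat("\n")
  invisible(x)
}

#' ppm tolerance window around a target m/z
#'
#' @param target_mz Target m/z (> 0).
#' @param ppm_tol Tolerance in parts per million (>= 0).
#' @return Closed interval `c(lo, hi)` with
#'   `lo = target_mz * (1 - ppm_tol * 1e-6)` and
#'   `hi = target_mz * (1 + ppm_tol * 1e-6)`. Boundary hits are inside.
#' @examples
#' mz_window(843.4570, 10)
#' @export
mz_window <- function(target_mz, ppm_tol) {
  check_number(target_mz, "target_mz", lower = .Machine$double.xmin)
  check_number(ppm_tol, "ppm_tol", lower = 0)
  c(target_mz * (1 - ppm_tol * 1e-6), target_mz * (1 + ppm_tol * 1e-6))
}

#' Extract an ion chromatogram at ppm accuracy
#'
#' For every scan, sums the intensities of all centroids whose m/z lies inside
#' the inclusive ppm window around `target_mz`. Scans with no matching centroid
#' contribute a zero point, so the trace always has one point per scan.
#'
#' @param spectra A [spectrum_set()].
#' @param target_mz Target m/z.
#' @param ppm_tol Window half-width in ppm (default 10).
#' @return An object of class `xic_trace`: list with `target_mz`, `ppm_tol` and
#'   a data frame `points` (`rt`, `intensity`). Empty input yields an empty
#'   trace.
#' @export
extract_xic <- function(spectra, target_mz, ppm_tol = 10) {
  if (!inherits(spectra, "spectrum_set")) {
    abort_invalid("'spectra' must be a spectrum_set")
  }
  win <- mz_window(target_mz, ppm_tol)
  pts <- lapply(spectra$scans, function(s) {
    keep <- s$mz >= win[1] & s$mz <= win[2]
    c(rt = s$rt, intensity = if (any(keep)) sum(s$intensity[keep]) else 0)
  })
  points <- if (length(pts)) {
    as.data.frame(do.call(rbind, pts))
  } else {
    data.frame(rt = numeric(0), intensity = numeric(0))
  }
  structure(
    list(target_mz = target_mz, ppm_tol = ppm_tol, points = points),
    class = "xic_trace"
  )
}

#' @export
print.xic_trace <- function(x, ...) {
  cat(sprintf(
    "<xic_trace> m/z %.4f +/- %g ppm, %d points, area %.4g\n",
    x$target_mz, x$ppm_tol, nrow(x$points), integrate_trace(x)
  ))
  invisible(x)
}

#' Integrate an ion chromatogram
#'
#' Trapezoidal integral of intensity over retention time (intensity x minutes).
#' Degenerate conventions: an empty trace integrates to 0; a single-point trace
#' returns that point's intensity so that peak tables round-trip through
#' one-scan spectra.
#'
#' @param trace An [extract_xic()] result (points sorted by retention time).
#' @return Numeric area.
#' @export
integrate_trace <- function(trace) {
  if (!inherits(trace, "xic_trace")) abort_invalid("'trace' must be an xic_trace")
  p <- trace$points
  n <- nrow(p)
  if (n == 0L) return(0)
  if (n == 1L) return(p$intensity[1])
  if (is.unsorted(p$rt)) abort_invalid("trace points must be sorted by retention time")
  sum(diff(p$rt) * (head(p$intensity, -1) + tail(p$intensity, -1)) / 2)
}
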