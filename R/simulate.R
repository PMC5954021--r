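# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_invalid("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# multiplicative log-normal noise with unit mean and the given CV;
# zero expected intensities stay exactly zero
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate peak tables of occupancy MS runs with known ground truth
#'
#' Generative model for one glycosite with true occupancy fraction `theta` and
#' spontaneous deamidation fraction `d` at sample abundance `A`: expected
#' noise-free intensities are `IN = A(1-theta)(1-d)` (native peptide, PNGase F
#' run), `INF = A(theta + (1-theta)d)` (deamidated peptide, PNGase F run:
#' enzymatically de-glycosylated plus spontaneously deamidated), and
#' `IND = A(1-theta)d` (deamidated peptide, control run without PNGase F).
#' Reference-peptide intensities are proportional to `A`. Independent
#' multiplicative log-normal noise with coefficient of variation `noise_cv` is
#' applied to every nonzero intensity. `theta` and `d` are latent parameters
#' of this generator; only the intensities are observable in a real
#' experiment.
#'
#' @param theta True occupancy fraction in `[0, 1]`.
#' @param d Spontaneous deamidation fraction in `[0, 1)`.
#' @param abundance Positive per-sample protein abundance; recycled over
#'   replicates, so a vector simulates unequal loading.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param n_replicates Number of replicate samples.
#' @param seed Integer seed; same seed, same table.
#' @param site_id Opaque glycosite label.
#' @param site_peptide Tryptic peptide carrying the sequon (must contain N).
#' @param site_charge Charge state of the site peptide ion.
#' @return Peak-table data frame (columns `sample_id`, `run_condition`,
#'   `peptide`, `variant`, `site_id`, `intensity`) with attributes `ions`
#'   (ion definitions incl. theoretical m/z), `true_occupancy` (percent) and
#'   `params`.
#' @examples
#' pt <- simulate_occupancy_runs(theta = 0.5, d = 0.1, noise_cv = 0, seed = 1)
#' occupancy_from_peak_table(pt)
#' @export
simulate_occupancy_runs <- function(theta, d = 0.1, abundance = 1,
                                    noise_cv = 0, n_replicates = 1, seed = 1,
                                    site_id = "site1",
                                    site_peptide = "SGNMTTLR",
                                    site_charge = 2L) {
  check_number(theta, "theta", lower = 0, upper = 1)
  check_number(d, "d", lower = 0, upper = 1 - 1e-12)
  check_number(abundance, "abundance", lower = .Machine$double.xmin)
  check_number(noise_cv, "noise_cv", lower = 0)
  if (n_replicates < 1) abort_invalid("'n_replicates' must be >= 1")
  npos <- regexpr("N", site_peptide, fixed = TRUE)
  if (npos < 0) abort_invalid("'site_peptide' must contain an asparagine (N)")

  native <- peptide_ion(site_peptide, site_charge, "native")
  deam <- apply_deamidation(native, as.integer(npos))
  refs <- Map(peptide_ion, REFERENCE_PEPTIDES$sequence, REFERENCE_PEPTIDES$charge,
              "reference")
  ions <- data.frame(
    peptide = c(site_peptide, observed_sequence(deam),
                REFERENCE_PEPTIDES$sequence),
    variant = c("native", "deamidated", "reference", "reference"),
    charge = c(site_charge, site_charge, REFERENCE_PEPTIDES$charge),
    mz = c(native$mz, deam$mz,
           vapply(refs, function(io) io$mz, numeric(1))),
    site_id = c(site_id, site_id, NA, NA),
    stringsAsFactors = FALSE
  )

  A <- rep_len(abundance, n_replicates)
  with_seed(seed, {
    rows <- lapply(seq_len(n_replicates), function(i) {
      s <- sprintf("S%02d", i)
      expected <- data.frame(
        sample_id = s,
        run_condition = c("pngasef", "pngasef", "pngasef", "pngasef",
                          "control", "control", "control", "control"),
        peptide = c(ions$peptide[c(1, 2, 3, 4)], ions$peptide[c(1, 2, 3, 4)]),
        variant = c(ions$variant[c(1, 2, 3, 4)], ions$variant[c(1, 2, 3, 4)]),
        site_id = c(ions$site_id[c(1, 2, 3, 4)], ions$site_id[c(1, 2, 3, 4)]),
        intensity = A[i] * c(
          (1 - theta) * (1 - d),        # IN: native after PNGase F
          theta + (1 - theta) * d,      # INF: de-glycosylated + spontaneous
          1, 1,                         # references track abundance
          (1 - theta) * (1 - d),        # native, control run
          (1 - theta) * d,              # IND: spontaneous deamidation only
          1, 1
        ),
        stringsAsFactors = FALSE
      )
      expected$intensity <- expected$intensity *
        lognormal_noise(nrow(expected), noise_cv)
      expected
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "ions") <- ions
    attr(out, "true_occupancy") <- 100 * theta
    attr(out, "params") <- list(
      theta = theta, d = d, abundance = A, noise_cv = noise_cv,
      n_replicates = n_replicates, seed = seed
    )
    out
  })
}

#' Render a peak table as centroided spectra with Gaussian elution peaks
#'
#' Each ion of each sample/run becomes a Gaussian-shaped series of centroids
#' at its theoretical m/z (optionally jittered per scan), scaled so that the
#' trapezoidal XIC area recovers the table intensity. The retention-time grid
#' spans `rt_center` +/- 4 `rt_sigma`.
#'
#' @param peak_table A table from [simulate_occupancy_runs()] (or of the same
#'   shape with an `ions` attribute / argument).
#' @param rt_center,rt_sigma Elution peak center and width, minutes.
#' @param mz_jitter_ppm Standard deviation of the per-centroid m/z jitter, in
#'   ppm of the theoretical m/z.
#' @param n_scans Number of scans (>= 3); >= 50 keeps the trapezoid within 2%
#'   of the generated area at jitter <= 2 ppm.
#' @param seed Integer seed for the jitter.
#' @param ions Ion definition data frame (`peptide`, `variant`, `charge`,
#'   `mz`, `site_id`); defaults to the table's `ions` attribute.
#' @param ppm_tol Extraction window the spectra are destined for; a jitter sd
#'   exceeding it triggers a signal-loss warning.
#' @return Named list of [spectrum_set()], keyed `"<sample_id>.<run_condition>"`,
#'   carrying the `ions` table as an attribute.
#' @export
simulate_spectra <- function(peak_table, rt_center = 10, rt_sigma = 0.2,
                             mz_jitter_ppm = 0, n_scans = 60, seed = 1,
                             ions = attr(peak_table, "ions"), ppm_tol = 10) {
  if (is.null(ions)) abort_invalid("'ions' definitions required (peptide, charge, mz)")
  if (n_scans < 3) abort_invalid("'n_scans' must be >= 3")
  check_number(rt_sigma, "rt_sigma", lower = .Machine$double.xmin)
  check_number(mz_jitter_ppm, "mz_jitter_ppm", lower = 0)
  if (mz_jitter_ppm > ppm_tol) {
    warning("m/z jitter exceeds the ppm window; expect signal loss", call. = FALSE)
  }
  rt <- seq(rt_center - 4 * rt_sigma, rt_center + 4 * rt_sigma,
            length.out = n_scans)
  shape <- stats::dnorm(rt, rt_center, rt_sigma)
  # trapezoid of the sampled gaussian, used to rescale so area == intensity
  shape_area <- sum(diff(rt) * (head(shape, -1) + tail(shape, -1)) / 2)
  groups <- unique(peak_table[, c("sample_id", "run_condition")])
  with_seed(seed, {
    out <- lapply(seq_len(nrow(groups)), function(g) {
      sub <- peak_table[peak_table$sample_id == groups$sample_id[g] &
                          peak_table$run_condition == groups$run_condition[g], ]
      key <- paste(sub$peptide, sub$variant)
      idx <- match(key, paste(ions$peptide, ions$variant))
      if (anyNA(idx)) abort_invalid("peak table row without a matching ion definition")
      scans <- lapply(seq_len(n_scans), function(k) {
        mzs <- inten <- numeric(0)
        for (j in seq_len(nrow(sub))) {
          amp <- sub$intensity[j] * shape[k] / shape_area
          if (amp <= 0) next
          jit <- if (mz_jitter_ppm > 0) {
            1 + mz_jitter_ppm * stats::rnorm(1) * 1e-6
          } else 1
          mzs <- c(mzs, ions$mz[idx[j]] * jit)
          inten <- c(inten, amp)
        }
        list(rt = rt[k], mz = mzs, intensity = inten)
      })
      spectrum_set(scans)
    })
    names(out) <- paste(groups$sample_id, groups$run_condition, sep = ".")
    attr(out, "ions") <- ions
    out
  })
}

#' Quantify ions from spectra by XIC extraction and integration
#'
#' Rebuilds a peak table from spectra: for every ion definition and every
#' sample/run spectrum set, extracts the ppm-window ion chromatogram at the
#' theoretical m/z and integrates it.
#'
#' @param spectra Named list of [spectrum_set()] keyed
#'   `"<sample_id>.<run_condition>"` (as produced by [simulate_spectra()]).
#' @param ions Ion definition data frame; defaults to the `ions` attribute.
#' @param ppm_tol Extraction tolerance in ppm (default 10).
#' @return Peak-table data frame suitable for [occupancy_from_peak_table()].
#' @export
xic_quantify <- function(spectra, ions = attr(spectra, "ions"), ppm_tol = 10) {
  if (is.null(ions)) abort_invalid("'ions' definitions required")
  keys <- strsplit(names(spectra), ".", fixed = TRUE)
  rows <- lapply(seq_along(spectra), function(g) {
    areas <- vapply(seq_len(nrow(ions)), function(j) {
      integrate_trace(extract_xic(spectra[[g]], ions$mz[j], ppm_tol))
    }, numeric(1))
    data.frame(
      sample_id = keys[[g]][1], run_condition = keys[[g]][2],
      peptide = ions$peptide, variant = ions$variant, site_id = ions$site_id,
      intensity = areas, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an expression matrix with epithelial/mesenchymal group structure
#'
#' Draws a baseline log2 expression level per gene, shifts signature-arm genes
#' by the group effect (mesenchymal-arm genes up by `effect` in the
#' mesenchymal group, epithelial-arm genes down by `effect`), injects genes
#' correlated with group membership at requested levels, adds Gaussian noise
#' on the log2 scale, and returns the matrix exponentiated back to raw
#' (RSEM-like) space.
#'
#' @param signature An [emt_signature()].
#' @param n_epithelial,n_mesenchymal Group sizes (>= 2).
#' @param effect Mean log2 shift of mesenchymal-arm genes in the mesenchymal
#'   group; epithelial-arm genes shift by `-effect` there.
#' @param noise_sd Residual standard deviation on the log2 scale (> 0).
#' @param linked_genes Named numeric vector mapping gene id to its target
#'   point-biserial correlation with group membership (|rho| < 1). A linked
#'   gene also present in the signature follows the linked specification (with
#'   a warning), not the arm shift.
#' @param n_background Number of unstructured background genes to add.
#' @param seed Integer seed.
#' @return Numeric gene x sample matrix in raw space, with attributes
#'   `space = "raw"` and `group` (factor `"epithelial"` / `"mesenchymal"` per
#'   sample).
#' @export
simulate_expression <- function(signature, n_epithelial = 50, n_mesenchymal = 50,
                                effect = 1, noise_sd = 0.5,
                                linked_genes = numeric(), n_background = 10,
                                seed = 1) {
  if (!inherits(signature, "emt_signature")) {
    abort_invalid("'signature' must be an emt_signature")
  }
  if (n_epithelial < 2 || n_mesenchymal < 2) abort_invalid("group sizes must be >= 2")
  check_number(noise_sd, "noise_sd", lower = .Machine$double.xmin)
  if (length(linked_genes)) {
    if (is.null(names(linked_genes)) || any(!nzchar(names(linked_genes)))) {
      abort_invalid("'linked_genes' must be a named vector")
    }
    check_number(linked_genes, "linked_genes", lower = -1 + 1e-9, upper = 1 - 1e-9)
  }
  mes <- signature$mesenchymal_genes
  epi <- signature$epithelial_genes
  collide <- intersect(names(linked_genes), c(mes, epi))
  if (length(collide)) {
    warning(sprintf(
      "gene(s) %s are both signature members and linked genes; linked correlation takes precedence",
      paste(collide, collapse = ", ")
    ), call. = FALSE)
  }
  bg <- if (n_background > 0) sprintf("BG%03d", seq_len(n_background)) else character()
  genes <- unique(c(mes, epi, names(linked_genes), bg))
  samples <- c(sprintf("E%03d", seq_len(n_epithelial)),
               sprintf("M%03d", seq_len(n_mesenchymal)))
  z <- c(rep(0, n_epithelial), rep(1, n_mesenchymal))

  with_seed(seed, {
    baseline <- stats::runif(length(genes), 5, 12)
    names(baseline) <- genes
    lg <- matrix(stats::rnorm(length(genes) * length(samples), sd = noise_sd),
                 nrow = length(genes), dimnames = list(genes, samples))
    lg <- lg + baseline
    arm_shift <- ifelse(genes %in% mes, effect, ifelse(genes %in% epi, -effect, 0))
    arm_shift[genes %in% collide] <- 0
    lg <- lg + outer(arm_shift, z)
    if (length(linked_genes)) {
      p <- mean(z)
      sz <- sqrt(p * (1 - p))
      for (g in names(linked_genes)) {
        rho <- linked_genes[[g]]
        b <- rho * noise_sd / (sz * sqrt(1 - rho^2))
        lg[g, ] <- baseline[g] + b * (z - p) +
          stats::rnorm(length(samples), sd = noise_sd)
      }
    }
    out <- 2^lg
    attr(out, "space") <- "raw"
    attr(out, "group") <- factor(ifelse(z == 1, "mesenchymal", "epithelial"),
                                 levels = c("epithelial", "mesenchymal"))
    out
  })
}

#' Simulate a co-expressed IHC marker table
#'
#' Draws one latent standard-normal value per specimen and marker with an
#' exchangeable latent correlation `rho` between markers, then maps each
#' latent monotonically to a percent-positive value (`100 * pnorm(z)`) and an
#' intensity grade (quantile cuts at the 25th, 50th and 75th latent
#' percentiles, giving grades 0-3). Observed score correlations are therefore
#' attenuated relative to `rho` by the discretization.
#'
#' @param n Number of specimens (>= 3).
#' @param rho Latent correlation, |rho| < 1.
#' @param markers Character vector of at least two marker names.
#' @param seed Integer seed.
#' @return Long-format data frame with columns `specimen_id`, `marker`,
#'   `percent_positive`, `intensity`, `score`.
#' @export
simulate_ihc <- function(n, rho, markers = c("markerA", "markerB"), seed = 1) {
  if (n < 3) abort_invalid("'n' must be >= 3")
  check_number(rho, "rho", lower = -1 + 1e-9, upper = 1 - 1e-9)
  k <- length(markers)
  if (k < 2) abort_invalid("need at least two markers")
  sigma <- matrix(rho, k, k); diag(sigma) <- 1
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort_invalid("'rho' does not give a positive-definite latent correlation")
  })
  with_seed(seed, {
    zl <- matrix(stats::rnorm(n * k), n, k) %*% ch
    cuts <- stats::qnorm(c(0.25, 0.5, 0.75))
    rows <- lapply(seq_len(k), function(j) {
      data.frame(
        specimen_id = sprintf("T%04d", seq_len(n)),
        marker = markers[j],
        percent_positive = round(100 * stats::pnorm(zl[, j]), 1),
        intensity = findInterval(zl[, j], cuts),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$score <- ihc_score(out$percent_positive, out$intensity)
    rownames(out) <- NULL
    out
  })
}
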