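test_that("reference normalization scales by baseline/sample mean ratio", {
  refs <- REFERENCE_PEPTIDES$sequence
  pt <- data.frame(
    sample_id = c("A", "A", "A", "B", "B", "B"),
    run_condition = "pngasef",
    peptide = c(refs, "SGNMTTLR", refs, "SGNMTTLR"),
    variant = c("reference", "reference", "native",
                "reference", "reference", "native"),
    site_id = c(NA, NA, "s1", NA, NA, "s1"),
    intensity = c(10, 10, 8, 5, 5, 3)
  )
  out <- normalize_to_reference(pt)
  # baseline A ref mean 10, sample B ref mean 5 -> factor 2
  expect_equal(out$normalized_intensity[out$sample_id == "B" &
                                          out$variant == "native"], 6)
  # baseline untouched
  expect_equal(out$normalized_intensity[out$sample_id == "A"],
               out$intensity[out$sample_id == "A"])
  # equal ref means everywhere -> identity
  pt2 <- pt; pt2$intensity <- c(10, 10, 8, 10, 10, 3)
  expect_equal(normalize_to_reference(pt2)$normalized_intensity, pt2$intensity)
})

test_that("normalization guards zero and missing references", {
  refs <- REFERENCE_PEPTIDES$sequence
  pt <- data.frame(
    sample_id = c("A", "A", "B", "B"),
    run_condition = "pngasef",
    peptide = c(refs, refs),
    variant = "reference", site_id = NA,
    intensity = c(10, 10, 0, 0)
  )
  err <- expect_error(normalize_to_reference(pt), class = "glycoEMT_zero_reference")
  expect_match(conditionMessage(err), "'B'")
  pt3 <- pt[-4, ]
  expect_error(normalize_to_reference(pt3), class = "glycoEMT_missing_reference")
})

test_that("occupancy formula handles boundary, zero-numerator and clamped cases", {
  # 100% occupancy: no native signal, no spontaneous deamidation
  expect_equal(compute_site_occupancy(IN = 0, INF = 1, IND = 0)$occupancy_percent, 100)
  # INF == IND -> numerator vanishes
  expect_equal(compute_site_occupancy(IN = 2, INF = 0.3, IND = 0.3)$occupancy_percent, 0)
  # generative noise-free example at theta 0.5, d 0.1
  expect_equal(
    compute_site_occupancy(IN = 0.45, INF = 0.55, IND = 0.05)$occupancy_percent, 50
  )
  # IND > INF: clamped to 0 and flagged, never dropped
  res <- compute_site_occupancy(IN = 1, INF = 0.1, IND = 0.5)
  expect_lt(res$raw_percent, 0)
  expect_equal(res$occupancy_percent, 0)
  expect_match(res$flags, "negative_raw")
  # zero denominator: occupancy unset with flag
  res0 <- compute_site_occupancy(IN = 0, INF = 0, IND = 0.2)
  expect_true(is.na(res0$occupancy_percent))
  expect_match(res0$flags, "zero_denominator")
  # low-signal floor
  resl <- compute_site_occupancy(IN = 1e-9, INF = 1e-9, IND = 0,
                                 low_signal_floor = 1e-6)
  expect_match(resl$flags, "low_signal")
  expect_error(compute_site_occupancy(-1, 1, 0), class = "glycoEMT_invalid_input")
})

test_that("noise-free generative intensities recover occupancy exactly over the grid", {
  for (theta in seq(0, 1, by = 0.1)) {
    for (d in c(0, 0.05, 0.1, 0.2)) {
      for (A in c(0.3, 1, 17)) {
        IN <- A * (1 - theta) * (1 - d)
        INF <- A * (theta + (1 - theta) * d)
        IND <- A * (1 - theta) * d
        res <- compute_site_occupancy(IN, INF, IND)
        if (IN + INF == 0) {
          expect_match(res$flags, "zero_denominator")
        } else {
          expect_equal(res$occupancy_percent, 100 * theta, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("occupancy is invariant to per-sample abundance rescaling", {
  pt <- simulate_occupancy_runs(theta = 0.37, d = 0.08, noise_cv = 0.1,
                                n_replicates = 3, seed = 5)
  base <- occupancy_from_peak_table(pt)
  scaled <- pt
  idx <- scaled$sample_id == "S02"
  scaled$intensity[idx] <- scaled$intensity[idx] * 7.3
  res <- occupancy_from_peak_table(scaled)
  expect_equal(res$occupancy_percent, base$occupancy_percent, tolerance = 1e-9)
})

test_that("peak-table assembly pivots IN/INF/IND per site and sample", {
  pt <- simulate_occupancy_runs(theta = 0.5, d = 0.1, noise_cv = 0,
                                n_replicates = 2, seed = 1)
  occ <- occupancy_from_peak_table(pt)
  expect_equal(nrow(occ), 2)
  expect_equal(occ$IN, c(0.45, 0.45))
  expect_equal(occ$INF, c(0.55, 0.55))
  expect_equal(occ$IND, c(0.05, 0.05))
  expect_equal(occ$occupancy_percent, c(50, 50))
})
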