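test_that("noise-free occupancy runs produce the model's expected intensities", {
  pt <- simulate_occupancy_runs(theta = 0.5, d = 0.1, abundance = 1,
                                noise_cv = 0, seed = 1)
  get <- function(variant, run) {
    pt$intensity[pt$variant == variant & pt$run_condition == run][1]
  }
  expect_equal(get("native", "pngasef"), 0.45)      # IN = A(1-theta)(1-d)
  expect_equal(get("deamidated", "pngasef"), 0.55)  # INF = A(theta+(1-theta)d)
  expect_equal(get("deamidated", "control"), 0.05)  # IND = A(1-theta)d
  expect_equal(occupancy_from_peak_table(pt)$occupancy_percent, 50)
})

test_that("boundary occupancies behave as the formula implies", {
  # full occupancy: no native signal and no spontaneous deamidation signal
  pt1 <- simulate_occupancy_runs(theta = 1, d = 0.2, noise_cv = 0, seed = 1)
  expect_equal(pt1$intensity[pt1$variant == "native" &
                               pt1$run_condition == "pngasef"], 0)
  expect_equal(pt1$intensity[pt1$variant == "deamidated" &
                               pt1$run_condition == "control"], 0)
  expect_equal(occupancy_from_peak_table(pt1)$occupancy_percent, 100)
  # nothing glycosylated, no deamidation
  pt0 <- simulate_occupancy_runs(theta = 0, d = 0, noise_cv = 0, seed = 1)
  expect_equal(pt0$intensity[pt0$variant == "deamidated" &
                               pt0$run_condition == "pngasef"], 0)
  expect_equal(occupancy_from_peak_table(pt0)$occupancy_percent, 0)
})

test_that("occupancy simulation is deterministic under a fixed seed", {
  a <- simulate_occupancy_runs(theta = 0.4, noise_cv = 0.2, n_replicates = 4, seed = 9)
  b <- simulate_occupancy_runs(theta = 0.4, noise_cv = 0.2, n_replicates = 4, seed = 9)
  expect_identical(a, b)
  c <- simulate_occupancy_runs(theta = 0.4, noise_cv = 0.2, n_replicates = 4, seed = 10)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("replicate means recover the true occupancy within 2 points at 5% CV", {
  for (theta in c(0.1, 0.5, 0.9)) {
    pt <- simulate_occupancy_runs(theta = theta, d = 0.1, noise_cv = 0.05,
                                  n_replicates = 3, seed = 11)
    occ <- occupancy_from_peak_table(pt)
    expect_lt(abs(mean(occ$occupancy_percent) - 100 * theta), 2)
  }
})

test_that("simulated spectra integrate back to the generating intensities", {
  # construction check: single gaussian ion of known total area
  sp <- gaussian_spectra(mz = 843.4570, total = 100)
  tr <- extract_xic(sp, 843.4570, 10)
  expect_equal(integrate_trace(tr), 100, tolerance = 0.02 * 100)
  # through the simulator: every ion within 2% at jitter <= 2 ppm, >= 50 scans
  pt <- simulate_occupancy_runs(theta = 0.3, d = 0.1, noise_cv = 0, seed = 2)
  sp2 <- simulate_spectra(pt, mz_jitter_ppm = 2, n_scans = 60, seed = 3)
  rebuilt <- xic_quantify(sp2)
  key <- function(df) paste(df$sample_id, df$run_condition, df$peptide, df$variant)
  m <- match(key(pt), key(rebuilt))
  expect_false(anyNA(m))
  expect_equal(rebuilt$intensity[m], pt$intensity, tolerance = 0.02)
})

test_that("jitter beyond the ppm window loses signal and warns", {
  pt <- simulate_occupancy_runs(theta = 0.5, d = 0.1, noise_cv = 0, seed = 2)
  expect_warning(
    sp <- simulate_spectra(pt, mz_jitter_ppm = 20, n_scans = 60, seed = 3),
    "signal loss"
  )
  rebuilt <- xic_quantify(sp)
  tot_in <- sum(pt$intensity)
  expect_lt(sum(rebuilt$intensity), tot_in)
})

test_that("spectra simulation is deterministic under a fixed seed", {
  pt <- simulate_occupancy_runs(theta = 0.5, d = 0.1, noise_cv = 0, seed = 2)
  s1 <- simulate_spectra(pt, mz_jitter_ppm = 1, n_scans = 20, seed = 5)
  s2 <- simulate_spectra(pt, mz_jitter_ppm = 1, n_scans = 20, seed = 5)
  expect_identical(s1, s2)
})

test_that("full pipeline from spectra recovers theta within 3 points", {
  for (theta in c(0.1, 0.5, 0.9)) {
    pt <- simulate_occupancy_runs(theta = theta, d = 0.1, noise_cv = 0.05,
                                  n_replicates = 3, seed = 11)
    sp <- simulate_spectra(pt, mz_jitter_ppm = 2, n_scans = 60, seed = 12)
    occ <- occupancy_from_peak_table(xic_quantify(sp))
    expect_lt(abs(mean(occ$occupancy_percent) - 100 * theta), 3)
  }
})

test_that("simulated expression separates groups by twice the arm effect", {
  sig <- default_emt_signature()
  m <- simulate_expression(sig, n_epithelial = 50, n_mesenchymal = 50,
                           effect = 1, seed = 13)
  expect_identical(attr(m, "space"), "raw")
  expect_true(all(m >= 0))
  lr <- log_ratio_transform(m)
  sc <- emt_score(lr, sig)
  g <- attr(m, "group")
  delta <- mean(sc$emt_score[g == "mesenchymal"]) -
    mean(sc$emt_score[g == "epithelial"])
  expect_lt(abs(delta - 2), 0.2)
  expect_gt(mean(sc$emt_score[g == "mesenchymal"]),
            mean(sc$emt_score[g == "epithelial"]))
})

test_that("null expression model shows no group separation", {
  sig <- default_emt_signature()
  m <- simulate_expression(sig, n_epithelial = 40, n_mesenchymal = 40,
                           effect = 0, noise_sd = 0.5, seed = 14)
  sc <- emt_score(log_ratio_transform(m), sig)
  g <- attr(m, "group")
  delta <- mean(sc$emt_score[g == "mesenchymal"]) -
    mean(sc$emt_score[g == "epithelial"])
  # |delta| < 3 standard errors of the mean difference
  se <- sqrt(var(sc$emt_score[g == "mesenchymal"]) / 40 +
               var(sc$emt_score[g == "epithelial"]) / 40)
  expect_lt(abs(delta), 3 * se)
})

test_that("expression simulation is deterministic and warns on collisions", {
  sig <- default_emt_signature()
  a <- simulate_expression(sig, 10, 10, seed = 15)
  b <- simulate_expression(sig, 10, 10, seed = 15)
  expect_identical(a, b)
  expect_warning(
    simulate_expression(sig, 10, 10, linked_genes = c(VIM = 0.5), seed = 15),
    "linked correlation takes precedence"
  )
})

test_that("simulated IHC tables honor their latent correlation structure", {
  null_tb <- simulate_ihc(1000, rho = 0, seed = 16)
  r0 <- correlate_markers(null_tb, "markerA", "markerB")$r
  expect_lt(abs(r0), 0.08)
  hi <- simulate_ihc(1000, rho = 0.9, seed = 17)
  expect_gt(correlate_markers(hi, "markerA", "markerB")$r, 0.6)
  expect_identical(simulate_ihc(50, 0.5, seed = 18), simulate_ihc(50, 0.5, seed = 18))
  expect_error(simulate_ihc(50, 1.5, seed = 1), class = "glycoEMT_invalid_input")
  expect_error(simulate_ihc(2, 0.5, seed = 1), class = "glycoEMT_invalid_input")
  tb <- simulate_ihc(20, 0.5, seed = 19)
  expect_true(all(tb$percent_positive >= 0 & tb$percent_positive <= 100))
  expect_true(all(tb$intensity %in% 0:3))
})

test_that("gene-score correlation is calibrated at the nominal level under the null", {
  sig <- default_emt_signature()
  rej <- vapply(1:200, function(i) {
    m <- simulate_expression(sig, n_epithelial = 15, n_mesenchymal = 15,
                             effect = 0, noise_sd = 0.5, n_background = 1,
                             seed = i)
    lr <- log_ratio_transform(m)
    sc <- emt_score(lr, sig)
    correlate(lr["BG001", ], sc$emt_score)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})
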