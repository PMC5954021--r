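test_that("log-ratio transform centers each gene at zero", {
  m <- matrix(c(4, 4, 4,   2, 4, 8,   1, 2, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  lr <- log_ratio_transform(m, pseudocount = 0)
  # constant gene -> all zeros
  expect_equal(unname(lr["g1", ]), c(0, 0, 0))
  # sample at 2x the gene median -> +1
  expect_equal(lr["g2", "c"], 1)
  expect_equal(lr["g3", "c"], 1)
  expect_identical(attr(lr, "space"), "log_ratio")
  # single-sample matrix -> all zeros
  m1 <- m[, 1, drop = FALSE]
  expect_true(all(log_ratio_transform(m1, pseudocount = 0) == 0))
  # zero values demand a positive pseudocount
  m0 <- m; m0["g1", 1] <- 0
  expect_error(log_ratio_transform(m0, pseudocount = 0),
               class = "glycoEMT_domain_error")
  expect_silent(log_ratio_transform(m0, pseudocount = 1))
})

test_that("EMT score is the documented arm-mean difference on hand-built matrices", {
  m <- hand_matrix()
  sig <- emt_signature(c("m1", "m2"), "e1")
  sc <- emt_score(m, sig)
  # sample s1: mean(1,3) - (-2) = 4; s2: mean(2,0) - 1 = 0; s3: mean(-1,1) - 0 = 0
  expect_equal(sc$emt_score, c(4, 0, 0))
  expect_equal(sc$sample_id, c("s1", "s2", "s3"))
  # permutation within an arm changes nothing
  sig_perm <- emt_signature(c("m2", "m1"), "e1")
  expect_equal(emt_score(m, sig_perm)$emt_score, sc$emt_score)
  # equal arm means -> 0 handled above (s2, s3)
})

test_that("EMT score is antisymmetric under arm swap", {
  sig <- default_emt_signature()
  m <- simulate_expression(sig, n_epithelial = 10, n_mesenchymal = 10,
                           effect = 0.8, seed = 21)
  lr <- log_ratio_transform(m)
  sc <- emt_score(lr, sig)
  swapped <- emt_score(lr, swap_arms(sig))
  expect_equal(swapped$emt_score, -sc$emt_score)
})

test_that("missing signature genes warn and shrink coverage; empty arm errors", {
  m <- hand_matrix()
  sig <- emt_signature(c("m1", "m2", "ghost"), "e1")
  expect_warning(sc <- emt_score(m, sig), "ghost")
  expect_equal(attr(sc, "coverage")[["mesenchymal"]], 2 / 3)
  expect_equal(attr(sc, "coverage")[["epithelial"]], 1)
  sig_bad <- emt_signature("m1", "nowhere")
  expect_error(emt_score(m, sig_bad), class = "glycoEMT_unusable_signature")
  # raw-space matrix must be transformed first
  raw <- matrix(1:4, 2, dimnames = list(c("m1", "e1"), c("a", "b")))
  attr(raw, "space") <- "raw"
  expect_error(emt_score(raw, emt_signature("m1", "e1")),
               class = "glycoEMT_invalid_input")
})

test_that("the packaged signature fixture has the expected two-arm shape", {
  sig <- default_emt_signature()
  expect_length(sig$mesenchymal_genes, 20)
  expect_length(sig$epithelial_genes, 17)
  expect_length(intersect(sig$mesenchymal_genes, sig$epithelial_genes), 0)
})

test_that("correlate matches the textbook Pearson formula and validates input", {
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20) + 0.5 * x
    res <- correlate(x, y)
    expect_equal(res$r, manual_pearson(x, y), tolerance = 1e-12)
    expect_equal(res$n, 20)
  }
  x <- rnorm(10)
  expect_equal(correlate(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(correlate(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 10)), class = "glycoEMT_undefined_correlation")
  expect_error(correlate(x, rnorm(9)), class = "glycoEMT_invalid_input")
  expect_error(correlate(1:2, 2:1), class = "glycoEMT_invalid_input")
})

test_that("a linked gene recovers its construction correlation with the group", {
  sig <- default_emt_signature()
  m <- simulate_expression(sig, n_epithelial = 250, n_mesenchymal = 250,
                           effect = 0, linked_genes = c(GENE1 = 0.8), seed = 7)
  z <- as.integer(attr(m, "group") == "mesenchymal")
  lr <- log_ratio_transform(m)
  expect_equal(correlate(lr["GENE1", ], z)$r, 0.8, tolerance = 0.08)
})

test_that("heatmap colors follow the two-sided ramp conventions", {
  ex <- heatmap_colors(c(0, 3, -3, 1.5, 10), "expression", vmax = 3)
  expect_equal(ex[1, ], c(r = 0, g = 0, b = 0))        # 0 -> black
  expect_equal(ex[2, ], c(r = 255, g = 0, b = 0))      # +vmax -> pure red
  expect_equal(ex[3, ], c(r = 0, g = 255, b = 0))      # -vmax -> pure green
  expect_equal(ex[4, ], c(r = 128, g = 0, b = 0))      # half-way up the ramp
  expect_equal(ex[5, ], c(r = 255, g = 0, b = 0))      # saturates beyond vmax
  sc <- heatmap_colors(c(0, 1, -1), "emt_score", vmax = 1)
  expect_equal(sc[1, ], c(r = 128, g = 128, b = 128))  # 0 -> gray
  expect_equal(sc[2, ], c(r = 255, g = 255, b = 0))    # mesenchymal -> yellow
  expect_equal(sc[3, ], c(r = 0, g = 0, b = 255))      # epithelial -> blue
  # hue oddness: same intensity, opposite arm
  set.seed(4)
  v <- runif(20, -3, 3)
  up <- heatmap_colors(abs(v), "expression", 3)
  dn <- heatmap_colors(-abs(v), "expression", 3)
  expect_equal(unname(up[, "r"]), unname(dn[, "g"]))
  expect_true(all(dn[, "r"] == 0) && all(up[, "g"] == 0))
})
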