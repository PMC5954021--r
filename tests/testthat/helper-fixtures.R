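# textbook Pearson correlation, kept independent of stats::cor for cross-checks
manual_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# brute-force residue-sum mass using an independently keyed copy of the
# standard monoisotopic table (checked against AA_MONO_MASS only via results)
brute_force_mass <- function(seq) {
  tab <- c(
    A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
    C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
    H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
    M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
    T = 101.047679, W = 186.079313, Y = 163.063329, V = 99.068414
  )
  sum(tab[strsplit(seq, "")[[1]]]) + 18.010565
}

random_peptide <- function(n) {
  paste(sample(names(glycoEMT::AA_MONO_MASS), n, replace = TRUE), collapse = "")
}

# one-ion spectrum set: gaussian elution at a single m/z
gaussian_spectra <- function(mz, total = 100, n_scans = 60, center = 10, sigma = 0.2) {
  rt <- seq(center - 4 * sigma, center + 4 * sigma, length.out = n_scans)
  shape <- dnorm(rt, center, sigma)
  area <- sum(diff(rt) * (head(shape, -1) + tail(shape, -1)) / 2)
  spectrum_set(lapply(seq_along(rt), function(k) {
    list(rt = rt[k], mz = mz, intensity = total * shape[k] / area)
  }))
}

# 3x3 log-ratio matrix with known arm means for exact score checks
hand_matrix <- function() {
  m <- matrix(
    c( 1,  2, -1,   # gene m1
       3,  0,  1,   # gene m2
      -2,  1,  0),  # gene e1
    nrow = 3, byrow = TRUE,
    dimnames = list(c("m1", "m2", "e1"), c("s1", "s2", "s3"))
  )
  attr(m, "space") <- "log_ratio"
  m
}
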