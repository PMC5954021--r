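#' Physical constants used throughout the package
#'
#' Monoisotopic residue masses of the 20 standard amino acids (mass of the
#' residue as incorporated in a peptide chain, i.e. amino acid minus water),
#' the mass of one water molecule added per intact peptide, the proton mass
#' used for charge-state m/z conversion, and the exact monoisotopic mass shift
#' of asparagine deamidation to aspartate (N -> D). Values follow the standard
#' monoisotopic mass tables used in proteomics (CODATA/IUPAC isotopic masses).
#'
#' @format `AA_MONO_MASS` is a named numeric vector keyed by one-letter residue
#'   code; the remaining objects are length-one numerics in Dalton.
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
AA_MONO_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' @rdname mass-constants
#' @export
WATER_MASS <- 18.010565

#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.00727646

# exact monoisotopic N -> D delta (replacement of -NH2 by -OH); the nominal
# "one mass unit" shift is an approximation that a ppm-level window must not use
#' @rdname mass-constants
#' @export
DEAMIDATION_DELTA <- 0.984016

#' Reference peptides used for protein-amount normalization
#'
#' Two non-glycosylated tryptic peptides of PD-L1 whose summed signal tracks
#' total protein amount across samples. Charge states 2+ and 3+ reproduce the
#' reported m/z values 843.4570 and 586.3003 from the monoisotopic masses.
#'
#' @format A data frame with columns `sequence` and `charge`.
#' @export
REFERENCE_PEPTIDES <- data.frame(
  sequence = c("DQLSLGNAALQITDVK", "AEVIWTSSDHQVLSGK"),
  charge = c(2L, 3L),
  stringsAsFactors = FALSE
)

# single serializable table of every constant, hashed into run logs so a log
# pins the exact values a run used
constants_table <- function() {
  list(
    residue_masses = as.list(AA_MONO_MASS),
    water_mass = WATER_MASS,
    proton_mass = PROTON_MASS,
    deamidation_delta = DEAMIDATION_DELTA,
    reference_peptides = REFERENCE_PEPTIDES
  )
}

constants_hash <- function() {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(constants_table(), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
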