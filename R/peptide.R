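#' Construct a peptide ion
#'
#' A peptide ion couples a tryptic peptide sequence with a charge state and a
#' variant label. `variant = "native"` is the unmodified sequon-carrying
#' peptide (N at the glycosite), `"deamidated"` is the de-N-glycosylated or
#' spontaneously deamidated form (N converted to D at the listed positions),
#' and `"reference"` marks a non-glycosylated normalization peptide.
#'
#' @param sequence Peptide string in one-letter amino-acid codes.
#' @param charge Positive integer charge state.
#' @param variant One of `"native"`, `"deamidated"`, `"reference"`.
#' @param deamidation_positions Integer vector of 1-based residue indices that
#'   have been converted N -> D; required (non-empty) iff
#'   `variant = "deamidated"`. Positions refer to the native sequence, which
#'   must carry N there.
#' @return An object of class `peptide_ion` with fields `sequence`, `charge`,
#'   `variant`, `deamidation_positions`, and derived `mass` (Da) and `mz`.
#' @examples
#' peptide_ion("DQLSLGNAALQITDVK", charge = 2, variant = "reference")
#' @export
peptide_ion <- function(sequence, charge, variant = c("native", "deamidated", "reference"),
                        deamidation_positions = integer()) {
  variant <- match.arg(variant)
  validate_sequence(sequence)
  if (!is.numeric(charge) || length(charge) != 1L || is.na(charge) ||
      charge < 1 || charge != as.integer(charge)) {
    abort_invalid("'charge' must be a positive integer")
  }
  deamidation_positions <- as.integer(deamidation_positions)
  if (variant == "deamidated") {
    if (length(deamidation_positions) == 0L) {
      abort_invalid("deamidated variant requires at least one deamidation position")
    }
    res <- strsplit(sequence, "", fixed = TRUE)[[1]]
    bad <- deamidation_positions[deamidation_positions < 1L |
                                   deamidation_positions > length(res)]
    if (length(bad)) {
      abort_invalid(sprintf("deamidation position %d outside sequence", bad[1]))
    }
    not_n <- deamidation_positions[res[deamidation_positions] != "N"]
    if (length(not_n)) {
      abort_invalid(sprintf(
        "residue at position %d is '%s', not N; cannot deamidate",
        not_n[1], res[not_n[1]]
      ))
    }
  } else if (length(deamidation_positions) > 0L) {
    abort_invalid("deamidation_positions only allowed for the deamidated variant")
  }
  mass <- monoisotopic_mass(sequence) +
    length(deamidation_positions) * DEAMIDATION_DELTA
  structure(
    list(
      sequence = sequence, charge = as.integer(charge), variant = variant,
      deamidation_positions = deamidation_positions,
      mass = mass, mz = ion_mz(mass, charge)
    ),
    class = "peptide_ion"
  )
}

#' @export
print.peptide_ion <- function(x, ...) {
  cat(sprintf(
    "<peptide_ion> %s (%s) %d+  mass %.6f Da  m/z %.4f\n",
    x$sequence, x$variant, x$charge, x$mass, x$mz
  ))
  invisible(x)
}

validate_sequence <- function(sequence, allow_empty = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort_invalid("'sequence' must be a single character string")
  }
  if (!allow_empty && !nzchar(sequence)) abort_invalid("'sequence' must be non-empty")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- which(!res %in% names(AA_MONO_MASS))
  if (length(unknown)) {
    abort_invalid(sprintf(
      "unknown residue '%s' at position %d in '%s'",
      res[unknown[1]], unknown[1], sequence
    ))
  }
  invisible(sequence)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of standard monoisotopic residue masses plus one water (18.010565 Da).
#' The empty string returns the mass of water.
#'
#' @param sequence Peptide string of standard one-letter residue codes.
#' @return Monoisotopic mass in Dalton.
#' @examples
#' monoisotopic_mass("DQLSLGNAALQITDVK") # 1684.8995
#' @export
monoisotopic_mass <- function(sequence) {
  validate_sequence(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(AA_MONO_MASS[res]) + WATER_MASS
}

#' m/z of a protonated ion
#'
#' @param mass Neutral monoisotopic mass in Dalton (> 0).
#' @param charge Positive integer charge state.
#' @return (mass + charge * 1.00727646) / charge. Full precision; round only
#'   for display (reports print 4 decimals).
#' @examples
#' ion_mz(1684.8995, 2) # 843.4570
#' @export
ion_mz <- function(mass, charge) {
  check_number(mass, "mass", lower = .Machine$double.xmin)
  if (!is.numeric(charge) || anyNA(charge) || any(charge < 1) ||
      any(charge != as.integer(charge))) {
    abort_invalid("'charge' must be a positive integer")
  }
  (mass + charge * PROTON_MASS) / charge
}

#' Deamidate an asparagine of a peptide ion
#'
#' Models the PNGase F conversion of a glycan-occupied Asn (N) to Asp (D),
#' shifting the monoisotopic mass by exactly +0.984016 Da per site.
#'
#' @param ion A [peptide_ion()] whose native sequence has N at `position`.
#' @param position 1-based residue index to convert.
#' @return A new `peptide_ion` of variant `"deamidated"` with D at `position`.
#' @export
apply_deamidation <- function(ion, position) {
  if (!inherits(ion, "peptide_ion")) abort_invalid("'ion' must be a peptide_ion")
  position <- as.integer(position)
  res <- strsplit(ion$sequence, "", fixed = TRUE)[[1]]
  if (position < 1L || position > length(res)) {
    abort_invalid(sprintf("position %d outside sequence", position))
  }
  if (res[position] != "N") {
    abort_invalid(sprintf(
      "residue at position %d is '%s', not N; cannot deamidate",
      position, res[position]
    ))
  }
  if (position %in% ion$deamidation_positions) {
    abort_invalid(sprintf("position %d already deamidated", position))
  }
  new_seq <- ion$sequence # native sequence retained; D substitution derived below
  out <- peptide_ion(
    new_seq, ion$charge, "deamidated",
    deamidation_positions = sort(c(ion$deamidation_positions, position))
  )
  out
}

#' Observed sequence of a peptide ion (with N -> D substitutions applied)
#'
#' @param ion A [peptide_ion()].
#' @return The sequence string with D at every deamidation position.
#' @export
observed_sequence <- function(ion) {
  if (!inherits(ion, "peptide_ion")) abort_invalid("'ion' must be a peptide_ion")
  res <- strsplit(ion$sequence, "", fixed = TRUE)[[1]]
  res[ion$deamidation_positions] <- "D"
  paste(res, collapse = "")
}
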