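# Monoisotopic residue masses (Da) for the 20 proteinogenic amino acids,
# and the constants needed to turn a peptide sequence into an m/z value.

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) of amino-acid *residues*
#' (i.e. already minus one water), standard 20-letter alphabet.
#'
#' @format Named numeric vector of length 20.
#' @export
RESIDUE_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.0105646863
MASS_PROTON <- 1.0072764666

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of a peptide: sum of residue masses plus one
#' water. Unknown residue letters are an error (the offending letters are
#' named), so typos and ambiguity codes (B, Z, X) are caught early.
#'
#' @param peptide Character vector of peptide sequences (uppercase one-letter
#'   codes).
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' peptide_mass("PEPTIDE") # 799.36
#' @export
peptide_mass <- function(peptide) {
  stopifnot(is.character(peptide))
  chars <- strsplit(peptide, "", fixed = TRUE)
  bad <- unique(unlist(lapply(chars, setdiff, y = names(RESIDUE_MONO_MASS))))
  if (length(bad) > 0) {
    abort(paste0(
      "unknown residue letter(s): ", paste(bad, collapse = ", ")
    ), class = "diauxielfq_residue_error")
  }
  vapply(chars, function(ch) sum(RESIDUE_MONO_MASS[ch]) + MASS_WATER,
         numeric(1))
}

#' Theoretical m/z of a peptide ion
#'
#' @param peptide Character vector of sequences.
#' @param charge Integer charge state(s), recycled.
#' @return m/z in Thomson.
#' @export
peptide_mz <- function(peptide, charge = 2L) {
  if (any(charge < 1)) abort("charge must be a positive integer")
  (peptide_mass(peptide) + charge * MASS_PROTON) / charge
}
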