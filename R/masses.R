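# Monoisotopic constants used throughout. All masses in Daltons.

#: Standard monoisotopic residue masses for the 20 amino acids.
AA_MONO <- c(
  G = 57.02146373, A = 71.03711381, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

PROTON_MASS <- 1.00727646688
WATER_MASS  <- 18.0105646863
NH3_MASS    <- 17.02654910

# Residues whose monoisotopic mass is undefined or ambiguous; peptides
# containing them are skipped during index construction rather than erroring.
AMBIGUOUS_RESIDUES <- c("B", "J", "O", "U", "X", "Z")

#' Neutral monoisotopic mass of a precursor ion
#'
#' Converts an observed precursor m/z and charge state to the neutral
#' (uncharged) monoisotopic mass: `(precursor_mz - m_proton) * charge`.
#'
#' @param precursor_mz Precursor mass-to-charge ratio in Thomson.
#' @param charge Positive integer charge state.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' neutral_mass(500.0, 2)
#' @export
neutral_mass <- function(precursor_mz, charge) {
  if (any(charge <= 0) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer")
  if (any(precursor_mz <= PROTON_MASS))
    stop("precursor_mz must exceed the proton mass")
  (precursor_mz - PROTON_MASS) * charge
}

# Per-residue monoisotopic masses for a peptide string, with any localized
# modification deltas added at their positions (1-based).
residue_masses <- function(sequence, mod_pos = integer(0), mod_delta = numeric(0)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty peptide sequence")
  m <- unname(AA_MONO[chars])
  if (anyNA(m))
    stop("unknown residue(s) in peptide: ",
         paste(unique(chars[is.na(m)]), collapse = ", "))
  if (length(mod_pos)) {
    if (any(mod_pos < 1L) || any(mod_pos > length(chars)))
      stop("modification position out of range")
    for (i in seq_along(mod_pos))
      m[mod_pos[i]] <- m[mod_pos[i]] + mod_delta[i]
  }
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of standard monoisotopic residue masses plus one water, plus any
#' modification deltas.
#'
#' @param sequence Peptide string over the 20 standard amino acids.
#' @param mod_pos Integer vector of modified positions (1-based).
#' @param mod_delta Numeric vector of mass deltas (Da), parallel to `mod_pos`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")
#' @export
peptide_mass <- function(sequence, mod_pos = integer(0), mod_delta = numeric(0)) {
  sum(residue_masses(sequence, mod_pos, mod_delta)) + WATER_MASS
}
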