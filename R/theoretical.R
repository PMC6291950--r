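# Theoretical fragment spectra for candidate peptides: b/y ion series on
# the fragment bin grid, with optional flanking peaks (low-resolution mode)
# and NH3/H2O neutral-loss peaks.

#' Fragment ion m/z values for one series
#'
#' `b_k = (sum of the first k residue+mod masses + z * m_proton) / z`;
#' `y_k = (sum of the last k residue+mod masses + water + z * m_proton) / z`;
#' k runs 1..length-1. A modification at position p contributes to every
#' fragment containing p.
#'
#' @param sequence Peptide residue string.
#' @param series `"b"` or `"y"`.
#' @param fragment_charge Positive integer fragment charge.
#' @param mod_pos,mod_delta Localized modifications (1-based positions).
#' @return Numeric vector of fragment m/z in Thomson, k = 1..length-1.
#' @export
fragment_mz <- function(sequence, series = c("b", "y"), fragment_charge = 1L,
                        mod_pos = integer(0), mod_delta = numeric(0)) {
  series <- match.arg(series)
  z <- as.integer(fragment_charge)
  if (z < 1L) stop("fragment_charge must be >= 1")
  m <- residue_masses(sequence, mod_pos, mod_delta)
  n <- length(m)
  if (n < 2L) return(numeric(0))
  if (series == "b") {
    neutral <- cumsum(m)[1:(n - 1L)]
    (neutral + z * PROTON_MASS) / z
  } else {
    neutral <- cumsum(rev(m))[1:(n - 1L)] + WATER_MASS
    (neutral + z * PROTON_MASS) / z
  }
}

# Fragment charges considered for a given precursor charge: singly charged
# fragments for precursor 1-2+, and 1..(z-1) for z >= 3.
fragment_charges <- function(precursor_charge) {
  if (precursor_charge <= 2L) 1L else seq_len(precursor_charge - 1L)
}

#' Build the theoretical spectrum of a candidate peptide
#'
#' b and y ions at fragment charges given by the precursor charge are
#' placed on the bin grid with weight 1.0; when flanking is on the bins
#' directly adjacent to each primary bin receive weight 0.5, and when
#' neutral losses are on the NH3 and H2O loss bins receive weight 0.2.
#' Same-bin collisions keep the maximum weight. Flanking defaults on for
#' bin widths of 0.5 Th and above (the low-resolution regime) and off for
#' narrow high-resolution bins.
#'
#' @param peptide A form as produced by [enumerate_modified_forms()]
#'   (`list(sequence, mod_pos, mod_delta, ...)`), or a plain sequence
#'   string.
#' @param precursor_charge Positive integer precursor charge.
#' @param params A [bin_params()].
#' @param use_flanking Logical or `NULL` (auto by bin width).
#' @param use_neutral_losses Logical, default `FALSE`.
#' @return A `"theoretical_spectrum"`: list with strictly increasing
#'   0-based `bins`, positive `weights`, and `peptide_ref`.
#' @export
build_theoretical <- function(peptide, precursor_charge = 2L,
                              params = bin_params(),
                              use_flanking = NULL,
                              use_neutral_losses = FALSE) {
  if (is.character(peptide))
    peptide <- list(sequence = peptide, mod_pos = integer(0),
                    mod_delta = numeric(0))
  if (precursor_charge < 1L) stop("precursor_charge must be >= 1")
  if (is.null(use_flanking)) use_flanking <- params$bin_width >= 0.5
  bins <- integer(0); weights <- numeric(0)
  add <- function(b, w) {
    keep <- b >= 0L
    bins <<- c(bins, b[keep]); weights <<- c(weights, rep(w, sum(keep)))
  }
  for (z in fragment_charges(precursor_charge)) {
    for (series in c("b", "y")) {
      mz <- fragment_mz(peptide$sequence, series, z,
                        peptide$mod_pos, peptide$mod_delta)
      if (!length(mz)) next
      primary <- bin_index(mz, params)
      add(primary, 1.0)
      if (isTRUE(use_flanking)) {
        add(primary - 1L, 0.5)
        add(primary + 1L, 0.5)
      }
      if (isTRUE(use_neutral_losses)) {
        add(bin_index(mz - NH3_MASS / z, params), 0.2)
        add(bin_index(mz - WATER_MASS / z, params), 0.2)
      }
    }
  }
  if (length(bins)) {
    o <- order(bins, -weights)
    bins <- bins[o]; weights <- weights[o]
    keep <- !duplicated(bins)
    bins <- bins[keep]; weights <- weights[keep]
  }
  structure(list(bins = bins, weights = weights,
                 peptide_ref = paste0(peptide$sequence, "/",
                                      serialize_mods(peptide$mod_pos,
                                                     peptide$mod_delta))),
            class = "theoretical_spectrum")
}

#' Theoretical spectra for a batch of candidates
#'
#' Candidates are independent and peaks within a candidate are independent,
#' so the batch contract is simply element-wise equality with
#' [build_theoretical()]; the evaluation order is unspecified.
#'
#' @param candidates List of peptide forms (or rows of a
#'   `"peptide_index"`, passed as a data frame).
#' @param precursor_charge,params,use_flanking,use_neutral_losses As in
#'   [build_theoretical()].
#' @return List of `"theoretical_spectrum"` objects, parallel to
#'   `candidates`.
#' @export
batch_theoretical <- function(candidates, precursor_charge = 2L,
                              params = bin_params(),
                              use_flanking = NULL,
                              use_neutral_losses = FALSE) {
  if (is.data.frame(candidates))
    candidates <- lapply(seq_len(nrow(candidates)), function(i)
      list(sequence = candidates$sequence[i],
           mod_pos = candidates$mod_pos[[i]],
           mod_delta = candidates$mod_delta[[i]]))
  if (!length(candidates)) stop("batch_theoretical requires candidates")
  lapply(candidates, build_theoretical,
         precursor_charge = precursor_charge, params = params,
         use_flanking = use_flanking,
         use_neutral_losses = use_neutral_losses)
}
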