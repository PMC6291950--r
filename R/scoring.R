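# XCorr scoring: the dot product of a preprocessed experimental spectrum
# with a theoretical fragment spectrum, a slow explicit-correlation
# reference oracle, and per-spectrum candidate scoring with deterministic
# ranking.

#' XCorr score of one peptide against a preprocessed spectrum
#'
#' `score = scale * sum over theoretical entries of weight *
#' preprocessed[bin]`. Theoretical bins at or beyond `n_bins` contribute 0
#' rather than erroring, so candidates heavier than the observed fragment
#' range are scoreable in open search.
#'
#' @param preprocessed A `"preprocessed_dense"`.
#' @param theoretical A `"theoretical_spectrum"`.
#' @param scale Score scale (default 0.005, giving the familiar
#'   SEQUEST-range magnitudes with unit primary weights and regional
#'   normalization target 50).
#' @return A single numeric score.
#' @export
xcorr <- function(preprocessed, theoretical, scale = 0.005) {
  keep <- theoretical$bins < preprocessed$n_bins
  if (!any(keep)) return(0)
  scale * sum(theoretical$weights[keep] *
                preprocessed$values[theoretical$bins[keep] + 1L])
}

#' Reference XCorr by explicit offset correlation
#'
#' Computes all `2F + 1` shifted correlations of the theoretical spectrum
#' against the *normalized* (untransformed) spectrum and returns
#' `scale * (R_0 - mean over tau != 0 of R_tau)` with divisor `2F`. This is
#' O(n * F) work and exists purely as an independent check of the fast
#' transform-then-dot-product path, with which it agrees algebraically.
#'
#' @param normalized A `"binned_spectrum"` (after [region_normalize()]).
#' @param theoretical A `"theoretical_spectrum"`.
#' @param flank_radius Background half-width F in bins.
#' @param scale Score scale as in [xcorr()].
#' @return A single numeric score.
#' @export
xcorr_reference_oracle <- function(normalized, theoretical,
                                   flank_radius = 75L, scale = 0.005) {
  F <- as.integer(flank_radius)
  y <- normalized$values
  n <- length(y)
  bins <- theoretical$bins
  w <- theoretical$weights
  keep <- bins < n
  bins <- bins[keep]; w <- w[keep]
  if (!length(bins)) return(0)
  r_tau <- function(tau) {
    idx <- bins + 1L + tau
    ok <- idx >= 1L & idx <= n
    sum(w[ok] * y[idx[ok]])
  }
  r0 <- r_tau(0L)
  background <- sum(vapply(c(-(F:1), 1:F), r_tau, 0))
  scale * (r0 - background / (2 * F))
}

#' Choose a scoring backend
#'
#' `"auto"` picks the sparse path when the dense grid is large relative to
#' the work of the sparse one — `n_bins > 20 * (2F + 1 + P_e)` — which is
#' the regime of high-resolution (narrow-bin) spectra; otherwise dense.
#'
#' @param name `"dense"`, `"sparse"` or `"auto"`.
#' @param n_bins Dense grid size (needed for `"auto"`).
#' @param p_e Experimental peak count after binning (needed for `"auto"`).
#' @param flank_radius Background half-width in bins.
#' @return `"dense"` or `"sparse"`.
#' @export
select_backend <- function(name = c("auto", "dense", "sparse"),
                           n_bins = NULL, p_e = NULL, flank_radius = 75L) {
  name <- match.arg(name)
  if (name != "auto") return(name)
  if (is.null(n_bins) || is.null(p_e))
    stop("auto backend selection needs n_bins and p_e")
  if (n_bins > 20 * (2 * flank_radius + 1 + p_e)) "sparse" else "dense"
}

#' Score all candidates against one spectrum
#'
#' Preprocesses the spectrum once, builds each candidate's theoretical
#' spectrum, and returns the top-N peptide-spectrum matches ranked by
#' XCorr. Ties are broken by smaller absolute delta mass, then
#' lexicographic sequence, then serialized mods — deterministic across
#' backends and platforms.
#'
#' @param spec A [spectrum()].
#' @param candidates Rows of a `"peptide_index"` (as from
#'   [extract_candidates()]).
#' @param config A [search_config()] (paths may be `NULL` here).
#' @return Data frame of PSMs with columns `scan_id`, `charge`,
#'   `precursor_mz`, `spectrum_neutral_mass`, `peptide_neutral_mass`,
#'   `delta_mass`, `xcorr`, `rank`, `sequence`, `mods`, `proteins`, plus a
#'   `"counters"` attribute (`candidates_scored`,
#'   `theoretical_peaks_scored`, `n_bins_processed`,
#'   `breakpoint_updates`).
#' @export
score_candidates <- function(spec, candidates, config = search_config()) {
  params <- bin_params(config$bin_width, config$bin_offset)
  spec_mass <- neutral_mass(spec$precursor_mz, spec$precursor_charge)
  counters <- list(candidates_scored = nrow(candidates),
                   theoretical_peaks_scored = 0L,
                   n_bins_processed = 0L, breakpoint_updates = 0L)
  empty <- data.frame(scan_id = character(0), charge = integer(0),
                      precursor_mz = numeric(0),
                      spectrum_neutral_mass = numeric(0),
                      peptide_neutral_mass = numeric(0),
                      delta_mass = numeric(0), xcorr = numeric(0),
                      rank = integer(0), sequence = character(0),
                      mods = character(0), proteins = character(0))
  if (!nrow(candidates)) {
    attr(empty, "counters") <- counters
    return(empty)
  }
  binned <- bin_peaks(spec, params, config$remove_precursor_tolerance,
                      config$flank_radius)
  backend <- select_backend(config$backend, n_bins = binned$n_bins,
                            p_e = length(binned$peak_bins),
                            flank_radius = config$flank_radius)
  pre <- preprocess_spectrum(
    spec, params, config$flank_radius, backend,
    config$n_regions, config$region_target, config$min_relative_intensity,
    config$remove_precursor_tolerance)
  counters$n_bins_processed <- pre$n_bins
  bu <- attr(pre, "breakpoint_updates")
  if (!is.null(bu)) counters$breakpoint_updates <- bu
  theo <- batch_theoretical(candidates, spec$precursor_charge, params,
                            config$use_flanking, config$use_neutral_losses)
  counters$theoretical_peaks_scored <-
    sum(vapply(theo, function(t) length(t$bins), 0L))
  scores <- vapply(theo, function(t) xcorr(pre, t, config$scale), 0)
  delta <- spec_mass - candidates$neutral_mass
  o <- order(-scores, abs(delta), candidates$sequence, candidates$mods)
  top <- utils::head(o, config$top_n)
  psms <- data.frame(
    scan_id = spec$scan_id,
    charge = spec$precursor_charge,
    precursor_mz = spec$precursor_mz,
    spectrum_neutral_mass = spec_mass,
    peptide_neutral_mass = candidates$neutral_mass[top],
    delta_mass = delta[top],
    xcorr = scores[top],
    rank = seq_along(top),
    sequence = candidates$sequence[top],
    mods = candidates$mods[top],
    proteins = vapply(candidates$proteins[top], paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  attr(psms, "counters") <- counters
  psms
}
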