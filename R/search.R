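# Search orchestration: configuration, the end-to-end search loop, and the
# candidate-count profile. Results tables are fully deterministic — scores
# are rounded before formatting, ordering is fixed by scan order then rank,
# and no wall-clock values enter the output (timings and counters go to
# the log / run summary only).

#' Search configuration
#'
#' Flat configuration shared by [run_search()], [score_candidates()] and
#' [run_candidate_profile()]. The defaults are the low-resolution profile
#' (1.0005079 Th bins, offset 0.40); pass `bin_width = 0.02,
#' bin_offset = 0` for high-resolution spectra.
#'
#' @param fasta_path,spectra_path Input files (FASTA proteome, spectra).
#' @param precursor_tolerance Precursor window half-width (> 0).
#' @param precursor_tolerance_unit `"Da"` or `"ppm"`.
#' @param bin_width,bin_offset Fragment bin grid (see [bin_params()]).
#' @param flank_radius Background half-width in bins (default 75).
#' @param n_regions,region_target,min_relative_intensity Normalization
#'   parameters (see [region_normalize()]).
#' @param remove_precursor_tolerance Precursor removal half-width in Th.
#' @param missed_cleavages,ntt,min_length,max_length Digestion parameters.
#' @param mods,static_mods Modification spec strings (see [mod_spec()]).
#' @param top_n PSMs reported per spectrum.
#' @param backend `"dense"`, `"sparse"` or `"auto"`.
#' @param workers Parallel workers for the per-spectrum loop (spectra are
#'   independent units of work; scheduling never changes the output).
#' @param output_path Results TSV path, or `NULL` to skip writing.
#' @param seed Seed for any sampling (the search itself is deterministic).
#' @param use_flanking Logical or `NULL` (auto by bin width).
#' @param use_neutral_losses Logical.
#' @param scale XCorr score scale.
#' @return An object of class `"search_config"`.
#' @export
search_config <- function(fasta_path = NULL, spectra_path = NULL,
                          precursor_tolerance = 3,
                          precursor_tolerance_unit = c("Da", "ppm"),
                          bin_width = 1.0005079, bin_offset = 0.40,
                          flank_radius = 75L, n_regions = 10L,
                          region_target = 50, min_relative_intensity = 0.05,
                          remove_precursor_tolerance = 1.5,
                          missed_cleavages = 2L, ntt = 2L,
                          min_length = 6L, max_length = 50L,
                          mods = "", static_mods = "",
                          top_n = 5L, backend = c("auto", "dense", "sparse"),
                          workers = 1L, output_path = NULL, seed = 1L,
                          use_flanking = NULL, use_neutral_losses = FALSE,
                          scale = 0.005) {
  if (precursor_tolerance <= 0) stop("precursor_tolerance must be positive")
  if (top_n < 1L) stop("top_n must be >= 1")
  if (workers < 1L) stop("workers must be >= 1")
  structure(list(
    fasta_path = fasta_path, spectra_path = spectra_path,
    precursor_tolerance = precursor_tolerance,
    precursor_tolerance_unit = match.arg(precursor_tolerance_unit),
    bin_width = bin_width, bin_offset = bin_offset,
    flank_radius = as.integer(flank_radius),
    n_regions = as.integer(n_regions), region_target = region_target,
    min_relative_intensity = min_relative_intensity,
    remove_precursor_tolerance = remove_precursor_tolerance,
    missed_cleavages = as.integer(missed_cleavages), ntt = as.integer(ntt),
    min_length = as.integer(min_length), max_length = as.integer(max_length),
    mods = mods, static_mods = static_mods,
    top_n = as.integer(top_n), backend = match.arg(backend),
    workers = as.integer(workers), output_path = output_path,
    seed = as.integer(seed), use_flanking = use_flanking,
    use_neutral_losses = use_neutral_losses, scale = scale
  ), class = "search_config")
}

#' Read a flat key=value configuration file
#'
#' Keys mirror the arguments of [search_config()]; values given on top of
#' the file (e.g. from CLI flags) override it.
#'
#' @param path Path to the config file.
#' @param overrides Named list of values taking precedence.
#' @return A [search_config()].
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), "")
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- c("precursor_tolerance", "bin_width", "bin_offset",
                    "flank_radius", "n_regions", "region_target",
                    "min_relative_intensity", "remove_precursor_tolerance",
                    "missed_cleavages", "ntt", "min_length", "max_length",
                    "top_n", "workers", "seed", "scale")
  logical_keys <- c("use_flanking", "use_neutral_losses")
  for (k in intersect(names(args), numeric_keys))
    args[[k]] <- as.numeric(args[[k]])
  for (k in intersect(names(args), logical_keys))
    args[[k]] <- as.logical(args[[k]])
  args[names(overrides)] <- overrides
  unknown <- setdiff(names(args), names(formals(search_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(search_config, args)
}

psm_table_header <- c("scan_id", "charge", "precursor_mz",
                      "spectrum_neutral_mass", "peptide_neutral_mass",
                      "delta_mass", "xcorr", "rank", "sequence", "mods",
                      "proteins")

# Deterministic text formatting of a PSM table. xcorr is rounded to 1e-4
# before formatting so the dense and sparse backends (which agree to far
# better than that) print byte-identical files.
format_psm_table <- function(psms) {
  if (!nrow(psms)) return(paste(psm_table_header, collapse = "\t"))
  rows <- sprintf("%s\t%d\t%.6f\t%.6f\t%.6f\t%.6f\t%.4f\t%d\t%s\t%s\t%s",
                  psms$scan_id, psms$charge, psms$precursor_mz,
                  psms$spectrum_neutral_mass, psms$peptide_neutral_mass,
                  psms$delta_mass, round(psms$xcorr, 4L), psms$rank,
                  psms$sequence, psms$mods, psms$proteins)
  paste(c(paste(psm_table_header, collapse = "\t"), rows), collapse = "\n")
}

#' Run a database search
#'
#' The full pipeline: read the proteome, build the peptide index once, and
#' for each spectrum extract candidates in the precursor window, build
#' their theoretical spectra, and score by XCorr, reporting the top-N PSMs
#' per spectrum. Output is a TSV sorted by (scan order, rank) and is
#' identical across worker counts and backend choices.
#'
#' @param config A [search_config()] with `fasta_path` and `spectra_path`
#'   set. An `index` may be passed to reuse a prebuilt one.
#' @param index Optional prebuilt `"peptide_index"`.
#' @param spectra Optional list of [spectrum()] objects (otherwise read
#'   from `config$spectra_path`).
#' @return List with `results` (PSM data frame), `summary` (named counters:
#'   spectra searched, candidates scored, theoretical peaks scored, bins
#'   processed, breakpoint updates), and `output_path`.
#' @export
run_search <- function(config, index = NULL, spectra = NULL) {
  if (is.null(index)) {
    proteins <- read_fasta(config$fasta_path)
    index <- build_index(
      proteins,
      digest_params(max_missed_cleavages = config$missed_cleavages,
                    ntt = config$ntt, min_length = config$min_length,
                    max_length = config$max_length),
      mod_spec(config$mods, config$static_mods))
  }
  if (!nrow(index)) stop("peptide index is empty; nothing to search")
  if (is.null(spectra)) spectra <- read_spectra(config$spectra_path)
  if (!length(spectra)) {
    warning("no spectra to search; writing empty results")
    if (!is.null(config$output_path))
      writeLines(paste(psm_table_header, collapse = "\t"), config$output_path)
    empty <- utils::read.table(text = paste(psm_table_header, collapse = "\t"),
                               header = TRUE, sep = "\t")
    return(list(results = empty,
                summary = c(spectra_searched = 0, candidates_scored = 0,
                            theoretical_peaks_scored = 0,
                            n_bins_processed = 0, breakpoint_updates = 0),
                output_path = config$output_path))
  }
  search_one <- function(s) {
    m <- neutral_mass(s$precursor_mz, s$precursor_charge)
    cands <- extract_candidates(index, m, config$precursor_tolerance,
                                config$precursor_tolerance_unit)
    score_candidates(s, cands, config)
  }
  per_spectrum <- if (config$workers > 1L) {
    parallel::mclapply(spectra, search_one, mc.cores = config$workers)
  } else {
    lapply(spectra, search_one)
  }
  counters <- c(spectra_searched = length(spectra),
                candidates_scored = 0, theoretical_peaks_scored = 0,
                n_bins_processed = 0, breakpoint_updates = 0)
  for (r in per_spectrum) {
    ct <- attr(r, "counters")
    counters["candidates_scored"] <-
      counters["candidates_scored"] + ct$candidates_scored
    counters["theoretical_peaks_scored"] <-
      counters["theoretical_peaks_scored"] + ct$theoretical_peaks_scored
    counters["n_bins_processed"] <-
      counters["n_bins_processed"] + ct$n_bins_processed
    counters["breakpoint_updates"] <-
      counters["breakpoint_updates"] + ct$breakpoint_updates
  }
  results <- do.call(rbind, per_spectrum)
  rownames(results) <- NULL
  if (!is.null(config$output_path))
    writeLines(format_psm_table(results), config$output_path)
  list(results = results, summary = counters,
       output_path = config$output_path)
}

#' Candidate-count profile over precursor tolerances
#'
#' Builds the index once and reports, for each tolerance, the mean number
#' of candidate peptides per spectrum — the trend that widening the
#' precursor window (up to an open search) inflates the candidate load.
#'
#' @param config A [search_config()].
#' @param tolerances Numeric vector of precursor window half-widths (Da).
#' @param output_path Optional TSV output path.
#' @param index,spectra Optional prebuilt inputs, as in [run_search()].
#' @return Data frame with columns `tolerance`, `mean_candidates`.
#' @export
run_candidate_profile <- function(config, tolerances, output_path = NULL,
                                  index = NULL, spectra = NULL) {
  if (is.null(index)) {
    proteins <- read_fasta(config$fasta_path)
    index <- build_index(
      proteins,
      digest_params(max_missed_cleavages = config$missed_cleavages,
                    ntt = config$ntt, min_length = config$min_length,
                    max_length = config$max_length),
      mod_spec(config$mods, config$static_mods))
  }
  if (!nrow(index)) stop("peptide index is empty; nothing to profile")
  if (is.null(spectra)) spectra <- read_spectra(config$spectra_path)
  rep <- candidate_report(index, spectra, tolerances)
  if (!is.null(output_path)) {
    writeLines(paste(c("tolerance\tmean_candidates",
                       sprintf("%g\t%.6f", rep$tolerance,
                               rep$mean_candidates)), collapse = "\n"),
               output_path)
  }
  rep
}
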