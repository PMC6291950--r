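# Synthetic proteomes and spectra with known ground truth. These fixtures
# emulate HCD/CID b/y fragmentation at a controllable noise level so that
# every stage of the engine — and the end-to-end search — is testable
# without any external data.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a random synthetic proteome
#'
#' Residues are drawn i.i.d. from the 20-letter alphabet (uniform by
#' default), which yields tryptic peptides at a realistic density since
#' K/R together make up a tenth of positions.
#'
#' @param n_proteins Number of proteins.
#' @param length_min,length_max Protein length bounds (residues).
#' @param seed Integer seed; the same seed reproduces the same proteome.
#' @param composition Optional named probability vector over the 20
#'   residues.
#' @param fasta_path Optional path to also write the proteome as FASTA.
#' @return Data frame with `accession`, `sequence`.
#' @export
generate_proteome <- function(n_proteins = 25L, length_min = 30L,
                              length_max = 60L, seed = 1L,
                              composition = NULL, fasta_path = NULL) {
  stopifnot(n_proteins >= 1L, length_min >= 1L, length_max >= length_min)
  alphabet <- names(AA_MONO)[!duplicated(names(AA_MONO))]
  prob <- if (is.null(composition)) NULL else composition[alphabet]
  proteins <- with_seed(seed, {
    lens <- sample(length_min:length_max, n_proteins, replace = TRUE)
    data.frame(
      accession = sprintf("SYN|P%03d", seq_len(n_proteins)),
      sequence = vapply(lens, function(L)
        paste(sample(alphabet, L, replace = TRUE, prob = prob),
              collapse = ""), "")
    )
  })
  if (!is.null(fasta_path)) write_fasta(proteins, fasta_path)
  proteins
}

#' Generate a synthetic MS/MS spectrum from a known peptide
#'
#' Places peaks at every b/y fragment m/z (fragment charges as in the
#' scoring model), with i.i.d. uniform intensities, optional Gaussian m/z
#' jitter, and optional uniform-random noise peaks. The precursor m/z is
#' `(neutral_mass + precursor_offset + z * m_proton) / z`; a nonzero
#' `precursor_offset` emulates an unanticipated modification for
#' open-search tests.
#'
#' @param peptide Sequence string or a form list (`sequence`, `mod_pos`,
#'   `mod_delta`).
#' @param charge Precursor charge.
#' @param scan_id Scan identifier.
#' @param noise_peaks Number of uniform-random noise peaks.
#' @param jitter_sd Gaussian m/z jitter standard deviation (Th).
#' @param precursor_offset Mass offset added to the precursor (Da).
#' @param seed Integer seed.
#' @param fragment_intensity,noise_intensity Intensity ranges
#'   (uniform draws).
#' @param noise_mz_range m/z range for noise peaks.
#' @return A [spectrum()].
#' @export
generate_spectrum <- function(peptide, charge = 2L, scan_id = "scan_1",
                              noise_peaks = 0L, jitter_sd = 0,
                              precursor_offset = 0, seed = 1L,
                              fragment_intensity = c(10, 100),
                              noise_intensity = c(1, 10),
                              noise_mz_range = c(100, 2000)) {
  if (is.character(peptide))
    peptide <- list(sequence = peptide, mod_pos = integer(0),
                    mod_delta = numeric(0))
  mass <- peptide_mass(peptide$sequence, peptide$mod_pos, peptide$mod_delta)
  frag <- unlist(lapply(fragment_charges(charge), function(z)
    c(fragment_mz(peptide$sequence, "b", z, peptide$mod_pos,
                  peptide$mod_delta),
      fragment_mz(peptide$sequence, "y", z, peptide$mod_pos,
                  peptide$mod_delta))))
  with_seed(seed, {
    it <- stats::runif(length(frag), fragment_intensity[1],
                       fragment_intensity[2])
    mz <- frag + if (jitter_sd > 0) stats::rnorm(length(frag), 0, jitter_sd)
                 else 0
    if (noise_peaks > 0L) {
      mz <- c(mz, stats::runif(noise_peaks, noise_mz_range[1],
                               noise_mz_range[2]))
      it <- c(it, stats::runif(noise_peaks, noise_intensity[1],
                               noise_intensity[2]))
    }
    pre_mz <- (mass + precursor_offset + charge * PROTON_MASS) / charge
    spectrum(scan_id, pre_mz, charge, mz, it)
  })
}

#' Generate a full synthetic benchmark with ground truth
#'
#' Builds a random proteome, digests it, samples peptides, and writes a
#' FASTA + MGF + ground-truth TSV triple. Every spectrum's generator
#' peptide is guaranteed present in the digest of the written proteome.
#'
#' @param n_spectra Number of spectra.
#' @param out_dir Output directory (created if needed); files
#'   `proteome.fasta`, `spectra.mgf`, `ground_truth.tsv`. Pass `NULL` to
#'   skip writing.
#' @param seed Integer seed driving all randomness.
#' @param n_proteins,length_min,length_max Proteome parameters.
#' @param charge Precursor charge for all spectra.
#' @param noise_peaks,jitter_sd,precursor_offset Spectrum parameters, as
#'   in [generate_spectrum()].
#' @param params Digestion parameters used to pick samplable peptides.
#' @return List with `proteins`, `spectra` (list of [spectrum()]), `truth`
#'   (data frame: `scan_id`, `peptide`, `mods`, `charge`, `mass_offset`,
#'   `noise_peaks`), and the file paths when written.
#' @export
generate_benchmark <- function(n_spectra = 50L, out_dir = NULL, seed = 1L,
                               n_proteins = 25L, length_min = 30L,
                               length_max = 60L, charge = 2L,
                               noise_peaks = 0L, jitter_sd = 0,
                               precursor_offset = 0,
                               params = digest_params()) {
  proteins <- generate_proteome(n_proteins, length_min, length_max,
                                seed = seed)
  peptides <- unique(unlist(lapply(proteins$sequence, function(s)
    digest(s, params)$peptide)))
  peptides <- peptides[!grepl(paste0("[", paste(AMBIGUOUS_RESIDUES,
                                                collapse = ""), "]"),
                              peptides)]
  if (!length(peptides))
    stop("proteome yields no peptides under the digestion parameters")
  chosen <- with_seed(seed + 1L,
                      sample(peptides, n_spectra, replace = TRUE))
  spectra <- lapply(seq_len(n_spectra), function(i)
    generate_spectrum(chosen[i], charge = charge,
                      scan_id = sprintf("synthetic_scan_%04d", i),
                      noise_peaks = noise_peaks, jitter_sd = jitter_sd,
                      precursor_offset = precursor_offset,
                      seed = seed + 1000L + i))
  truth <- data.frame(
    scan_id = vapply(spectra, `[[`, "", "scan_id"),
    peptide = chosen, mods = "",
    charge = as.integer(charge),
    mass_offset = precursor_offset,
    noise_peaks = as.integer(noise_peaks)
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(out_dir, "proteome.fasta"),
                  mgf = file.path(out_dir, "spectra.mgf"),
                  truth = file.path(out_dir, "ground_truth.tsv"))
    write_fasta(proteins, paths$fasta)
    write_spectra(spectra, paths$mgf)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(proteins = proteins, spectra = spectra, truth = truth, paths = paths)
}
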