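# Independent brute-force oracles and fixture generators shared by the
# tests. These deliberately avoid the package's fast paths: the digest
# oracle enumerates all substrings, the transform oracle loops bin by bin.

# Raw random spectrum (not derived from a peptide), for preprocessing
# properties.
random_raw_spectrum <- function(seed, n_peaks = 40, mz_range = c(150, 1800)) {
  set.seed(seed)
  xcorrsearch::spectrum(
    scan_id = paste0("rand_", seed),
    precursor_mz = runif(1, 400, 900),
    precursor_charge = sample(2:3, 1),
    mz = runif(n_peaks, mz_range[1], mz_range[2]),
    intensity = runif(n_peaks, 1, 100)
  )
}

# O(n * F) bin-by-bin evaluation of the XCorr background subtraction.
naive_xcorr_transform <- function(y, F) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - F); hi <- min(n, i + F)
    W <- sum(y[lo:hi])
    y[i] - (W - y[i]) / (2 * F)
  }, 0)
}

# All-substrings digestion oracle: enumerate every substring, classify its
# termini against the cleavage rule, count internal missed cleavages.
brute_force_digest <- function(sequence, max_mc, ntt, min_len, max_len) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  sites <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  out <- character(0)
  for (s in 0:(n - 1)) {
    for (e in (s + 1):n) {
      len <- e - s
      if (len < min_len || len > max_len) next
      start_enz <- s == 0 || s %in% sites
      end_enz <- e == n || e %in% sites
      n_term <- start_enz + end_enz
      internal <- sum(sites > s & sites < e)
      if (internal > max_mc) next
      if (n_term < ntt) next
      out <- c(out, substr(sequence, s + 1, e))
    }
  }
  sort(unique(out))
}

# Closed-form count of modified forms for disjoint-residue variable mods:
# product over mods of sum_{j=0..min(max_occ,k)} choose(k, j).
closed_form_mod_count <- function(peptide, spec) {
  chars <- strsplit(peptide, "")[[1]]
  prod(vapply(spec$variable, function(v) {
    k <- sum(chars %in% v$residues)
    sum(choose(k, 0:min(v$max_occ, k)))
  }, 0))
}

random_peptide <- function(seed, len = NULL) {
  set.seed(seed)
  if (is.null(len)) len <- sample(7:20, 1)
  paste(sample(c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E",
                 "M","H","F","R","Y","W"), len, replace = TRUE),
        collapse = "")
}

random_protein <- function(seed, max_len = 50) {
  set.seed(seed)
  len <- sample(10:max_len, 1)
  paste(sample(c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E",
                 "M","H","F","R","Y","W"), len, replace = TRUE),
        collapse = "")
}
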