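test_that("FASTA reading handles multi-line, case and empty inputs", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|TEST1 first protein", "mkra", "DEK",
               ">P2", "ACDEFGHIK"), path)
  pr <- read_fasta(path)
  expect_identical(pr$accession, c("sp|P1|TEST1", "P2"))
  expect_identical(pr$sequence, c("MKRADEK", "ACDEFGHIK"))

  file.create(path)
  writeLines(character(0), path)
  expect_identical(nrow(read_fasta(path)), 0L)
})

test_that("tryptic digestion matches the worked examples", {
  dp0 <- digest_params(max_missed_cleavages = 0L, ntt = 2L, min_length = 1L)
  expect_setequal(digest("MKRADEK", dp0)$peptide, c("MK", "R", "ADEK"))
  dp1 <- digest_params(max_missed_cleavages = 1L, ntt = 2L, min_length = 1L)
  expect_setequal(digest("MKRADEK", dp1)$peptide,
                  c("MK", "R", "ADEK", "MKR", "RADEK"))
  # K before P does not cleave
  expect_setequal(digest("AKPR", dp0)$peptide, "AKPR")
})

test_that("digestion equals the all-substrings oracle on random proteins", {
  for (seed in 1:50) {
    prot <- random_protein(seed)
    for (mc in 0:2) {
      for (ntt in 1:2) {
        dp <- digest_params(max_missed_cleavages = mc, ntt = ntt,
                            min_length = 2L, max_length = 30L)
        got <- sort(digest(prot, dp)$peptide)
        want <- brute_force_digest(prot, mc, ntt, 2L, 30L)
        expect_identical(got, want,
                         info = sprintf("seed=%d mc=%d ntt=%d", seed, mc, ntt))
      }
    }
  }
})

test_that("modified-form enumeration matches worked examples and closed form", {
  ox2 <- mod_spec("2M+15.994915")
  expect_length(enumerate_modified_forms("AMSMK", ox2), 4L)
  ox1 <- mod_spec("1M+15.994915")
  expect_length(enumerate_modified_forms("AMSMK", ox1), 3L)
  expect_length(enumerate_modified_forms("AMSMK", mod_spec()), 1L)

  # closed-form product of binomial sums on random draws (disjoint residues)
  spec <- mod_spec("2M+15.994915,2NQ+0.984016,1STY+79.966331")
  for (seed in 1:40) {
    pep <- random_peptide(seed)
    expect_identical(length(enumerate_modified_forms(pep, spec)),
                     as.integer(closed_form_mod_count(pep, spec)))
  }
})

test_that("modified forms carry correct masses and at most one variable mod per site", {
  spec <- mod_spec("2M+15.994915", static = "C+57.021464")
  forms <- enumerate_modified_forms("CMAMC", spec)
  expect_length(forms, 4L)
  for (f in forms) {
    expect_equal(f$neutral_mass,
                 peptide_mass(f$sequence, f$mod_pos, f$mod_delta),
                 tolerance = 1e-9)
    expect_identical(anyDuplicated(f$mod_pos), 0L)
    # static carbamidomethyl present on both C residues in every form
    expect_true(all(c(1L, 5L) %in% f$mod_pos))
  }
})

test_that("peptide_mass follows the monoisotopic residue table", {
  expect_equal(peptide_mass("G"), 75.0320, tolerance = 1e-4)
  expect_equal(peptide_mass("PEPTIDE"), 799.3600, tolerance = 1e-4)
  expect_error(peptide_mass(""), "empty")
  expect_error(peptide_mass("PEPTIDEX"), "unknown residue")
  # a localized mod adds exactly its delta
  expect_equal(peptide_mass("PEPTIDE", 2L, 79.966331),
               peptide_mass("PEPTIDE") + 79.966331, tolerance = 1e-9)
})

test_that("index construction deduplicates, sorts and skips ambiguous residues", {
  proteins <- data.frame(
    accession = c("A", "B", "C"),
    sequence = c("MMMKAAADEFGHKRTTTK", "CCCRAAADEFGHK", "XXXBBBK")
  )
  dp <- digest_params(max_missed_cleavages = 0L, ntt = 2L, min_length = 4L)
  expect_warning(idx <- build_index(proteins, dp), "ambiguous")
  # shared peptide appears once with both parents
  shared <- idx[idx$sequence == "AAADEFGHK", ]
  expect_identical(nrow(shared), 1L)
  expect_identical(shared$proteins[[1]], c("A", "B"))
  # sorted by mass, deterministic tie order
  expect_true(!is.unsorted(idx$neutral_mass))
  # every entry's mass matches recomputation
  for (i in seq_len(nrow(idx))) {
    expect_equal(idx$neutral_mass[i],
                 peptide_mass(idx$sequence[i], idx$mod_pos[[i]],
                              idx$mod_delta[[i]]),
                 tolerance = 1e-6)
  }
  # empty proteome
  empty <- build_index(proteins[integer(0), , drop = FALSE], dp)
  expect_identical(nrow(empty), 0L)
})

test_that("candidate extraction is an inclusive binary-searched window", {
  proteins <- generate_proteome(12, 40, 60, seed = 11)
  idx <- build_index(proteins, digest_params(min_length = 6L))
  # hand windows on a small fake index
  fake <- idx[seq_len(min(nrow(idx), 50L)), ]
  fake$neutral_mass <- seq(500, by = 100, length.out = nrow(fake))
  got <- extract_candidates(fake, 600, 50)
  expect_identical(nrow(got), 1L)
  expect_identical(nrow(extract_candidates(fake, 600, 150)), 3L)
  # inclusive bounds at both ends
  expect_identical(nrow(extract_candidates(fake, 600, 100)), 3L)

  # equals linear scan on random queries, Da and ppm
  for (seed in 1:30) {
    set.seed(seed)
    q <- runif(1, 600, 4000)
    tol <- sample(c(0.1, 1, 10, 100, 500), 1)
    got <- extract_candidates(idx, q, tol)
    want <- which(abs(idx$neutral_mass - q) <= tol)
    expect_identical(nrow(got), length(want))
    got_ppm <- extract_candidates(idx, q, 20, unit = "ppm")
    want_ppm <- which(abs(idx$neutral_mass - q) <= q * 20e-6)
    expect_identical(nrow(got_ppm), length(want_ppm))
  }
})

test_that("candidate counts are non-decreasing in tolerance and dedup-stable", {
  proteins <- generate_proteome(10, 40, 60, seed = 3)
  idx <- build_index(proteins, digest_params())
  spectra <- generate_benchmark(8, seed = 3, n_proteins = 10)$spectra
  rep <- candidate_report(idx, spectra, c(0.1, 1, 10, 100))
  expect_true(all(diff(rep$mean_candidates) >= 0))

  # concatenating a renamed copy of the proteome leaves counts unchanged
  doubled <- rbind(proteins,
                   transform(proteins, accession = paste0(accession, "_dup")))
  idx2 <- build_index(doubled, digest_params())
  rep2 <- candidate_report(idx2, spectra, c(0.1, 1, 10, 100))
  expect_equal(rep2$mean_candidates, rep$mean_candidates)
})

test_that("mod spec strings parse per the engine grammar", {
  ms <- mod_spec("2M+15.994915,1STY+79.966331", static = "C+57.021464")
  expect_length(ms$variable, 2L)
  expect_identical(ms$variable[[1]]$residues, "M")
  expect_identical(ms$variable[[1]]$max_occ, 2L)
  expect_identical(ms$variable[[2]]$residues, c("S", "T", "Y"))
  expect_equal(unname(ms$static["C"]), 57.021464)
  expect_error(mod_spec("M+15.99"), "count prefix")
  expect_error(mod_spec("2M~15.99"), "unparsable")
})
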