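Package: xcorrsearch
Title: Open-Modification Peptide-Spectrum Search with Sparse XCorr Preprocessing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tandem mass spectrometry database search engine built around the
    SEQUEST-family cross-correlation (XCorr) score. Implements both the classic
    dense background-subtraction preprocessing transform and a sparse,
    peak-count-proportional transform with an explicit sparse-to-dense mapping
    stage; the two scoring paths are guaranteed to produce identical scores.
    Includes tryptic in-silico digestion with variable modification enumeration,
    a mass-sorted peptide index with narrow-to-open precursor windows,
    theoretical b/y fragment spectrum generation, batched dot-product scoring,
    MGF/MS2 spectrum input and output, and a synthetic benchmark generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    parallel,
    stats,
    utils
Suggests:
    mzR,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
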