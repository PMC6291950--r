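---
title: "The xcorrsearch engine: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The xcorrsearch engine: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcorrsearch)
```

## The scoring model

`xcorrsearch` implements the cross-correlation (XCorr) score of the
SEQUEST/Tide engine family. For each spectrum the pipeline is: bin the
fragment peaks onto a tolerance grid, normalize, background-subtract, and
take dot products with theoretical spectra of candidate peptides drawn
from a mass-sorted index.

**Binning.** `bin index = floor(mz / width + 1 - offset)`, with the
maximum intensity kept when several peaks share a bin, and peaks within
±1.5 Th of the precursor discarded first. The grid realizes the fragment
tolerance: 1.0005079 Th with offset 0.40 is the classic low-resolution
(ion trap CID) setting — the width is the average spacing of peptide
fragment masses, and the offset centers bins on where fragments actually
fall — while 0.02 Th with offset 0 serves high-resolution HCD/Orbitrap
data. The dense grid extends one flank radius past the last retained
peak so the background window is complete everywhere it can be nonzero.

**Normalization.** Intensities are square-root transformed (taming the
dynamic range of detector counts), the occupied bin range is split into
10 equal regions, each region is scaled to a maximum of 50, and values
below 5% of the global maximum are zeroed. Regional rather than global
scaling keeps fragment evidence visible across the m/z range even when
one ion dominates; the scheme and its constants are the dominant
convention in this engine family, and `n_regions` and the target are
configurable.

**The transform.** The background subtraction

$$y'_i = y_i - \frac{1}{2F}\sum_{\tau=-F,\ \tau\neq 0}^{F} y_{i+\tau}$$

with flank radius $F = 75$ bins converts the subsequent dot product into
a correlation-minus-mean-shifted-correlation, which is what makes XCorr
robust to broad background. The center bin is excluded and the divisor is
$2F = 150$; because engines differ on whether the center is included,
both $F$ and the scheme are exposed as configuration rather than
hard-coded. Note that at 0.02 Th bins, $F = 75$ spans ±1.5 Th — the same
window in bin units is a much narrower m/z window at high resolution,
matching established practice.

**Two equivalent paths.** The dense path computes the window sum with a
cumulative-sum sliding window, O(n) in the bin count. The sparse path
observes that $W(i) = \sum_{|\tau| \le F} y_{i+\tau}$ is piecewise
constant, changing only where a peak enters ($p - F$) or leaves
($p + F + 1$) the window: it builds the breakpoint list directly from the
occupied bins, O(P_e log P_e) with P_e the peak count and independent of
n. A mapping stage expands the breakpoints to the full vector; each
output bin is an independent point evaluation, which is exactly the
contract that lets the expansion be vectorized — or, in a GPU
implementation, assigned one bin per thread. The two paths are
algebraically identical; the test suite holds them to 1e-9 per bin and
1e-6 per score, and they agree to machine precision in practice. The
sparse transform also counts its breakpoint updates (2 per peak), the
observable that pins down its complexity class in tests.

**Theoretical spectra.** b and y ions at fragment charge 1 for precursor
charges 1–2 and 1..(z−1) for z ≥ 3, weight 1.0 at the primary bin; with
flanking on (the default at bin widths ≥ 0.5 Th) the ±1 bins get 0.5;
with neutral losses on, NH3/H2O loss bins get 0.2. These are the
SEQUEST 50/25/10 weights rescaled to unit primaries; the score scale of
0.005 (with the normalization target of 50) restores the familiar XCorr
magnitudes, where ~1 separates noise matches and good high-resolution
matches run from ~2 upward. a/c/z ions and fragment isotope envelopes are
deliberately out of scope.

**Scoring and ranking.** `XCorr = scale × Σ weight × y'[bin]`;
theoretical bins beyond the observed grid contribute zero rather than
erroring, so open-search candidates heavier than the spectrum's fragment
range score normally. Ties are broken by smaller |delta mass|, then
lexicographic sequence, then serialized modifications — fully
deterministic across backends, worker counts, and platforms. An explicit
offset-correlation oracle (`xcorr_reference_oracle`, O(nF)) exists purely
to cross-check the fast path in tests.

## The peptide index

Trypsin cleaves after K/R except before P; protein termini count as
enzymatic. Defaults: up to 2 missed cleavages, fully enzymatic termini
(NTT = 2, with semi-enzymatic NTT = 1 available), lengths 6–50. Variable
modifications are enumerated combinatorially (at most one per residue,
per-modification occurrence caps); defaults for the classic set follow
Unimod: oxidation +15.994915 (M), deamidation +0.984016 (N/Q),
phosphorylation +79.966331 (S/T/Y). Peptides containing B/J/O/U/X/Z are
skipped with a warning since their monoisotopic mass is undefined.
Entries are deduplicated globally by (sequence, modification set) with
parent accessions merged, and sorted by neutral mass with a deterministic
tie order, so candidate extraction is an inclusive binary-searched
window. A tolerance in ppm scales with the query mass; a wide Da window
(e.g. ±500 Da) turns the same machinery into an open-modification search
in which the precursor–peptide delta mass is the modification-mass
estimate.

## The synthetic benchmark generator

`generate_benchmark()` emulates the situation the engine is built for:
proteins are i.i.d. uniform over the 20 residues (K+R ≈ 10% of positions,
so tryptic peptide lengths are realistic), spectra carry peaks at every
b/y fragment m/z with i.i.d. uniform intensities in [10, 100], optional
Gaussian m/z jitter, and uniform-random noise peaks with intensities in
[1, 10]; a precursor mass offset emulates an unanticipated modification
for open-search tests. All randomness flows from one seed, so every file
triple is reproducible. What the generator does **not** model — real
fragmentation propensities, isotope envelopes, chimeric spectra,
retention time, charge-state errors — bounds what passing tests show:
they demonstrate the engine's algorithmic correctness (score equivalence,
complexity, recovery of planted ground truth under noise), not
identification performance on biological data, which additionally depends
on decoy-based error control that is out of scope here.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use benchmarks of 25 proteins
(30–60 residues) and 13–50 spectra, searched at tolerances from 0.1 to
500 Da across both bin-width regimes — sizes chosen so the full
property suite (score-path equivalence over >100 searches, 1000
transform-oracle comparisons, 1200 digestion oracle comparisons, three
50-spectrum recovery studies) completes in minutes while still exercising
grids of 10^5–10^6 bins. Floating-point equivalence is asserted at 1e-9
on preprocessed bins and 1e-6 on scores; results files round scores to
1e-4 before formatting so that dense and sparse runs are byte-identical.
Degenerate inputs are contracts, not errors: empty spectra yield all-zero
preprocessed vectors, empty candidate lists yield empty PSM sets, an
empty spectrum file yields a header-only results table with a warning,
and only an empty peptide index aborts a search.

## Known limitations

No decoy generation, FDR estimation, or rescoring features; no secondary
scores (delta-Cn, Sp); no vendor raw formats or profile-mode centroiding;
MGF records lacking a charge are assigned 2+ (flagged in the log) rather
than searched under multiple assumed charges. The sparse path's benefit
is asymptotic — in this R implementation both paths are vectorized and
fast at desk scale, and the value of the sparse representation is the
complexity guarantee verified by its update counter, not wall-clock
speed.
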