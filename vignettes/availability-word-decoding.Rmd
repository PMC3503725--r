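---
title: "Availability scores and word statistics for protein sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Availability scores and word statistics for protein sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsavail)
```

## The model

A protein database is treated as a collection of letter sequences over the
20-letter amino-acid alphabet, and every contiguous k-letter window (a
*short constituent sequence*, SCS; k = 1..6 by default) is a candidate
"word". Two corpus-level numbers summarize the material: `T`, the total
number of letters, and `t`, the total number of k-windows
(`t = sum over segments of max(0, len - k + 1)`).

The *availability* of a word w is the ratio

  A(w) = R(w) / E(w),

where R is the observed window count and E is the count expected if the
database's letters were arranged uniformly at random. E is computed under a
*without-replacement* model: writing the word as a_0 .. a_{m-1}, with n_k
the database count of letter a_k and x_k the multiplicity of a_k among the
word's preceding letters,

  E = t * prod_{k=0}^{m-1} (n_k - x_k) / (T - k).

Each factor is the probability that the next position of a random
arrangement supplies the required letter, given that the word has already
consumed x_k copies of it and k letters of the database overall. This is
exactly the expected window count under uniform random permutation of the
letter multiset, which is why a Monte-Carlo shuffle of the database is the
package's acceptance oracle for E (`tests/testthat/test-acceptance.R`). The
with-replacement simplification `E = t * prod n_k / T` is available as
`model = "simple"`; the two converge as T grows at fixed letter
frequencies. Summed over *all* m-letter words, E equals t exactly — the
model is a proper probability distribution over words times t — and the
test suite verifies this by brute-force enumeration on small alphabets.

Words that the database cannot supply (a letter absent, or more copies
needed than exist) have no defined ratio and are reported as
unscorable (`NA`), never as 0; words that simply never occur have A = 0.

Why a ratio and not the difference R − E? The working thresholds
("A ≥ 3", "A ≥ 5") and typical motif/background medians near 1 are only
dimensionally coherent for a ratio; a difference would scale with database
size. The difference variant remains available behind
`method = "difference"` for sensitivity checks.

## Sanitization and coordinates

Residues outside the declared alphabet (X, U, B, Z, J, O, ...) terminate
the current segment; analysis resumes at the next standard residue, and the
offending letters are counted in neither T nor t, so both numbers describe
the same analyzed material. All coordinates are 1-based and inclusive.
Segments remember their offset on the original record, so profile windows
and motif intervals share the record coordinate system regardless of how
many splits sanitization introduced.

## Availability profiles

`availability_profile()` assigns each window of a query its database
availability and rescales within the query: the largest score becomes the
*relative availability* rA = 100%, the rest proportionally. Unscorable
windows are excluded from the normalization (an all-zero profile has rA = 0
everywhere). Relative, not absolute, scores are what make peaks comparable
across proteins of very different composition.

## Rank-frequency diagnostics

`rank_frequency()` orders words by descending count (ties broken
lexicographically so ranking is deterministic) and works in base-10 logs
throughout, because linear widths are conventionally quoted in decades.
`fit_loglog()` is ordinary least squares of log10(count) on log10(rank)
over all ranks — deliberately no xmin search, mirroring the
whole-distribution regression the availability literature uses — reporting
the exponent b (minus the slope), the coefficient a = 10^intercept and the
correlation magnitude r.

`linear_range()` draws two bounding lines with slopes -(b ± band)
(band = 0.15 by default, the conventional half-width) through the best-fit
line at the centroid of the fitted points, and reports the longest
contiguous run of ranks between them, with widths on both axes.
`passes_two_decades()` applies the scale-free screening rule: at least two
decades of linear width on *both* axes, boundary inclusive (published
passing widths such as 2.3 decades make an exclusive reading of "more than
two orders" untenable at the printed precision). Two caveats are inherent
to the construction and documented rather than hidden: the band pinches to
zero width at the pivot abscissa, so a noisy point near the centroid can
split the run (the pivot is configurable via `pivot_x`); and the published
ranges were determined manually, so this automated rule is a declared
convention, not a reconstruction.

`discriminant_R()` asks whether the count values favor a discrete power law
or a discrete exponential: both are fitted by maximum likelihood with xmin
fixed at the minimum observed value (again, no xmin search — the question
is about the whole distribution), and the signed log-likelihood ratio R is
reported with a Vuong-normalized two-sided p. Positive R favors the power
law. The power-law normalizer is a Hurwitz zeta evaluated by
Euler–Maclaurin summation (16 direct terms plus tail corrections, accurate
to ~1e-12 over the fitted range); the exponential MLE is closed-form.
`truncation_sweep()` repeats the comparison keeping only the top-ranked
fraction of words, tracing how a noisy low-rank tail can mask a scale-free
body: protein word counts typically give strongly negative R untruncated
and positive R once only the top ~10% of ranks remain.

## Motif statistics

Motif intervals arrive as a validated TSV (protein, start, end, name;
1-based inclusive; overlaps rejected; motifs longer than 20 residues
filtered and counted — the length cap under which "motif" means a short
sequence pattern rather than a domain).

`enrichment()` counts, over the motif-containing proteins only, windows
with A ≥ thr overall versus inside motifs, and motif residue coverage
versus the share of high-A windows inside motifs. A window is "inside" a
motif when fully contained (default); an overlap-based variant is a flag.
The second fold deliberately divides a window percentage by a residue
percentage — that is how the headline numbers are conventionally formed —
and a units-consistent window baseline (`f_windows_in_motif`) is reported
alongside for readers who want the cleaner ratio.

`peak_correspondence()` asks whether the top of the rA profile lands on a
motif: qualifying windows are the rA = 100 ties (or rA ≥ 50), and a motif
counts as identified if any qualifying window shares at least one residue
with it. Because the literature mixes motif-level and protein-level
denominators, both percentages are always returned, labeled.

`random_fragments()` draws the matched null: 13-residue stretches (13 ~ the
average motif length) sampled uniformly from the same proteins, rejecting
any candidate that touches a motif, reproducibly under a seed.
`compare_distributions()` is the standard Mann-Whitney U with normal
approximation and tie correction (checked against exact enumeration in the
tests). Composition shifts are summarized by ranking the 20 letters by
frequency (ties alphabetical; absent letters after all present ones),
per-letter rank changes Δ = rank_ref − rank_query (positive = the letter
rose in the query), and the rank order distance ROD = mean |Δ|, which is 0
for identical orderings, 10 for a full reversal of 20 letters, and 6.65 in
expectation for a random permutation.

## Synthetic data: what it emulates and what it does not

The generators supply every input class the pipeline needs, so all tests
run without downloads:

* `gen_protein_db()` — i.i.d. letters, uniform composition by default,
  200 sequences of 300 residues (a typical protein length) unless asked
  otherwise. It emulates database-scale letter statistics, not biology: no
  domain structure, no repeats, no homology.
* `gen_zipf_corpus()` — exact inverse-CDF sampling over a finite
  vocabulary with P(rank i) ∝ i^−s, so the generating exponent is exact
  for recovery tests; vocabulary word lengths are shifted-Poisson with
  mode 3 (short words dominate, as in English). Defaults: 5000 words,
  s = 1, 10^5 tokens.
* `plant_motifs()` — a fixed random 13-mer whose constituent pentats are
  first oversampled into the background (default 60 copies each,
  unannotated) so they become genuinely high-availability words, then
  inserted at 40 annotated, non-overlapping sites.

One deliberate regime choice: the planted-motif world uses an 8-letter
alphabet. With 20 letters at desk scale (~3.6e4 windows against 3.2e6
possible pentats) every observed pentat is a sampling singleton with
E ≈ 0.01 and A ≈ 90, so an absolute threshold like A ≥ 3 selects
everything. An 8-letter alphabet saturates the word space (8^5 = 32768),
putting the fixture in the same statistical regime as a full-size protein
database, where the threshold is discriminative. Passing tests therefore
demonstrate the machinery and its statistics, not biological motif
signal — real proteomes add composition bias, repeats and homologous
redundancy that no generator here models.

The truncation-sweep fixture is a power-law body (n = 2000, α = 1.8,
support bounded at 2000) over a geometric excess (n = 18000, mean 4):
bounded, because with an unbounded Pareto tail the exponential's likelihood
collapses on a few extreme counts and the power law wins even untruncated,
whereas empirical protein count distributions are bounded and
exponential-dominated at full rank depth.

## Numerical choices and degenerate inputs

* Ties in ranking and in composition ranking break lexicographically /
  alphabetically — every ordering in the package is deterministic.
* `linear_range` membership uses a relative tolerance of 1e-9 so exact
  constructions are not excluded by float fuzz; `band = 0` degenerates to
  "rows exactly on the line".
* `discriminant_R` requires ≥ 10 integer values ≥ 1 and rejects
  all-identical samples (the ratio is undefined); truncations leaving
  fewer than 10 rows are flagged `insufficient`, not computed.
* Empty corpora give T = t = 0 dictionaries with a warning; queries
  shorter than k give empty profiles with a warning; profiles that score 0
  everywhere report rA = 0 rather than dividing by zero.
* The Zipf corpus uses 31-bit-safe integer seeds throughout; every
  stochastic function takes an explicit `seed` and restores the caller's
  RNG state.

## Problem sizes

The shipped test suite and acceptance script run at desk scale, chosen so
the statistical claims are well-powered: 10^5-shuffle Monte-Carlo for the
worked expected-count example (standard error ~0.004), 10^5-token Zipf
corpora for exponent recovery (±0.1), 20 seeds × 10^4 draws for the
discriminant sign rates, 120 × 300-residue planted-motif databases with
200 null fragments, and 5000 permutations for the ROD expectation. Full
enumeration checks stop at the 3.2M pentat key space.

## Known limitations

* The availability model conditions on composition only; it does not model
  dipeptide bias or local order, which is precisely why deviations from
  A = 1 are informative.
* `linear_range` automates a procedure that was historically manual; its
  pivot convention is principled but not unique.
* The discriminant compares exactly two families (power law vs
  exponential); it does not adjudicate lognormal or stretched-exponential
  alternatives, and no xmin scan is performed by design.
* K-mer counting is in-memory and intended for desk-scale corpora (up to
  ~10^7 letters), not genome-scale disk-backed counting.
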