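# scsavail

Word-decoding statistics for protein amino-acid sequences.

Proteins carry no spaces, yet their sequences can be read as unbroken
strings of short "words" — short constituent sequences (SCSs), i.e.
k-mers with k = 1..6. `scsavail` implements the statistics needed to study
protein word usage this way:

* **SCS dictionaries** — sparse counts of every observed k-mer over a
  sanitized corpus (non-standard residues X/U/B/Z/J/O split sequences and
  are excluded from all totals), with the letter composition, total letter
  count `T` and total window count `t`.
* **Availability scores** — for each word `w = a_0..a_{m-1}`, the observed
  count `R(w)` relative to the count expected under a uniform random
  arrangement of the database's letters *without replacement*:

  ```
  A(w) = R(w) / E(w),   E(w) = t * prod_k (n_k - x_k) / (T - k)
  ```

  where `n_k` is the database count of letter `a_k` and `x_k` its
  multiplicity among the word's preceding letters. `A > 1` marks over-used
  words; per-query profiles rescale to the relative availability `rA`
  (maximum = 100%).
* **Zipf / power-law diagnostics** — deterministic rank-frequency tables,
  log10-log10 least-squares fits (`y = a x^-b`), linear-range widths
  inside a ±0.15-exponent band with the two-decades scale-free criterion,
  and a signed power-law-vs-exponential likelihood-ratio discriminant
  (Vuong-normalized, xmin fixed at the minimum) with top-rank truncation
  sweeps. Plain-text corpora are supported too, including the "compressed"
  mode with inter-word spaces removed.
* **Motif statistics** — enrichment of high-availability windows
  (`A >= 3`) in motif intervals and vice versa, availability-peak/motif
  correspondence (`rA = 100%` and `rA >= 50%`), random motif-free
  13-residue fragment nulls, Mann-Whitney comparisons, and amino-acid
  composition rank-order distances (ROD).
* **Synthetic generators** — seed-deterministic i.i.d. protein databases,
  exact inverse-CDF Zipfian corpora, and planted-motif databases with
  availability-boosted motif words, so the whole pipeline is testable
  offline.

## Worked example

Build a planted-motif database, score availability, and ask whether the
planted motifs sit on high-availability words:

```r
library(scsavail)

db  <- gen_protein_db(n_sequences = 120, length = 300,
                      alphabet = aa_alphabet()[1:8], seed = 11)
pl  <- plant_motifs(db, n_sites = 40, boost = 60, seed = 12)
dict <- count_scs(pl$corpus, 5)
dict
#> <scs_dict> k=5: 20680 distinct SCS, t=35520 windows over T=36000 letters (r=0.9867)

tab <- build_availability_table(dict)
head(as.data.frame(tab), 3)
#>     scs   R        E        A
#> 1 CIHDG 126 1.116815 112.8208
#> 2 IHDGF 121 1.149485 105.2645
#> 3 DGFFE 123 1.212603 101.4347

enrichment(pl$corpus, pl$motifs, tab)
#> <enrichment_report> k=5, A>=3 (full containment)
#>   high windows: 21.4% overall vs 100.0% in motifs (4.68-fold)
#>   motif share: 5.0% of residues vs 16.2% of high windows (3.28-fold)
```

The top dictionary entries are the planted motif's constituent pentats:
each occurs ~120 times against an expected ~1.1, hence availability ~100.
Every pentat inside a planted motif clears the `A >= 3` threshold versus
21.4% of windows overall (a 4.7-fold enrichment), and motif windows
dominate the high-availability set 3.3-fold relative to the 5.0% of
residues motifs occupy. The matched null separates cleanly:

```r
frags <- random_fragments(pl$corpus, pl$motifs, frag_len = 13, n = 200, seed = 13)
motif_A <- interval_window_scores(pl$corpus, pl$motifs, tab, 5)
frag_A  <- interval_window_scores(pl$corpus, frags, tab, 5)
c(median(motif_A), median(frag_A))
#> [1] 99.94  1.83
compare_distributions(motif_A, frag_A)$p
#> [1] 1.23e-187
```

Rank-frequency diagnostics on the same dictionary show the behavior
typical of protein word counts — a heavy low-rank tail that defeats the
power law until it is truncated away:

```r
rf <- rank_frequency(dict)
fit_loglog(rf)
#> <loglog_fit> y = 82.8 * x^-0.452  (r = 0.928, n = 20680)
truncation_sweep(rf, c(100, 50, 10))
#>   fraction n_kept     R_disc             p insufficient
#> 1      100  20680 -1337.3720  2.004585e-06        FALSE
#> 2       50  10340 -3607.7596 3.179526e-106        FALSE
#> 3       10   2068   624.6159  1.513502e-05        FALSE
```

The discriminant is negative on all ranks (exponential wins) and flips
positive once only the top 10% of ranks remain.

## Command line

A thin launcher over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/scsavail build-dict --k 5 --out work/dict proteins.fasta
Rscript inst/cli/scsavail avail --dict work/dict/dict.tsv --out work/avail
Rscript inst/cli/scsavail profile --dict work/dict/dict.tsv --out work/prof query.fasta
```

Every run writes a `manifest.json` echoing the full configuration; same
config + same seed means byte-identical outputs.

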