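toy_motif_world <- function() {
  # one 20-residue protein with a motif at 6..15; the 6 pentats fully
  # inside the motif carry A = 5, the other 10 windows A = 1
  seq20 <- "ACDEFGHIKLMNPQRSTVWY"
  corpus <- make_corpus(list(p1 = seq20), sanitize = FALSE)
  wins <- extract_windows(seq20, 5)
  A <- ifelse(wins$start >= 6 & wins$start + 4 <= 15, 5, 1)
  tab <- fake_avail_table(wins$scs, A)
  motifs <- as_motif_set(data.frame(protein = "p1", start = 6L, end = 15L,
                                    name = "M1", stringsAsFactors = FALSE),
                         corpus)
  list(corpus = corpus, tab = tab, motifs = motifs)
}

test_that("motif loading validates coordinates, ids, overlap and length", {
  corpus <- make_corpus(list(p1 = strrep("A", 20)), sanitize = FALSE)
  path <- tempfile(fileext = ".tsv")
  writeLines(c("protein\tstart\tend\tname", "p1\t6\t15\tM1"), path)
  ms <- load_motifs(path, corpus)
  expect_s3_class(ms, "motif_set")
  expect_equal(ms$end - ms$start + 1L, 10L)
  bad <- data.frame(protein = "p1", start = 0L, end = 5L, name = "M")
  expect_error(as_motif_set(bad, corpus), "1-based")
  expect_error(as_motif_set(data.frame(protein = "p9", start = 1L, end = 5L,
                                       name = "M"), corpus), "unknown")
  expect_error(as_motif_set(data.frame(protein = "p1", start = 5L, end = 25L,
                                       name = "M"), corpus), "invalid")
  expect_error(as_motif_set(data.frame(protein = c("p1", "p1"),
                                       start = c(1L, 5L), end = c(6L, 9L),
                                       name = c("a", "b")), corpus),
               "overlapping")
  # a 21-residue motif is filtered out and counted
  big <- make_corpus(list(p1 = strrep("A", 40)), sanitize = FALSE)
  ms2 <- as_motif_set(data.frame(protein = "p1", start = c(1L, 30L),
                                 end = c(21L, 34L), name = c("long", "ok")),
                      big)
  expect_equal(nrow(ms2), 1L)
  expect_equal(attr(ms2, "n_rejected_long"), 1L)
})

test_that("high_windows applies the availability threshold", {
  tab <- fake_avail_table(c("AAAAA", "AAAAC", "AAACA"), A = c(1, 3, 5))
  prof <- availability_profile("AAAAACA", tab)
  expect_equal(high_windows(prof, thr = 3), c(2L, 3L))
  expect_equal(high_windows(prof, thr = 5), 3L)
  expect_length(high_windows(prof, thr = 99), 0L)
})

test_that("enrichment reproduces the constructed toy arithmetic", {
  w <- toy_motif_world()
  rep <- enrichment(w$corpus, w$motifs, w$tab, k = 5, thr = 3)
  expect_equal(rep$counts$windows, 16L)
  expect_equal(rep$f_high_all, 100 * 6 / 16)   # 37.5%
  expect_equal(rep$f_high_in_motif, 100)
  expect_equal(rep$fold_high_in_motif, 16 / 6, tolerance = 1e-9)  # ~2.67
  expect_equal(rep$f_motif_residues, 50)
  expect_equal(rep$f_high_windows_in_motif, 100)
  # conservation: windows inside + outside = total
  expect_equal(rep$counts$windows_in_motif +
                 (rep$counts$windows - rep$counts$windows_in_motif),
               rep$counts$windows)
})

test_that("no high windows anywhere reports zero folds with a flag", {
  w <- toy_motif_world()
  rep <- enrichment(w$corpus, w$motifs, w$tab, k = 5, thr = 99)
  expect_true(rep$no_high_windows)
  expect_equal(rep$fold_high_in_motif, 0)
  expect_equal(rep$fold_motif_in_high, 0)
})

test_that("planted-motif databases show fold enrichment above 1", {
  fx <- planted_fixture()
  rep <- enrichment(fx$corpus, fx$motifs, fx$table, k = 5, thr = 3)
  expect_gt(rep$fold_high_in_motif, 1)
  expect_gt(rep$fold_motif_in_high, 1)
})

test_that("peak correspondence finds motifs under the max-A peak", {
  w <- toy_motif_world()
  res <- peak_correspondence(w$corpus, w$motifs, w$tab, k = 5, mode = "rA100")
  expect_equal(res$pct_motifs, 100)
  expect_equal(res$pct_proteins, 100)
  # move all the high availability outside the motif: no correspondence
  wins <- extract_windows("ACDEFGHIKLMNPQRSTVWY", 5)
  tab2 <- fake_avail_table(wins$scs, ifelse(wins$start == 1, 9, 1))
  res2 <- peak_correspondence(w$corpus, w$motifs, tab2, k = 5, mode = "rA100")
  expect_equal(res2$pct_motifs, 0)
})

test_that("rA>=50 correspondence dominates rA=100 on random fixtures", {
  for (seed in c(7, 19, 33)) {
    db <- gen_protein_db(n_sequences = 30, length = 120, seed = seed)
    pl <- plant_motifs(db, n_sites = 10, boost = 10, seed = seed + 1)
    tab <- build_availability_table(count_scs(pl$corpus, 5))
    r100 <- peak_correspondence(pl$corpus, pl$motifs, tab, mode = "rA100")
    r50 <- peak_correspondence(pl$corpus, pl$motifs, tab, mode = "rA50")
    expect_gte(r50$pct_motifs, r100$pct_motifs)
    expect_gte(r50$pct_proteins, r100$pct_proteins)
  }
})

test_that("random fragments are reproducible and never touch motifs", {
  fx <- planted_fixture(n_sequences = 40, n_sites = 15)
  fr1 <- random_fragments(fx$corpus, fx$motifs, frag_len = 13, n = 100,
                          seed = 5)
  fr2 <- random_fragments(fx$corpus, fx$motifs, frag_len = 13, n = 100,
                          seed = 5)
  expect_identical(fr1, fr2)
  expect_equal(nrow(fr1), 100L)
  expect_true(all(fr1$end - fr1$start + 1L == 13L))
  for (i in seq_len(nrow(fr1))) {
    rows <- fx$motifs[fx$motifs$protein == fr1$protein[i], , drop = FALSE]
    expect_false(any(fr1$start[i] <= rows$end & fr1$end[i] >= rows$start))
  }
})

test_that("fragment sampling aborts when motif-free space is exhausted", {
  corpus <- make_corpus(list(p1 = strrep("A", 20)), sanitize = FALSE)
  motifs <- as_motif_set(data.frame(protein = "p1", start = 1L, end = 20L,
                                    name = "all"), corpus)
  expect_error(random_fragments(corpus, motifs, frag_len = 13, n = 5,
                                seed = 1, max_consecutive_failures = 200),
               "stalled")
})

test_that("motif windows score higher than random fragments on planted data", {
  fx <- planted_fixture()
  motif_scores <- interval_window_scores(fx$corpus, fx$motifs, fx$table, 5)
  frags <- random_fragments(fx$corpus, fx$motifs, frag_len = 13, n = 200,
                            seed = 11)
  frag_scores <- interval_window_scores(fx$corpus, frags, fx$table, 5)
  expect_gt(stats::median(motif_scores), stats::median(frag_scores))
  cmp <- compare_distributions(motif_scores, frag_scores)
  expect_lt(cmp$p, 0.01)
})

test_that("Mann-Whitney comparison matches exact enumeration and edge cases", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  res <- compare_distributions(a, b)
  expect_equal(res$U, 0)
  expect_lt(res$p, 0.05)
  same <- compare_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.99)
  expect_warning(compare_distributions(c(1, 2), c(3, 4, 5)), "fewer than 3")
  set.seed(23)
  for (rep in 1:5) {
    x <- sample(1:30, 8); y <- sample(1:30, 8)
    mine <- compare_distributions(x, y)
    ref <- mw_exact(x, y)
    expect_equal(mine$U, ref$U)
    expect_lt(abs(mine$p - ref$p), 0.05)
  }
})

test_that("composition ranking orders letters with documented tie rules", {
  rk <- composition_ranking("AAACCG", alphabet = c("A", "C", "G", "T"))
  expect_equal(unname(rk[c("A", "C", "G", "T")]), c(1L, 2L, 3L, 4L))
  # absent letters rank after all present ones, alphabetically
  expect_equal(names(sort(rk))[4], "T")
  expect_error(composition_ranking(""), "empty")
})

test_that("rank changes and ROD satisfy their closed forms", {
  set.seed(29)
  pool <- paste(sample(aa_alphabet(), 500, TRUE), collapse = "")
  ref <- composition_ranking(pool)
  expect_equal(rod(ref, ref), 0)
  expect_true(all(rank_changes(ref, ref) == 0L))
  # full reversal of 20 ranks: mean |2i - 21| = 10
  rev_rank <- structure(21L - ref, names = names(ref))
  expect_equal(rod(rev_rank, ref), 10)
  # random permutations: E[ROD] = (20^2 - 1)/60 = 6.65
  sim <- replicate(3000, {
    perm <- structure(sample(20L), names = names(ref))
    rod(perm, ref)
  })
  expect_equal(mean(sim), (20^2 - 1) / 60, tolerance = 0.02)
})
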