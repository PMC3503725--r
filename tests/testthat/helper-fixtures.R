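# Shared fixture builders and independent oracles.

# Write named sequences to a temp FASTA and read them back as a corpus.
make_corpus <- function(seqs, alphabet = scsavail::aa_alphabet(),
                        sanitize = TRUE) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  corp <- read_fasta(path, alphabet = alphabet)
  if (sanitize) sanitize_corpus(corp) else corp
}

# Hand-built availability table with prescribed scores (for profile and
# motif tests where the A values themselves are the fixture).
fake_avail_table <- function(scs, A, alphabet = scsavail::aa_alphabet(),
                             k = nchar(scs[1])) {
  comp <- rep(1000L, length(alphabet))
  names(comp) <- alphabet
  structure(data.frame(scs = scs, R = rep(1L, length(scs)),
                       E = rep(1, length(scs)), A = A,
                       stringsAsFactors = FALSE),
            class = c("avail_table", "data.frame"),
            k = k, T = sum(comp), t = sum(comp) - k + 1L,
            composition = comp, alphabet = alphabet,
            method = "ratio", model = "elaborate")
}

# Brute-force window scanner over a raw (unsanitized) record: counts k-mers
# skipping any window that touches a non-alphabet letter.
brute_force_windows <- function(residues, k, alphabet) {
  n <- nchar(residues)
  out <- character(0)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- substring(residues, i, i + k - 1)
      ch <- strsplit(w, "", fixed = TRUE)[[1]]
      if (all(ch %in% alphabet)) out <- c(out, w)
    }
  }
  out
}

# Monte-Carlo oracle for the expected window count: mean occurrences of
# `word` over uniform random shuffles of the letter multiset.
mc_expected_count <- function(letter_multiset, word, n_shuffles, seed = 1) {
  set.seed(seed)
  counts <- vapply(seq_len(n_shuffles), function(i) {
    s <- paste(sample(letter_multiset), collapse = "")
    hits <- gregexpr(word, s, fixed = TRUE)[[1]]
    sum(hits > 0)
  }, numeric(1))
  list(mean = mean(counts), se = stats::sd(counts) / sqrt(n_shuffles))
}

# Discrete power-law sampler over bounded support 1..cap.
pl_sample <- function(n, alpha, cap = 1e5) {
  p <- (1:cap)^(-alpha)
  sample.int(cap, n, replace = TRUE, prob = p)
}

# Independent implementation of the power-law vs exponential likelihood
# comparison (grid-search MLE, direct zeta summation + integral tail):
# a different code path from the package's optimize()/Euler-Maclaurin route.
csn_oracle <- function(x) {
  xmin <- min(x)
  n <- length(x)
  alphas <- seq(1.05, 6, by = 0.002)
  j <- 0:9999
  zmat <- vapply(alphas, function(a)
    sum((xmin + j)^(-a)) + (xmin + 1e4)^(1 - a) / (a - 1) +
      0.5 * (xmin + 1e4)^(-a), numeric(1))
  slx <- sum(log(x))
  nll <- n * log(zmat) + alphas * slx
  a_hat <- alphas[which.min(nll)]
  z_hat <- zmat[which.min(nll)]
  ll_pl <- -a_hat * log(x) - log(z_hat)
  d <- mean(x) - xmin
  q <- d / (d + 1)
  ll_ex <- log(1 - q) + (x - xmin) * log(q)
  di <- ll_pl - ll_ex
  R <- sum(di)
  p <- 2 * stats::pnorm(-abs(R) / (stats::sd(di) * sqrt(n)))
  list(R = R, p = p, alpha = a_hat)
}

# Exact two-sided permutation p-value of the Mann-Whitney U statistic
# (enumerates all assignments of the pooled ranks; ties via midranks).
mw_exact <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(ii) sum(rk[ii]) - n1 * (n1 + 1) / 2)
  mu <- mean(u_all)
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p = p)
}

# Power-law body plus geometric low-rank excess: the truncation-sweep
# fixture (bounded power law so the exponential bulk wins untruncated).
mixture_counts <- function(seed, n_pl = 2000, alpha = 1.8, cap = 2000,
                           n_geo = 18000, mean_geo = 4) {
  set.seed(seed)
  plx <- pl_sample(n_pl, alpha, cap)
  geo <- stats::rgeom(n_geo, 1 / mean_geo) + 1
  counts <- c(plx, geo)
  names(counts) <- paste0("w", seq_along(counts))
  counts
}

# Small planted-motif world shared by motif-pipeline tests and acceptance.
# An 8-letter alphabet keeps the pentat word space saturated (8^5 = 32768
# words against ~36k windows), so the A >= 3 threshold is discriminative at
# desk scale the way it is for a full proteome database; with 20 letters
# and this few windows every observed pentat would be "high".
planted_fixture <- function(seed = 101, n_sequences = 120, length = 300,
                            n_sites = 40, boost = 60,
                            alphabet = scsavail::aa_alphabet()[1:8]) {
  db <- gen_protein_db(n_sequences = n_sequences, length = length,
                       alphabet = alphabet, seed = seed)
  pl <- plant_motifs(db, motif_length = 13, n_sites = n_sites,
                     boost = boost, seed = seed + 1)
  dict <- count_scs(pl$corpus, 5)
  table <- build_availability_table(dict)
  list(corpus = pl$corpus, motifs = pl$motifs, motif_seq = pl$motif_seq,
       dict = dict, table = table)
}
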