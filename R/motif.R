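# Rebuild a record's residue string from a corpus; gaps left by
# sanitization are filled with "-" (never in any alphabet) so windows
# cannot span them.
record_residues <- function(corpus, id) {
  segs <- corpus$segments[corpus$segments$record == id, , drop = FALSE]
  len <- corpus$records$length[match(id, corpus$records$id)]
  if (is.na(len)) stop("unknown protein id: ", id)
  if (nrow(segs) == 1L && segs$offset[1] == 0L &&
      nchar(segs$residues[1]) == len)
    return(segs$residues[1])
  chars <- rep("-", len)
  for (i in seq_len(nrow(segs))) {
    piece <- strsplit(segs$residues[i], "", fixed = TRUE)[[1]]
    chars[segs$offset[i] + seq_along(piece)] <- piece
  }
  paste(chars, collapse = "")
}

#' Load motif intervals from a TSV file
#'
#' Expects columns `protein`, `start`, `end`, `name` with 1-based inclusive
#' coordinates on the original protein record (the shape a PROSITE scan
#' report reduces to). Rows are validated against the corpus: unknown
#' protein ids, non-positive or inverted coordinates, out-of-range ends and
#' overlapping intervals within a protein are rejected with a message.
#' Motifs longer than `max_len` residues are filtered out and counted.
#'
#' @param path TSV path (header required).
#' @param corpus The corpus the coordinates refer to.
#' @param max_len Maximum motif length kept (default 20 residues).
#' @return data.frame of class `motif_set`; attribute `n_rejected_long`
#'   holds the number filtered by the length cap.
#' @export
load_motifs <- function(path, corpus, max_len = 20L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein", "start", "end", "name")
  if (!all(need %in% names(df)))
    stop("motif TSV must have columns: ", paste(need, collapse = ", "))
  as_motif_set(df[need], corpus, max_len)
}

#' @rdname load_motifs
#' @param df data.frame with columns protein, start, end, name.
#' @export
as_motif_set <- function(df, corpus, max_len = 20L) {
  lens <- corpus$records$length[match(df$protein, corpus$records$id)]
  if (anyNA(lens))
    stop("motif on unknown protein id: ",
         paste(unique(df$protein[is.na(lens)]), collapse = ", "))
  bad <- df$start < 1L | df$start > df$end | df$end > lens
  if (any(bad))
    stop("invalid motif coordinates (1-based inclusive required): ",
         paste(sprintf("%s:%d-%d", df$protein[bad], df$start[bad],
                       df$end[bad]), collapse = "; "))
  long <- (df$end - df$start + 1L) > max_len
  kept <- df[!long, , drop = FALSE]
  kept <- kept[order(kept$protein, kept$start), , drop = FALSE]
  for (p in unique(kept$protein)) {
    rows <- kept[kept$protein == p, , drop = FALSE]
    if (nrow(rows) > 1L && any(rows$start[-1L] <= rows$end[-nrow(rows)]))
      stop("overlapping motifs on protein ", p)
  }
  rownames(kept) <- NULL
  structure(kept, class = c("motif_set", "data.frame"),
            n_rejected_long = sum(long))
}

#' Window positions with availability at or above a threshold
#'
#' @param profile An `avail_profile`.
#' @param thr Availability threshold (default 3, the "high-availability"
#'   cutoff; 5 marks the strictest sites).
#' @return Integer vector of qualifying window start positions, ascending.
#' @export
high_windows <- function(profile, thr = 3) {
  stopifnot(inherits(profile, "avail_profile"))
  pos <- profile$position[!is.na(profile$A) & profile$A >= thr]
  sort(pos)
}

# windows fully contained in (or overlapping) any motif interval of one protein
windows_in_motifs <- function(positions, k, starts, ends,
                              containment = c("full", "overlap")) {
  containment <- match.arg(containment)
  if (length(starts) == 0L) return(rep(FALSE, length(positions)))
  ins <- rep(FALSE, length(positions))
  for (i in seq_along(starts)) {
    ins <- ins | if (containment == "full")
      positions >= starts[i] & (positions + k - 1L) <= ends[i]
    else
      positions <= ends[i] & (positions + k - 1L) >= starts[i]
  }
  ins
}

#' Enrichment of high-availability windows in motifs (and vice versa)
#'
#' Over the motif-containing proteins only, computes the percentage of
#' k-windows with A >= thr among all windows (`f_high_all`) and among the
#' windows inside motifs (`f_high_in_motif`), the percentage of residues
#' covered by motifs (`f_motif_residues`), and the percentage of
#' high-availability windows that fall inside motifs
#' (`f_high_windows_in_motif`). The two fold enrichments are the ratios of
#' the paired quantities. Note the second fold deliberately compares a
#' window percentage against a residue-percentage baseline; a window-based
#' baseline is available as `f_windows_in_motif` for a units-consistent
#' reading.
#'
#' A window is "inside" a motif when all k residues lie within the motif
#' interval (`containment = "full"`, default) or when it overlaps the motif
#' by at least one residue (`"overlap"`).
#'
#' @param corpus Corpus holding the motif-bearing proteins.
#' @param motifs A `motif_set`.
#' @param table An `avail_table` built at word length `k`.
#' @param k Window length (default 5).
#' @param thr High-availability threshold (default 3).
#' @param containment Window-in-motif rule.
#' @return list of class `enrichment_report` with all percentages, folds
#'   and the raw counts backing them.
#' @export
enrichment <- function(corpus, motifs, table, k = 5L, thr = 3,
                       containment = c("full", "overlap")) {
  containment <- match.arg(containment)
  stopifnot(inherits(motifs, "motif_set"))
  prots <- unique(motifs$protein)
  if (length(prots) == 0L) stop("no motif-containing proteins")
  n_win <- n_high <- n_win_in <- n_high_in <- 0L
  n_res <- n_res_motif <- 0L
  for (p in prots) {
    prof <- availability_profile(record_residues(corpus, p), table, k, id = p)
    high <- !is.na(prof$A) & prof$A >= thr
    rows <- motifs[motifs$protein == p, , drop = FALSE]
    ins <- windows_in_motifs(prof$position, k, rows$start, rows$end,
                             containment)
    n_win <- n_win + nrow(prof)
    n_high <- n_high + sum(high)
    n_win_in <- n_win_in + sum(ins)
    n_high_in <- n_high_in + sum(ins & high)
    n_res <- n_res + corpus$records$length[match(p, corpus$records$id)]
    n_res_motif <- n_res_motif + sum(rows$end - rows$start + 1L)
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  f_high_all <- pct(n_high, n_win)
  f_high_in_motif <- pct(n_high_in, n_win_in)
  f_motif_residues <- pct(n_res_motif, n_res)
  f_high_windows_in_motif <- pct(n_high_in, n_high)
  f_windows_in_motif <- pct(n_win_in, n_win)
  no_high <- n_high == 0L
  folds <- if (no_high) c(0, 0) else
    unname(enrichment_folds(f_high_all, f_high_in_motif,
                            f_motif_residues, f_high_windows_in_motif))
  structure(
    list(f_high_all = f_high_all,
         f_high_in_motif = f_high_in_motif,
         fold_high_in_motif = folds[1],
         f_motif_residues = f_motif_residues,
         f_high_windows_in_motif = f_high_windows_in_motif,
         fold_motif_in_high = folds[2],
         f_windows_in_motif = f_windows_in_motif,
         no_high_windows = no_high,
         counts = list(windows = n_win, high = n_high,
                       windows_in_motif = n_win_in,
                       high_in_motif = n_high_in,
                       residues = n_res, motif_residues = n_res_motif),
         k = k, thr = thr, containment = containment),
    class = "enrichment_report")
}

#' Fold enrichments from the four report percentages
#'
#' `fold_high_in_motif` = f_high_in_motif / f_high_all;
#' `fold_motif_in_high` = f_high_windows_in_motif / f_motif_residues.
#'
#' @param f_high_all,f_high_in_motif,f_motif_residues,f_high_windows_in_motif
#'   Percentages as in [enrichment()].
#' @return Numeric vector of the two folds.
#' @export
enrichment_folds <- function(f_high_all, f_high_in_motif,
                             f_motif_residues, f_high_windows_in_motif) {
  c(fold_high_in_motif = f_high_in_motif / f_high_all,
    fold_motif_in_high = f_high_windows_in_motif / f_motif_residues)
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report> k=%d, A>=%g (%s containment)\n",
              x$k, x$thr, x$containment))
  cat(sprintf("  high windows: %.1f%% overall vs %.1f%% in motifs (%.2f-fold)\n",
              x$f_high_all, x$f_high_in_motif, x$fold_high_in_motif))
  cat(sprintf("  motif share: %.1f%% of residues vs %.1f%% of high windows (%.2f-fold)\n",
              x$f_motif_residues, x$f_high_windows_in_motif,
              x$fold_motif_in_high))
  invisible(x)
}

#' Correspondence between availability peaks and motifs
#'
#' Qualifying windows are those at the top of a protein's relative
#' availability profile: rA = 100 (all tied maxima) or rA >= 50. A motif is
#' identified when at least one qualifying window shares at least one
#' residue with it. Both the motif-level percentage (identified motifs /
#' all motifs) and the protein-level percentage (proteins with >= 1
#' identified motif / motif-containing proteins) are returned.
#'
#' @inheritParams enrichment
#' @param mode `"rA100"` or `"rA50"`.
#' @return list: pct_motifs, pct_proteins, n_motifs, n_proteins,
#'   n_motifs_identified, n_proteins_identified, mode.
#' @export
peak_correspondence <- function(corpus, motifs, table, k = 5L,
                                mode = c("rA100", "rA50")) {
  mode <- match.arg(mode)
  stopifnot(inherits(motifs, "motif_set"))
  prots <- unique(motifs$protein)
  n_motif_hit <- 0L; n_prot_hit <- 0L
  for (p in prots) {
    prof <- availability_profile(record_residues(corpus, p), table, k, id = p)
    qual <- if (mode == "rA100") which(!is.na(prof$rA) & prof$rA >= 100 - 1e-9)
            else which(!is.na(prof$rA) & prof$rA >= 50)
    qpos <- prof$position[qual]
    rows <- motifs[motifs$protein == p, , drop = FALSE]
    hit_any <- FALSE
    for (i in seq_len(nrow(rows))) {
      hit <- any(qpos <= rows$end[i] & (qpos + k - 1L) >= rows$start[i])
      if (hit) { n_motif_hit <- n_motif_hit + 1L; hit_any <- TRUE }
    }
    if (hit_any) n_prot_hit <- n_prot_hit + 1L
  }
  list(pct_motifs = 100 * n_motif_hit / nrow(motifs),
       pct_proteins = 100 * n_prot_hit / length(prots),
       n_motifs = nrow(motifs), n_proteins = length(prots),
       n_motifs_identified = n_motif_hit, n_proteins_identified = n_prot_hit,
       mode = mode)
}

#' Random motif-free fragments from motif-containing proteins
#'
#' Draws fragments of `frag_len` residues uniformly at random (protein, then
#' start) from the motif-containing proteins, discarding any candidate that
#' shares a residue with a motif, until `n` fragments are collected.
#' Reproducible under `seed`.
#'
#' @inheritParams enrichment
#' @param frag_len Fragment length (default 13, the average motif length the
#'   sampler is matched to).
#' @param n Number of fragments.
#' @param seed Integer RNG seed.
#' @param max_consecutive_failures Abort threshold for rejection sampling.
#' @return data.frame (protein, start, end, sequence).
#' @export
random_fragments <- function(corpus, motifs, frag_len = 13L, n = 521L,
                             seed = 1L, max_consecutive_failures = 1e4) {
  stopifnot(inherits(motifs, "motif_set"))
  prots <- unique(motifs$protein)
  lens <- corpus$records$length[match(prots, corpus$records$id)]
  eligible <- prots[lens >= frag_len]
  if (length(eligible) == 0L) stop("no protein long enough for fragments")
  res <- vector("list", n)
  with_seed(seed, {
    got <- 0L; fails <- 0L
    while (got < n) {
      p <- eligible[sample.int(length(eligible), 1L)]
      plen <- corpus$records$length[match(p, corpus$records$id)]
      start <- sample.int(plen - frag_len + 1L, 1L)
      end <- start + frag_len - 1L
      rows <- motifs[motifs$protein == p, , drop = FALSE]
      overlap <- any(start <= rows$end & end >= rows$start)
      if (overlap) {
        fails <- fails + 1L
        if (fails >= max_consecutive_failures)
          stop("rejection sampling stalled: ", fails,
               " consecutive overlaps; too little motif-free sequence")
        next
      }
      fails <- 0L
      got <- got + 1L
      res[[got]] <- data.frame(protein = p, start = start, end = end,
                               stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$sequence <- vapply(seq_len(nrow(out)), function(i)
    substring(record_residues(corpus, out$protein[i]), out$start[i],
              out$end[i]), character(1))
  out
}

#' Availability scores of windows inside a set of intervals
#'
#' Collects the availability of every k-window fully contained in the given
#' intervals (e.g. motifs, or random fragments), pooling over proteins.
#' Unscorable windows are dropped.
#'
#' @param corpus Corpus holding the proteins.
#' @param intervals data.frame with columns protein, start, end.
#' @param table An `avail_table`.
#' @param k Window length.
#' @return Numeric vector of availability scores.
#' @export
interval_window_scores <- function(corpus, intervals, table, k = 5L) {
  scores <- numeric(0)
  for (p in unique(intervals$protein)) {
    prof <- availability_profile(record_residues(corpus, p), table, k, id = p)
    rows <- intervals[intervals$protein == p, , drop = FALSE]
    ins <- windows_in_motifs(prof$position, k, rows$start, rows$end, "full")
    scores <- c(scores, prof$A[ins & !is.na(prof$A)])
  }
  scores
}

#' Mann-Whitney comparison of two score distributions
#'
#' Standard two-sided Mann-Whitney U test with normal approximation and tie
#' correction (no continuity correction).
#'
#' @param scores_a,scores_b Numeric vectors.
#' @return list: U (pairs where a beats b, ties half), p.
#' @export
compare_distributions <- function(scores_a, scores_b) {
  if (length(scores_a) == 0L || length(scores_b) == 0L)
    stop("both samples must be non-empty")
  if (length(scores_a) < 3L || length(scores_b) < 3L)
    warning("fewer than 3 observations on one side; p unreliable")
  wt <- stats::wilcox.test(scores_a, scores_b, exact = FALSE, correct = FALSE)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Amino-acid composition ranking of a residue pool
#'
#' Rank 1 is the most frequent letter; ties are broken alphabetically, and
#' letters absent from the pool are ranked after all present letters
#' (alphabetically among themselves, which the same rule gives for count 0).
#'
#' @param pool Residue string(s), or a named count vector over the alphabet.
#' @param alphabet Alphabet to rank over (default the 20 amino acids).
#' @return Named integer vector: rank of each alphabet letter.
#' @export
composition_ranking <- function(pool, alphabet = aa_alphabet()) {
  if (is.character(pool)) {
    chars <- strsplit(paste(toupper(pool), collapse = ""), "", fixed = TRUE)[[1]]
    counts <- table(factor(chars[chars %in% alphabet], levels = alphabet))
    counts <- structure(as.integer(counts), names = alphabet)
  } else {
    counts <- structure(as.integer(pool[alphabet]), names = alphabet)
    counts[is.na(counts)] <- 0L
  }
  if (sum(counts) == 0L) stop("empty residue pool")
  ord <- order(-counts, names(counts), method = "radix")
  rk <- integer(length(alphabet))
  rk[ord] <- seq_along(ord)
  structure(rk, names = names(counts))
}

#' Per-letter rank changes between two composition rankings
#'
#' Delta(letter) = rank in reference minus rank in query; positive means the
#' letter rose (became relatively more frequent) in the query pool.
#'
#' @param query,reference Rankings from [composition_ranking()] over the
#'   same alphabet.
#' @return Named integer vector of rank changes.
#' @export
rank_changes <- function(query, reference) {
  if (!setequal(names(query), names(reference)))
    stop("rankings must cover the same alphabet")
  reference[names(query)] - query
}

#' Rank order distance (ROD) between two composition rankings
#'
#' Mean absolute rank change over the alphabet: 0 for identical orderings,
#' 10 for a full reversal of 20 letters, about 6.65 expected for a random
#' permutation of 20 ranks.
#'
#' @inheritParams rank_changes
#' @return Non-negative number.
#' @export
rod <- function(query, reference) mean(abs(rank_changes(query, reference)))
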