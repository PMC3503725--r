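#' Generate a synthetic protein database
#'
#' Draws `n_sequences` records with i.i.d. letters from `composition`
#' (default: uniform over the 20 amino acids). Sequence lengths follow the
#' chosen law; the default, 300 residues, is a typical protein length.
#' Output is fully determined by `seed`, and the exact realized letter
#' counts are returned as truth for downstream checks.
#'
#' @param n_sequences Number of records.
#' @param length_law `"fixed"`, `"uniform"` (range) or `"geometric"` (mean).
#' @param length Fixed length, c(min, max) for uniform, or mean for
#'   geometric.
#' @param composition Named probability vector over the alphabet, or NULL
#'   for uniform. Probabilities are normalized to sum to 1.
#' @param alphabet Alphabet (default 20 amino acids).
#' @param seed Integer RNG seed.
#' @return list with `corpus` (a sanitized `scs_corpus`) and `truth`
#'   (composition counts, lengths, the spec used).
#' @export
gen_protein_db <- function(n_sequences = 200L,
                           length_law = c("fixed", "uniform", "geometric"),
                           length = 300L, composition = NULL,
                           alphabet = aa_alphabet(), seed = 1L) {
  length_law <- match.arg(length_law)
  if (is.null(composition)) {
    composition <- rep(1 / length(alphabet), length(alphabet))
    names(composition) <- alphabet
  }
  if (!all(names(composition) %in% alphabet) || any(composition < 0) ||
      sum(composition) <= 0)
    stop("invalid composition")
  p <- composition[alphabet]; p[is.na(p)] <- 0
  p <- p / sum(p)
  with_seed(seed, {
    lens <- switch(length_law,
      fixed = rep(as.integer(length[1]), n_sequences),
      uniform = sample(length[1]:length[2], n_sequences, replace = TRUE),
      geometric = 1L + stats::rgeom(n_sequences, 1 / max(length[1], 1)))
    seqs <- vapply(lens, function(L)
      paste(sample(alphabet, L, replace = TRUE, prob = p), collapse = ""),
      character(1))
  })
  ids <- sprintf("syn%04d", seq_len(n_sequences))
  segments <- data.frame(id = ids, record = ids, offset = 0L,
                         residues = seqs, stringsAsFactors = FALSE)
  records <- data.frame(id = ids, length = lens, stringsAsFactors = FALSE)
  corpus <- new_corpus(segments, records, alphabet,
                       provenance = sprintf("gen_protein_db(seed=%d)", seed),
                       sanitized = TRUE)
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  comp_counts <- table(factor(chars, levels = alphabet))
  list(corpus = corpus,
       truth = list(seed = seed, n_sequences = n_sequences,
                    lengths = lens,
                    composition_counts = structure(as.integer(comp_counts),
                                                   names = alphabet),
                    composition_probs = p))
}

#' Generate a Zipfian word corpus
#'
#' Builds a vocabulary of `vocab_size` distinct words (lengths drawn from a
#' shifted Poisson so short words dominate, as in natural English) and
#' samples `n_tokens` tokens with P(rank i) proportional to i^-s by exact
#' inverse-CDF lookup over the finite vocabulary. The generating exponent
#' and realized counts are returned as truth.
#'
#' @param vocab_size Vocabulary size (>= 2).
#' @param s Zipf exponent (>= 0; s = 0 gives uniform token frequencies).
#' @param n_tokens Number of tokens to draw.
#' @param word_length_mean Mean word length of the vocabulary (>= 1).
#' @param alphabet Letter alphabet (default English).
#' @param seed Integer RNG seed.
#' @return list: `tokens`, `text` (space-separated), `compressed` (spaces
#'   removed), `truth` (s, vocabulary in rank order, realized counts).
#' @export
gen_zipf_corpus <- function(vocab_size = 5000L, s = 1, n_tokens = 1e5,
                            word_length_mean = 3.6,
                            alphabet = en_alphabet(), seed = 1L) {
  if (vocab_size < 2L) stop("vocabulary must have at least 2 words")
  if (s < 0) stop("s must be >= 0")
  with_seed(seed, {
    vocab <- character(0)
    tries <- 0L
    while (length(vocab) < vocab_size) {
      need <- vocab_size - length(vocab)
      lens <- 1L + stats::rpois(need, max(word_length_mean - 1, 0))
      new <- vapply(lens, function(L)
        paste(sample(alphabet, L, replace = TRUE), collapse = ""),
        character(1))
      vocab <- unique(c(vocab, new))
      tries <- tries + 1L
      if (tries > 1000L) stop("could not build a distinct vocabulary")
    }
    vocab <- vocab[seq_len(vocab_size)]
    p <- seq_len(vocab_size)^(-s)
    cdf <- cumsum(p) / sum(p)
    ranks <- findInterval(stats::runif(n_tokens), cdf) + 1L
    tokens <- vocab[ranks]
  })
  counts <- tabulate(ranks, nbins = vocab_size)
  list(tokens = tokens,
       text = paste(tokens, collapse = " "),
       compressed = paste(tokens, collapse = ""),
       truth = list(seed = seed, s = s, vocab = vocab,
                    rank_counts = counts, n_tokens = n_tokens))
}

#' Plant an availability-enriched motif into a protein database
#'
#' Assembles a fixed random motif of `motif_length` residues, oversamples
#' its constituent pentats into the background (each pentat overwritten into
#' `boost` random non-overlapping locations, unannotated) so those pentats
#' become high-availability words corpus-wide, and inserts the full motif at
#' `n_sites` random non-overlapping locations. Only the full-motif
#' insertions are recorded as truth intervals.
#'
#' @param db Result of [gen_protein_db()] or an `scs_corpus`.
#' @param motif_length Motif length (default 13).
#' @param n_sites Number of annotated motif insertions.
#' @param boost Background copies per constituent pentat (> 1).
#' @param seed Integer RNG seed.
#' @return list: `corpus` (modified), `motifs` (truth `motif_set`),
#'   `motif_seq`.
#' @export
plant_motifs <- function(db, motif_length = 13L, n_sites = 50L, boost = 50L,
                         seed = 1L) {
  corpus <- if (inherits(db, "scs_corpus")) db else db$corpus
  if (boost <= 1) stop("boost must be > 1")
  alphabet <- corpus$alphabet
  ids <- corpus$records$id
  lens <- corpus$records$length
  seqs <- vapply(ids, function(id) record_residues(corpus, id), character(1))
  occupied <- lapply(seq_along(ids), function(i)
    data.frame(start = integer(), end = integer()))
  names(occupied) <- ids
  place <- function(len) {
    # one random non-overlapping slot (record index, start); NULL if stalled
    for (attempt in seq_len(1e4)) {
      i <- sample.int(length(ids), 1L)
      if (lens[i] < len) next
      start <- sample.int(lens[i] - len + 1L, 1L)
      end <- start + len - 1L
      occ <- occupied[[i]]
      if (nrow(occ) && any(start <= occ$end & end >= occ$start)) next
      occupied[[i]] <<- rbind(occ, data.frame(start = start, end = end))
      return(list(i = i, start = start, end = end))
    }
    NULL
  }
  motif_rows <- list()
  with_seed(seed, {
    motif_seq <- paste(sample(alphabet, motif_length, replace = TRUE),
                       collapse = "")
    if (n_sites > 0L) {
      pentats <- if (motif_length >= 5L)
        substring(motif_seq, 1:(motif_length - 4L), 5:motif_length)
      else character(0)
      # background oversampling first, so motif sites are never overwritten
      for (pent in pentats) {
        for (b in seq_len(boost)) {
          slot <- place(5L)
          if (is.null(slot)) break
          substr(seqs[slot$i], slot$start, slot$end) <- pent
        }
      }
      placed <- 0L
      for (site in seq_len(n_sites)) {
        slot <- place(motif_length)
        if (is.null(slot)) break
        substr(seqs[slot$i], slot$start, slot$end) <- motif_seq
        placed <- placed + 1L
        motif_rows[[placed]] <- data.frame(protein = ids[slot$i],
                                           start = slot$start, end = slot$end,
                                           name = "planted",
                                           stringsAsFactors = FALSE)
      }
      if (placed < n_sites)
        warning("only ", placed, " of ", n_sites,
                " motif sites could be placed without overlap")
    }
  })
  segments <- data.frame(id = ids, record = ids, offset = 0L,
                         residues = unname(seqs), stringsAsFactors = FALSE)
  out <- new_corpus(segments, corpus$records, alphabet,
                    provenance = sprintf("plant_motifs(seed=%d)", seed),
                    sanitized = TRUE)
  truth <- if (length(motif_rows))
    as_motif_set(do.call(rbind, motif_rows), out, max_len = motif_length)
  else
    structure(data.frame(protein = character(), start = integer(),
                         end = integer(), name = character(),
                         stringsAsFactors = FALSE),
              class = c("motif_set", "data.frame"), n_rejected_long = 0L)
  list(corpus = out, motifs = truth, motif_seq = motif_seq)
}
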