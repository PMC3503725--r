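#' Prefix occurrence counts of a word
#'
#' For an m-letter word a_0..a_{m-1}, returns x_k = how many times the
#' letter a_k already appears among the preceding letters a_0..a_{k-1}.
#' These enter the without-replacement expected-count model: having used a
#' copy of a letter in the word, one fewer copy remains in the database.
#'
#' @param word A single word (character scalar).
#' @return Integer vector of length nchar(word).
#' @export
occurrence_prefix_counts <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  m <- length(chars)
  x <- integer(m)
  for (j in seq_len(m))
    x[j] <- sum(chars[seq_len(j - 1L)] == chars[j])
  x
}

# split words into an (n_words x k) letter matrix
word_letter_matrix <- function(words, k) {
  mat <- matrix("", nrow = length(words), ncol = k)
  for (j in seq_len(k)) mat[, j] <- substring(words, j, j)
  mat
}

#' Expected count of a word under a random-arrangement null
#'
#' The expected number of sliding-window occurrences of `word` in the
#' corpus summarized by `dict`, were its letters arranged uniformly at
#' random.
#'
#' The default `"elaborate"` model draws letters without replacement:
#' \deqn{E = t \prod_{k=0}^{m-1} \frac{n_k - x_k}{T - k}}
#' where T is the total letter count, t the total window count, n_k the
#' corpus count of the word's k-th letter and x_k its multiplicity among the
#' preceding letters of the word. The `"simple"` model is the
#' with-replacement limit \eqn{E = t \prod_k n_k / T}; the two converge as T
#' grows at fixed letter frequencies.
#'
#' Words whose letters cannot all be supplied by the corpus (a letter absent,
#' or more copies needed than exist) have no defined availability ratio and
#' are returned as `NA`.
#'
#' @param words Character vector of words, each of length `dict$k`.
#' @param dict An `scs_dict` built at the same word length.
#' @param model `"elaborate"` (without replacement, default) or `"simple"`.
#' @return Numeric vector of expected counts (NA where undefined).
#' @export
expected_count <- function(words, dict, model = c("elaborate", "simple")) {
  model <- match.arg(model)
  stopifnot(inherits(dict, "scs_dict"))
  m <- dict$k
  if (any(nchar(words) != m))
    stop("all words must have length k = ", m)
  if (dict$T < m) stop("corpus has fewer than k letters (T = ", dict$T, ")")
  L <- word_letter_matrix(words, m)
  bad <- !(L %in% names(dict$composition))
  if (any(bad)) stop("word letter outside dictionary alphabet: ",
                     paste(unique(L[bad]), collapse = ", "))
  n <- matrix(dict$composition[L], nrow = length(words), ncol = m)
  if (model == "simple") {
    E <- dict$t * apply(n / dict$T, 1L, prod)
  } else {
    x <- matrix(0L, nrow = length(words), ncol = m)
    if (m > 1L)
      for (j in 2:m)
        for (i in seq_len(j - 1L))
          x[, j] <- x[, j] + (L[, i] == L[, j])
    num <- n - x
    denom <- dict$T - (seq_len(m) - 1L)
    E <- dict$t * apply(sweep(num, 2L, denom, "/"), 1L, prod)
    E[apply(num <= 0, 1L, any)] <- NA_real_
  }
  E[E <= 0] <- NA_real_
  unname(E)
}

#' Availability score of words
#'
#' A = R/E: the real (observed) window count R of a word relative to its
#' expected count E under the random-arrangement null. A > 1 marks over-used
#' "words", A = 0 words that never occur. Words with undefined E are NA, not
#' 0. A difference variant R - E is available for sensitivity checks.
#'
#' @param words Character vector of words of length `dict$k`.
#' @param dict An `scs_dict`.
#' @param method `"ratio"` (default) or `"difference"`.
#' @param model Expected-count model passed to [expected_count()].
#' @return Numeric vector of availability scores.
#' @export
availability_score <- function(words, dict, method = c("ratio", "difference"),
                               model = c("elaborate", "simple")) {
  method <- match.arg(method)
  E <- expected_count(words, dict, model = model)
  R <- dict$counts[words]
  R[is.na(R)] <- 0L
  A <- if (method == "ratio") unname(R) / E else unname(R) - E
  unname(A)
}

#' Build the availability database for all observed SCSs
#'
#' One row per observed word, ordered by descending availability (ties
#' lexicographic). The dictionary metadata (k, T, t, composition) is carried
#' in attributes so profiles can detect unscorable query words.
#'
#' @param dict An `scs_dict`.
#' @param method,model Passed to [availability_score()].
#' @return data.frame of class `avail_table` with columns scs, R, E, A.
#' @export
build_availability_table <- function(dict, method = c("ratio", "difference"),
                                     model = c("elaborate", "simple")) {
  method <- match.arg(method); model <- match.arg(model)
  words <- names(dict$counts)
  if (is.null(words)) words <- character(0)
  E <- if (length(words)) expected_count(words, dict, model = model) else numeric(0)
  R <- unname(dict$counts)
  A <- if (method == "ratio") R / E else R - E
  tab <- data.frame(scs = words, R = R, E = E, A = A, stringsAsFactors = FALSE)
  ord <- order(-tab$A, tab$scs, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("avail_table", "data.frame"),
            k = dict$k, T = dict$T, t = dict$t,
            composition = dict$composition, alphabet = dict$alphabet,
            method = method, model = model)
}

#' Availability profile of a query sequence
#'
#' Assigns the availability score of every k-window along a query to its
#' start position, then rescales to the relative availability rA: the
#' largest score in the query is set to 100% and the rest proportionally
#' adjusted. Window positions are 1-based starts on the original record;
#' non-standard letters split the query and windows never span a split.
#' Words absent from the table get A = 0; words containing letters the
#' training corpus lacks are unscorable (A = NA) and are excluded from the
#' rA normalization.
#'
#' @param query Residue string, or a one-row slice of `corpus$segments`.
#' @param table An `avail_table`.
#' @param k Word length; defaults to the table's.
#' @param id Query label used in the result.
#' @return data.frame of class `avail_profile` with columns position, scs,
#'   A, rA.
#' @export
availability_profile <- function(query, table, k = attr(table, "k"),
                                 id = "query") {
  stopifnot(inherits(table, "avail_table"))
  if (k != attr(table, "k"))
    stop("table was built at k = ", attr(table, "k"), ", not k = ", k)
  residues <- toupper(query)
  segs <- sanitize_record(id, residues, attr(table, "alphabet"))
  prof <- data.frame(position = integer(), scs = character(),
                     A = numeric(), rA = numeric(), stringsAsFactors = FALSE)
  if (nchar(residues) < k) {
    warning("query shorter than k: empty profile")
  } else if (nrow(segs) > 0L) {
    pieces <- lapply(seq_len(nrow(segs)), function(i) {
      w <- extract_windows(segs$residues[i], k)
      if (nrow(w)) w$position <- w$start + segs$offset[i]
      w
    })
    w <- do.call(rbind, pieces)
    if (!is.null(w) && nrow(w)) {
      lookup <- structure(table$A, names = table$scs)
      A <- unname(lookup[w$scs])
      A[is.na(A)] <- 0
      # letters in the corpus support set: composition > 0
      supported <- names(attr(table, "composition"))[attr(table, "composition") > 0]
      unscorable <- vapply(strsplit(w$scs, "", fixed = TRUE),
                           function(ch) any(!ch %in% supported), logical(1))
      A[unscorable] <- NA_real_
      maxA <- suppressWarnings(max(A, na.rm = TRUE))
      rA <- if (is.finite(maxA) && maxA > 0) 100 * A / maxA else
        ifelse(is.na(A), NA_real_, 0)
      prof <- data.frame(position = w$position, scs = w$scs, A = A, rA = rA,
                         stringsAsFactors = FALSE)
      prof <- prof[order(prof$position), , drop = FALSE]
      rownames(prof) <- NULL
    }
  }
  structure(prof, class = c("avail_profile", "data.frame"),
            k = k, query_id = id, query_length = nchar(residues))
}

#' Write an availability table or profile as TSV
#'
#' Expected counts and scores are printed at 6 significant digits;
#' spreadsheet-friendly plain TSV with a header row.
#'
#' @param x An `avail_table` or `avail_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_avail_tsv <- function(x, path) {
  df <- as.data.frame(x)
  for (col in intersect(c("E", "A", "rA"), names(df)))
    df[[col]] <- signif(df[[col]], 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an availability table written by [write_avail_tsv()]
#'
#' Reconstructs the `avail_table` attributes from a companion dictionary.
#'
#' @param path TSV path.
#' @param dict The `scs_dict` the table was built from.
#' @return An `avail_table`.
#' @export
read_avail_table <- function(path, dict) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "numeric",
                                         "numeric"))
  structure(df, class = c("avail_table", "data.frame"),
            k = dict$k, T = dict$T, t = dict$t,
            composition = dict$composition, alphabet = dict$alphabet,
            method = "ratio", model = "elaborate")
}
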