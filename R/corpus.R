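#' The 20-letter standard amino-acid alphabet
#'
#' Returns the one-letter codes of the 20 standard amino acids, in
#' alphabetical order. This is the default alphabet for protein corpora;
#' any other letter (X, U, B, Z, J, O, ...) is treated as non-standard and
#' terminates a segment during sanitization.
#'
#' @return Character vector of 20 single letters.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' The 26-letter English alphabet
#'
#' @return Character vector `LETTERS`.
#' @export
en_alphabet <- function() LETTERS

new_corpus <- function(segments, records, alphabet, provenance = "",
                       sanitized = FALSE) {
  stopifnot(is.data.frame(segments),
            all(c("id", "record", "offset", "residues") %in% names(segments)))
  structure(
    list(segments = segments, records = records, alphabet = alphabet,
         provenance = provenance, sanitized = sanitized),
    class = "scs_corpus"
  )
}

#' @export
print.scs_corpus <- function(x, ...) {
  cat(sprintf("<scs_corpus> %d record(s), %d segment(s), %d letters (%s)\n",
              nrow(x$records), nrow(x$segments),
              sum(nchar(x$segments$residues)),
              if (x$sanitized) "sanitized" else "unsanitized"))
  cat("  alphabet:", paste(x$alphabet, collapse = ""), "\n")
  if (nzchar(x$provenance)) cat("  source:", x$provenance, "\n")
  invisible(x)
}

#' Total letter count of a corpus
#' @param corpus An `scs_corpus`.
#' @return Integer, summed segment lengths.
#' @export
corpus_letters <- function(corpus) sum(nchar(corpus$segments$residues))

#' Read a multi-record FASTA file into a corpus
#'
#' Residues are upper-cased and line breaks removed; record order is
#' preserved. The result is *unsanitized*: residues may contain letters
#' outside the declared alphabet until [sanitize_corpus()] is applied.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Declared alphabet (default: the 20 amino acids).
#' @return An `scs_corpus` with one segment per FASTA record.
#' @export
read_fasta <- function(path, alphabet = aa_alphabet()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("FASTA file is empty: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(trimws(first), ">"))
    stop("not a FASTA file (first record has no '>' header): ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  res <- toupper(as.character(seqs))
  segments <- data.frame(id = ids, record = ids, offset = 0L,
                         residues = unname(res), stringsAsFactors = FALSE)
  records <- data.frame(id = ids, length = nchar(res), stringsAsFactors = FALSE)
  new_corpus(segments, records, alphabet, provenance = path)
}

#' Split one record at non-alphabet letters
#'
#' A residue outside the alphabet ends the current segment; analysis
#' resumes at the next alphabet letter. Non-alphabet characters belong to
#' no segment and are discarded; empty segments are dropped. Segment ids are
#' the record id plus an ordinal suffix, and each segment records its 0-based
#' offset on the original record so window positions can be mapped back.
#'
#' @param id Record identifier.
#' @param residues Upper-case residue string.
#' @param alphabet Character vector of allowed letters.
#' @return data.frame with columns id, record, offset, residues (possibly
#'   zero rows).
#' @export
sanitize_record <- function(id, residues, alphabet = aa_alphabet()) {
  empty <- data.frame(id = character(), record = character(),
                      offset = integer(), residues = character(),
                      stringsAsFactors = FALSE)
  if (nchar(residues) == 0L) return(empty)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  ok <- chars %in% alphabet
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    id = paste0(id, ".", seq_along(keep)),
    record = id,
    offset = starts[keep] - 1L,
    residues = vapply(keep, function(i)
      paste(chars[starts[i]:ends[i]], collapse = ""), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Sanitize every record of a corpus
#'
#' @param corpus An unsanitized `scs_corpus` (e.g. from [read_fasta()]).
#' @param alphabet Alphabet to enforce; defaults to the corpus's own.
#' @return A sanitized `scs_corpus`; records with no standard residues
#'   contribute zero segments.
#' @export
sanitize_corpus <- function(corpus, alphabet = corpus$alphabet) {
  pieces <- lapply(seq_len(nrow(corpus$segments)), function(i)
    sanitize_record(corpus$segments$record[i], corpus$segments$residues[i],
                    alphabet))
  segments <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(segments) || nrow(segments) == 0L)
    segments <- data.frame(id = character(), record = character(),
                           offset = integer(), residues = character(),
                           stringsAsFactors = FALSE)
  new_corpus(segments, corpus$records, alphabet,
             provenance = corpus$provenance, sanitized = TRUE)
}

#' Normalize free text into a letter corpus
#'
#' Keeps ASCII letters only, upper-cases them, and either compresses each
#' input block into one unbroken segment (no inter-word spaces, the
#' "compressed" mode used for fixed-length word windows) or retains
#' whitespace-delimited word tokens as individual segments. Punctuation
#' (including hyphens and apostrophes) is deleted, never treated as a word
#' break.
#'
#' @param text Character vector; each element is one input block.
#' @param compress_spaces If TRUE, one segment per block with spaces removed;
#'   if FALSE, one segment per word token.
#' @return An `scs_corpus` over the 26-letter alphabet (sanitized by
#'   construction).
#' @export
normalize_text <- function(text, compress_spaces = FALSE) {
  text <- toupper(text)
  # delete everything that is neither a letter nor whitespace
  kept <- gsub("[^A-Z[:space:]]+", "", text)
  if (compress_spaces) {
    segs <- gsub("[[:space:]]+", "", kept)
    ids <- paste0("block", seq_along(segs))
    keep <- nzchar(segs)
    segments <- data.frame(id = ids[keep], record = ids[keep],
                           offset = rep(0L, sum(keep)),
                           residues = segs[keep], stringsAsFactors = FALSE)
  } else {
    toks <- tokenize_words(kept)
    segments <- data.frame(
      id = if (length(toks)) paste0("w", seq_along(toks)) else character(),
      record = if (length(toks)) paste0("w", seq_along(toks)) else character(),
      offset = rep(0L, length(toks)), residues = toks,
      stringsAsFactors = FALSE)
  }
  records <- data.frame(id = segments$id, length = nchar(segments$residues),
                        stringsAsFactors = FALSE)
  new_corpus(segments, records, en_alphabet(),
             provenance = "normalized text", sanitized = TRUE)
}

#' Tokenize normalized text into words
#'
#' Maximal runs of letters are tokens; order is preserved.
#'
#' @param text Character vector of (normalized, space-retaining) text.
#' @return Character vector of upper-case word tokens.
#' @export
tokenize_words <- function(text) {
  m <- regmatches(toupper(text), gregexpr("[A-Z]+", toupper(text)))
  unlist(m, use.names = FALSE)
}

#' Sliding k-letter windows of a segment
#'
#' Windows start at every position 1..len-k+1 (1-based, inclusive
#' coordinates on the segment).
#'
#' @param residues A residue string.
#' @param k Window length (>= 1).
#' @return data.frame with columns `start` and `scs`; zero rows when the
#'   segment is shorter than `k`.
#' @export
extract_windows <- function(residues, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a positive integer")
  n <- nchar(residues)
  if (n < k)
    return(data.frame(start = integer(), scs = character(),
                      stringsAsFactors = FALSE))
  starts <- seq_len(n - k + 1L)
  data.frame(start = starts, scs = substring(residues, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Summarize a corpus as a plain list (JSON-friendly)
#'
#' @param corpus An `scs_corpus`.
#' @return list with record count, segment count, letter count and alphabet.
#' @export
corpus_summary <- function(corpus) {
  list(records = nrow(corpus$records),
       segments = nrow(corpus$segments),
       letters = corpus_letters(corpus),
       alphabet = paste(corpus$alphabet, collapse = ""),
       sanitized = corpus$sanitized)
}
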