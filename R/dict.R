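new_scs_dict <- function(k, counts, composition, T_total, t_total, alphabet) {
  structure(
    list(k = k, counts = counts, composition = composition,
         T = T_total, t = t_total, alphabet = alphabet),
    class = "scs_dict"
  )
}

#' @export
print.scs_dict <- function(x, ...) {
  cat(sprintf("<scs_dict> k=%d: %d distinct SCS, t=%d windows over T=%d letters (r=%.4g)\n",
              x$k, length(x$counts), x$t, x$T, scs_ratio(x)))
  invisible(x)
}

#' Window-to-letter ratio t/T of a dictionary
#' @param dict An `scs_dict`.
#' @return t/T (NA when the corpus is empty).
#' @export
scs_ratio <- function(dict) if (dict$T > 0) dict$t / dict$T else NA_real_

#' Build the dictionary of word occurrence
#'
#' Counts every k-letter window (SCS) over all segments of a sanitized
#' corpus, together with the corpus letter composition. Only observed SCSs
#' are stored (sparse map); the full 20^k key space is never materialized.
#'
#' @param corpus A sanitized `scs_corpus`.
#' @param k Word length (1..6 by default; raise `max_k` to go beyond).
#' @param max_k Soft cap on `k`.
#' @return An `scs_dict` with fields `k`, `counts` (named vector, observed
#'   SCSs only, lexicographic order), `composition` (letter counts over the
#'   full alphabet), `T` (total letters) and `t` (total windows).
#' @export
count_scs <- function(corpus, k, max_k = 6L) {
  stopifnot(inherits(corpus, "scs_corpus"))
  if (!corpus$sanitized)
    stop("corpus must be sanitized before counting (see sanitize_corpus)")
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  if (k > max_k) stop("k = ", k, " exceeds the cap max_k = ", max_k)
  alphabet <- corpus$alphabet
  segs <- corpus$segments$residues
  T_total <- sum(nchar(segs))
  if (T_total == 0L) {
    warning("empty corpus: dictionary has T = t = 0")
    comp <- integer(length(alphabet)); names(comp) <- alphabet
    return(new_scs_dict(as.integer(k), integer(0), comp, 0L, 0L, alphabet))
  }
  comp_tab <- table(factor(strsplit(paste(segs, collapse = ""), "",
                                    fixed = TRUE)[[1]], levels = alphabet))
  comp <- as.integer(comp_tab); names(comp) <- alphabet
  words <- unlist(lapply(segs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  t_total <- length(words)
  if (t_total == 0L) {
    counts <- integer(0)
  } else {
    tab <- table(words)
    counts <- as.integer(tab)
    names(counts) <- names(tab)  # table() sorts keys lexicographically
  }
  new_scs_dict(as.integer(k), counts, comp, as.integer(T_total),
               as.integer(t_total), alphabet)
}

#' Merge dictionaries built from chunks of a corpus
#'
#' Fieldwise sums; associative and commutative. All dictionaries must share
#' the same word length and alphabet.
#'
#' @param dicts List of `scs_dict` objects.
#' @return A single merged `scs_dict`.
#' @export
merge_scs_dicts <- function(dicts) {
  stopifnot(length(dicts) >= 1L, all(vapply(dicts, inherits, TRUE, "scs_dict")))
  k <- dicts[[1]]$k
  alphabet <- dicts[[1]]$alphabet
  for (d in dicts) {
    if (d$k != k) stop("cannot merge dictionaries with different k")
    if (!identical(d$alphabet, alphabet))
      stop("cannot merge dictionaries with different alphabets")
  }
  all_counts <- unlist(lapply(dicts, `[[`, "counts"))
  if (length(all_counts)) {
    merged <- tapply(all_counts, names(all_counts), sum)
    counts <- as.integer(merged[sort(names(merged))])
    names(counts) <- sort(names(merged))
  } else counts <- integer(0)
  comp <- Reduce(`+`, lapply(dicts, `[[`, "composition"))
  new_scs_dict(k, counts, comp,
               sum(vapply(dicts, `[[`, integer(1), "T")),
               sum(vapply(dicts, `[[`, integer(1), "t")),
               alphabet)
}

#' Write / read a dictionary as TSV
#'
#' Two-column TSV (`scs`, `count`) preceded by `#`-prefixed header lines
#' carrying `k`, `T`, `t`, the alphabet and the letter composition, so the
#' round trip is exact.
#'
#' @param dict An `scs_dict`.
#' @param path Output path.
#' @return `write_scs_dict` returns `path` invisibly; `read_scs_dict`
#'   returns the reconstructed `scs_dict`.
#' @export
write_scs_dict <- function(dict, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# k=%d", dict$k),
    sprintf("# T=%d", dict$T),
    sprintf("# t=%d", dict$t),
    sprintf("# alphabet=%s", paste(dict$alphabet, collapse = "")),
    sprintf("# composition=%s",
            paste(sprintf("%s:%d", names(dict$composition), dict$composition),
                  collapse = ","))
  ), con)
  writeLines("scs\tcount", con)
  if (length(dict$counts))
    writeLines(sprintf("%s\t%d", names(dict$counts), dict$counts), con)
  invisible(path)
}

#' @rdname write_scs_dict
#' @export
read_scs_dict <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, "="), "",
                           grep(paste0("^# ", key, "="), hdr, value = TRUE))
  k <- as.integer(get("k")); T_total <- as.integer(get("T"))
  t_total <- as.integer(get("t"))
  alphabet <- strsplit(get("alphabet"), "", fixed = TRUE)[[1]]
  comp_pairs <- strsplit(strsplit(get("composition"), ",", fixed = TRUE)[[1]],
                         ":", fixed = TRUE)
  comp <- as.integer(vapply(comp_pairs, `[`, character(1), 2))
  names(comp) <- vapply(comp_pairs, `[`, character(1), 1)
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                          sep = "\t", colClasses = c("character", "integer"))
  counts <- df$count; names(counts) <- df$scs
  new_scs_dict(k, counts, comp, T_total, t_total, alphabet)
}
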