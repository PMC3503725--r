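# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Write a corpus to a FASTA file
#'
#' One record per corpus record; sanitized corpora are written with their
#' original record residues reconstructed (sanitization gaps as `-`).
#' Output is deterministic, 60 columns per sequence line.
#'
#' @param corpus An `scs_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in corpus$records$id) {
    res <- record_residues(corpus, id)
    writeLines(paste0(">", id), con)
    n <- nchar(res)
    starts <- seq(1L, max(n, 1L), by = 60L)
    writeLines(substring(res, starts, pmin(starts + 59L, n)), con)
  }
  invisible(path)
}
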