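#' Rank-frequency table of word counts
#'
#' Orders items by descending count (ties broken lexicographically by item,
#' so ranking is deterministic) and attaches base-10 logs of rank and count
#' for the log-log plot.
#'
#' @param x An `scs_dict`, or a named numeric vector of counts.
#' @return data.frame of class `rank_freq` with columns rank, item, count,
#'   logR, logN.
#' @export
rank_frequency <- function(x) {
  counts <- if (inherits(x, "scs_dict")) x$counts else x
  if (length(counts) == 0L) stop("no items to rank")
  if (is.null(names(counts))) stop("counts must be named by item")
  ord <- order(-counts, names(counts), method = "radix")
  df <- data.frame(rank = seq_along(counts),
                   item = names(counts)[ord],
                   count = unname(counts[ord]),
                   stringsAsFactors = FALSE)
  df$logR <- log10(df$rank)
  df$logN <- log10(df$count)
  structure(df, class = c("rank_freq", "data.frame"))
}

#' Least-squares line on the log-log rank-frequency plot
#'
#' Ordinary least squares of logN on logR over all rows: the power law
#' y = a x^-b appears as Y = log10(a) - b X. The correlation coefficient is
#' reported as a magnitude.
#'
#' @param table A `rank_freq` table.
#' @return list of class `loglog_fit`: a, b (exponent, = minus the slope),
#'   r (|Pearson|), intercept (log10 a), and the centroid of the fitted
#'   points.
#' @export
fit_loglog <- function(table) {
  stopifnot(inherits(table, "rank_freq"))
  if (length(unique(table$logR)) < 2L)
    stop("need at least two distinct ranks to fit")
  fit <- stats::lm(logN ~ logR, data = table)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- if (stats::sd(table$logN) == 0) 1 else
    abs(stats::cor(table$logR, table$logN))
  structure(
    list(a = 10^intercept, b = -slope, r = r, intercept = intercept,
         centroid_x = mean(table$logR), centroid_y = mean(table$logN),
         n = nrow(table)),
    class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("<loglog_fit> y = %.3g * x^-%.3g  (r = %.3f, n = %d)\n",
              x$a, x$b, x$r, x$n))
  invisible(x)
}

#' Linear range of a rank-frequency distribution
#'
#' Determines the contiguous stretch of the distribution that stays within a
#' band of +/- `band` around the best-fit exponent. The two bounding lines
#' have slopes -(b - band) and -(b + band) and pass through the best-fit
#' line at the centroid of the fitted logR values (where an OLS line always
#' passes); a row is inside when its logN lies between the two lines at its
#' logR, inclusive. The linear range is the longest contiguous run of inside
#' rows; widths are reported in decades on both axes.
#'
#' @param table A `rank_freq` table.
#' @param fit The `loglog_fit` computed on the same table.
#' @param band Exponent half-width of the band (default 0.15).
#' @param pivot_x Abscissa where the bounding lines cross the best-fit line;
#'   default the centroid of the fitted points.
#' @return list of class `linear_range`: x_lo, x_hi, width_x, y_lo, y_hi,
#'   width_y, band, plus the row indices of the run.
#' @export
linear_range <- function(table, fit, band = 0.15, pivot_x = fit$centroid_x) {
  stopifnot(inherits(table, "rank_freq"), inherits(fit, "loglog_fit"))
  pivot_y <- fit$intercept - fit$b * pivot_x
  s1 <- -(fit$b - band); s2 <- -(fit$b + band)
  y1 <- pivot_y + s1 * (table$logR - pivot_x)
  y2 <- pivot_y + s2 * (table$logR - pivot_x)
  lo <- pmin(y1, y2); hi <- pmax(y1, y2)
  eps <- 1e-9 * pmax(1, abs(hi))
  inside <- table$logN >= lo - eps & table$logN <= hi + eps
  runs <- rle(inside)
  if (!any(runs$values)) {
    return(structure(list(x_lo = NA_real_, x_hi = NA_real_, width_x = 0,
                          y_lo = NA_real_, y_hi = NA_real_, width_y = 0,
                          band = band, rows = integer(0)),
                     class = "linear_range"))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  rows <- starts[best]:ends[best]
  x <- table$logR[rows]; y <- table$logN[rows]
  structure(list(x_lo = min(x), x_hi = max(x), width_x = max(x) - min(x),
                 y_lo = min(y[c(1L, length(y))]),
                 y_hi = max(y[c(1L, length(y))]),
                 width_y = abs(y[length(y)] - y[1L]),
                 band = band, rows = rows),
            class = "linear_range")
}

#' @export
print.linear_range <- function(x, ...) {
  cat(sprintf("<linear_range> X: %.2f-%.2f (width %.2f)  Y: %.2f-%.2f (width %.2f)  band +/-%.2f\n",
              x$x_lo, x$x_hi, x$width_x, x$y_lo, x$y_hi, x$width_y, x$band))
  invisible(x)
}

#' Two-decades scale-free criterion
#'
#' TRUE when the linear width spans at least two orders of magnitude on both
#' axes (the Stumpf-Porter requirement for calling a distribution
#' scale-free). The boundary is inclusive.
#'
#' @param range A `linear_range`.
#' @return logical flag.
#' @export
passes_two_decades <- function(range) {
  stopifnot(inherits(range, "linear_range"))
  isTRUE(range$width_x >= 2 && range$width_y >= 2)
}

#' Truncation sweep of the power-law discriminant
#'
#' Keeps only the highest-count (top-rank) fraction of the table and
#' recomputes the power-law-versus-exponential discriminant, tracing how the
#' low-rank tail drives the verdict.
#'
#' @param table A `rank_freq` table.
#' @param keep_fractions Percentages of top ranks to keep, in (0, 100].
#' @param min_rows Minimum rows required for a discriminant fit; smaller
#'   truncations are flagged insufficient.
#' @return data.frame with columns fraction, n_kept, R_disc, p,
#'   insufficient; fractions sorted descending.
#' @export
truncation_sweep <- function(table, keep_fractions = c(100, 75, 50, 25, 10),
                             min_rows = 10L) {
  stopifnot(inherits(table, "rank_freq"))
  if (any(keep_fractions <= 0 | keep_fractions > 100))
    stop("keep_fractions must lie in (0, 100]")
  keep_fractions <- sort(keep_fractions, decreasing = TRUE)
  n <- nrow(table)
  rows <- lapply(keep_fractions, function(f) {
    n_keep <- ceiling(f * n / 100)
    kept <- table$count[seq_len(n_keep)]
    if (n_keep < min_rows || length(unique(kept)) == 1L)
      return(data.frame(fraction = f, n_kept = n_keep, R_disc = NA_real_,
                        p = NA_real_, insufficient = TRUE))
    d <- discriminant_R(kept)
    data.frame(fraction = f, n_kept = n_keep, R_disc = d$R_disc, p = d$p,
               insufficient = FALSE)
  })
  do.call(rbind, rows)
}

#' Word-length histogram of a token stream
#'
#' @param tokens Character vector of word tokens.
#' @return list with `histogram` (named count vector over observed lengths),
#'   `mode` (smallest length achieving the maximum) and `mean`.
#' @export
word_length_histogram <- function(tokens) {
  if (length(tokens) == 0L) stop("no tokens")
  len <- nchar(tokens)
  tab <- table(len)
  lengths <- as.integer(names(tab))
  list(histogram = structure(as.integer(tab), names = names(tab)),
       mode = min(lengths[tab == max(tab)]),
       mean = mean(len))
}
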