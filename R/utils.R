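`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers do not disturb the
#' caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed for a named stage from a master seed.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Otsu threshold of a numeric vector
#'
#' Histogram-based between-class variance maximisation on a 1-D sample, used to
#' split per-cell mean intensities into negative and positive populations.
#'
#' @param x numeric vector (at least two distinct values).
#' @param n_bins number of histogram bins.
#' @return the threshold value; elements `> threshold` are "positive".
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0)
    stop("otsu_threshold() needs at least 2 finite values with unequal intensities; ",
         "use fixed thresholds instead")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                           nbins = n_bins))
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / w1
  m2 <- (sum(h * mids) - cumsum(h * mids)) / w2
  bcv <- w1 * w2 * (m1 - m2)^2
  bcv[w1 == 0 | w2 == 0] <- -Inf
  breaks[which.max(bcv) + 1L]
}

logistic_gradient <- function(d, p_near, p_far, midpoint, steepness) {
  p_near + (p_far - p_near) / (1 + exp(-(d - midpoint) / steepness))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name))
  invisible(x)
}
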