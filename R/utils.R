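#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm runif rpois sd cor dist hclust cutree quantile setNames
#' @importFrom utils write.csv read.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' All stochastic code in the package routes its randomness through an
#' explicit integer seed; the caller's RNG state is saved and restored so
#' generation never perturbs global state.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; kept below 2^31 - 1.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629)
}

#' Otsu threshold for an arbitrary numeric vector
#'
#' Histogram-based maximisation of between-class variance over `levels`
#' equal-width bins spanning the data range. Unlike image-specific
#' implementations this makes no assumption about the value range, so the
#' same routine thresholds optical-density images and per-cell feature
#' vectors.
#'
#' @param x numeric vector (or matrix) of finite values.
#' @param levels number of histogram bins.
#' @return The threshold value (a scalar); `NA` if `x` is constant.
#' @export
otsuThreshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  r <- range(x)
  if (diff(r) <= 0) return(NA_real_)
  edges <- seq(r[1], r[2], length.out = levels + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > levels] <- levels
  counts <- tabulate(bin, nbins = levels)
  p <- counts / sum(counts)
  mids <- (edges[-1L] + edges[-(levels + 1L)]) / 2
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[levels]
  sb <- (muT * w1 - mu)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-levels])
  edges[k + 1L]
}

# Coefficient of variation; guards data-driven thresholds against unimodal
# (effectively constant) inputs.
coefVar <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(0)
  sd(x) / m
}

# Pixel indices of a filled disc clipped to a (w x h) image; 0-based centre
# coordinates, pixel-centre convention. Returns a 2-column 1-based index
# matrix suitable for matrix indexing.
discIndex <- function(cx, cy, r, w, h) {
  x0 <- max(0L, floor(cx - r)); x1 <- min(w - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(h - 1L, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(matrix(integer(0), ncol = 2))
  xs <- x0:x1; ys <- y0:y1
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  cbind(g$x[keep] + 1L, g$y[keep] + 1L)
}

# Clamp values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

asMatrix <- function(x) {
  if (is(x, "Image")) x <- EBImage::imageData(x)
  if (length(dim(x)) > 2L) stop("expected a single-channel 2-D image")
  as.matrix(x)
}
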