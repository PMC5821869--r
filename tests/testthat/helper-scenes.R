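# Shared helpers: small scene builders and a brute-force deconvolution
# oracle used across test files.

# per-pixel least-squares deconvolution, solved one pixel at a time with
# qr.solve (independent of the vectorised pseudo-inverse implementation)
bruteDeconvolve <- function(od, stains) {
  M <- stains@vectors
  d <- dim(od)
  V <- matrix(od, ncol = 3L)
  C <- t(apply(V, 1L, function(v) qr.solve(t(M), v)))
  if (nrow(M) == 1L) C <- matrix(C, ncol = 1L)
  C[C < 0] <- 0
  out <- lapply(seq_len(nrow(M)), function(i) matrix(C[, i], d[1L], d[2L]))
  names(out) <- stainNames(stains)
  out
}

# brute-force single-linkage foci: connected components of the graph with
# an edge between every pair closer than the linking distance (union-find)
bruteFoci <- function(cells, geometry, linkingDistanceUm, minFocusSize) {
  n <- nrow(cells)
  if (n == 0L) return(integer(0))
  um <- cbind(cells$x, cells$y) * geometry@micronsPerPixel
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sqrt(sum((um[i, ] - um[j, ])^2)) <= linkingDistanceUm) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  sizes <- tabulate(comp)
  ifelse(sizes[comp] >= minFocusSize, comp, 0L)
}

# paint a disc of constant value into a matrix (0-based centre)
paintTestDisc <- function(mat, cx, cy, r, value) {
  w <- nrow(mat); h <- ncol(mat)
  g <- expand.grid(x = seq_len(w) - 1L, y = seq_len(h) - 1L)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  mat[cbind(g$x[keep] + 1L, g$y[keep] + 1L)] <- value
  mat
}
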