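#' Built-in stain optical-density vectors
#'
#' Unit-norm RGB absorbance vectors for the stains the pipeline handles.
#' Haematoxylin, eosin and DAB use the published Ruifrok-Johnston
#' deconvolution values; the Sirius Red vector was estimated from a
#' synthetic pure-stain swatch (a saturated picro-sirius red) and is, like
#' all vectors, overridable via [readStainConfig()].
#'
#' @param stains character vector of stain names to include; any of
#'   `"haematoxylin"`, `"eosin"`, `"dab"`, `"sirius_red"`.
#' @return A [StainMatrix-class] with the requested stains, in order.
#' @examples
#' defaultStains(c("haematoxylin", "dab"))
#' @export
defaultStains <- function(stains = c("haematoxylin", "dab")) {
  known <- rbind(
    haematoxylin = c(0.650, 0.704, 0.286),   # Ruifrok-Johnston
    eosin        = c(0.072, 0.990, 0.105),   # Ruifrok-Johnston
    dab          = c(0.268, 0.570, 0.776),   # Ruifrok-Johnston
    sirius_red   = c(0.241, 0.777, 0.582))   # measured from pure-stain swatch
  bad <- setdiff(stains, rownames(known))
  if (length(bad)) stop("unknown stain(s): ", paste(bad, collapse = ", "))
  stainMatrix(known[stains, , drop = FALSE])
}

#' Convert an RGB image to per-channel optical density
#'
#' Beer-Lambert transform: `od = -log10(max(I, eps) / I0)` per channel,
#' with `eps = I0/255` so saturated-black pixels map to a finite maximum
#' OD of log10(255) ~ 2.41. Background (white) pixels map to OD 0.
#'
#' @param image numeric array `width x height x 3` with intensities in
#'   `[0, backgroundIntensity]`, or a `width x height` matrix for a single
#'   channel.
#' @param backgroundIntensity incident-light intensity I0 (default 255 for
#'   8-bit images).
#' @return Array (or matrix) of the same shape holding optical densities.
#' @examples
#' rgbToOd(array(255, c(2, 2, 3)))    # white -> OD 0
#' @export
rgbToOd <- function(image, backgroundIntensity = 255) {
  if (!is.numeric(backgroundIntensity) || length(backgroundIntensity) != 1L ||
      !is.finite(backgroundIntensity) || backgroundIntensity <= 0)
    stop("'backgroundIntensity' must be a single positive number")
  image <- unclass(image)
  if (any(image < 0 | image > backgroundIntensity, na.rm = TRUE))
    stop("image intensities must lie in [0, backgroundIntensity]")
  eps <- backgroundIntensity / 255
  -log10(pmax(image, eps) / backgroundIntensity)
}

#' Convert optical density back to transmitted intensity
#'
#' Inverse Beer-Lambert: `I = I0 * 10^(-od)`, clipped to
#' `[0, backgroundIntensity]`.
#'
#' @param od numeric array/matrix of non-negative finite optical densities.
#' @param backgroundIntensity incident-light intensity I0.
#' @return Intensity array of the same shape.
#' @export
odToRgb <- function(od, backgroundIntensity = 255) {
  if (any(!is.finite(od))) stop("optical densities must be finite")
  if (any(od < 0)) stop("optical densities must be non-negative")
  clamp(backgroundIntensity * 10^(-od), 0, backgroundIntensity)
}

stainConditionNumber <- function(M) {
  sv <- svd(M)$d
  sv[1L] / sv[length(sv)]
}

#' Unmix per-channel optical density into per-stain concentrations
#'
#' Solves the linear Beer-Lambert mixture `v = M^T c` per pixel by the
#' Moore-Penrose pseudo-inverse of the stain matrix (exact inverse for
#' three stains, least squares for one or two); negative concentrations
#' are clipped to zero. For concentrations composed with
#' [composeStains()] from non-negative maps the round trip is exact to
#' numerical precision.
#'
#' @param od numeric array `width x height x 3` of per-channel OD.
#' @param stains a [StainMatrix-class].
#' @return Named list of `width x height` matrices, one concentration
#'   (OD units) map per stain.
#' @export
deconvolveStains <- function(od, stains) {
  stopifnot(is(stains, "StainMatrix"))
  M <- stains@vectors                       # k x 3
  if (stainConditionNumber(M) > 1e6)
    stop("degenerate stain matrix: condition number exceeds 1e6")
  d <- dim(od)
  if (length(d) != 3L || d[3L] != 3L) stop("'od' must be a width x height x 3 array")
  V <- matrix(od, ncol = 3L)                # n x 3
  # pinv(M^T) applied to each pixel: C = V M^T (M M^T)^-1
  Ct <- V %*% t(M) %*% solve(M %*% t(M))
  Ct[Ct < 0] <- 0
  out <- lapply(seq_len(nrow(M)), function(i) matrix(Ct[, i], d[1L], d[2L]))
  names(out) <- stainNames(stains)
  out
}

#' Compose per-stain concentration maps into per-channel optical density
#'
#' @param concentrations named list of `width x height` matrices matching
#'   the stain matrix, or a single matrix for a one-stain system.
#' @param stains a [StainMatrix-class].
#' @return Array `width x height x 3` of per-channel OD.
#' @export
composeStains <- function(concentrations, stains) {
  stopifnot(is(stains, "StainMatrix"))
  if (is.matrix(concentrations)) concentrations <- list(concentrations)
  M <- stains@vectors
  if (length(concentrations) != nrow(M))
    stop("one concentration map per stain required")
  if (!is.null(names(concentrations)))
    concentrations <- concentrations[stainNames(stains)]
  d <- dim(concentrations[[1L]])
  C <- vapply(concentrations, as.numeric, numeric(prod(d)))  # n x k
  V <- C %*% M                                               # n x 3
  array(V, c(d, 3L))
}

#' Read a stain matrix from a plain-text config
#'
#' Format: one stain per non-comment line, `name r g b` (whitespace
#' separated); vectors are normalised on read.
#'
#' @param path file path.
#' @return A [StainMatrix-class].
#' @export
readStainConfig <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  if (!length(ln)) stop("no stain definitions in ", path)
  parts <- strsplit(ln, "[[:space:]]+")
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("each stain line must be 'name r g b'")
  v <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  rownames(v) <- vapply(parts, `[[`, character(1), 1L)
  stainMatrix(v)
}

#' Read an RGB TIFF field of view
#'
#' Reads an 8-bit interleaved RGB TIFF and returns it in the package's
#' native orientation (`width x height x 3`, intensities 0-255).
#'
#' @param path TIFF file path.
#' @return Numeric array `width x height x 3`.
#' @export
readFovTiff <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- tiff::readTIFF(path)               # h x w x ch in [0,1]
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3]
  aperm(img, c(2L, 1L, 3L)) * 255
}

#' Write an image as TIFF
#'
#' Writes `width x height (x 3)` arrays; 8-bit for intensity images (values
#' 0-255), 16-bit for label images when `bits = 16`.
#'
#' @param image numeric array/matrix in the package's orientation.
#' @param path output path.
#' @param bits integer sample depth (8 or 16).
#' @param max value mapped to full scale.
#' @return Invisibly, `path`.
#' @export
writeImageTiff <- function(image, path, bits = 8L, max = 255) {
  img <- if (length(dim(image)) == 3L) aperm(image, c(2L, 1L, 3L)) else t(image)
  tiff::writeTIFF(clamp(img / max, 0, 1), path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Export / import an optical-density map as 32-bit float TIFF
#'
#' TIFF float samples are stored on a \[0,1\] scale, so OD values are
#' divided by a fixed `odScale` on write and re-multiplied on read; the
#' default 4 comfortably covers the maximum representable OD of
#' log10(255) per stain plus deconvolution overshoot.
#'
#' @param od OD matrix.
#' @param path file path.
#' @param odScale fixed scale factor.
#' @return `writeOdTiff` invisibly returns `path`; `readOdTiff` the OD
#'   matrix.
#' @export
writeOdTiff <- function(od, path, odScale = 4) {
  tiff::writeTIFF(clamp(t(od) / odScale, 0, 1), path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname writeOdTiff
#' @export
readOdTiff <- function(path, odScale = 4) {
  t(tiff::readTIFF(path)) * odScale
}
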