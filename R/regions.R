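minAreaFilter <- function(mask, minPx) {
  if (!any(mask) || minPx <= 1L) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- asMatrix(EBImage::imageData(lab))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minPx)
  lab > 0L & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Detect tissue (vs glass) in a brightfield RGB image
#'
#' Tissue pixels are those whose total optical density across the RGB
#' channels exceeds a small threshold; the mask is then morphologically
#' closed and its enclosed holes filled, so unstained structures inside
#' the section (steatotic vacuoles, pale necrotic zones, sinusoids) stay
#' part of the tissue rather than being mistaken for glass.
#'
#' @param rgb numeric array `w x h x 3`, intensities 0-255.
#' @param backgroundIntensity incident intensity I0.
#' @param odThreshold minimum summed OD for tissue.
#' @param closeRadius closing radius in px.
#' @return Logical matrix; an empty mask (all-glass image) is allowed.
#' @export
detectTissue <- function(rgb, backgroundIntensity = 255, odThreshold = 0.12,
                         closeRadius = 5L) {
  od <- rgbToOd(rgb, backgroundIntensity)
  total <- od[, , 1L] + od[, , 2L] + od[, , 3L]
  mask <- total > odThreshold
  if (any(mask)) {
    # despeckle before closing: isolated noise pixels on glass must not be
    # merged into the tissue boundary
    mask <- asMatrix(EBImage::opening(EBImage::Image(mask),
                                      EBImage::makeBrush(3L, "disc"))) > 0
    if (closeRadius > 0L) {
      brush <- EBImage::makeBrush(2L * as.integer(closeRadius) + 1L, "disc")
      mask <- asMatrix(EBImage::closing(EBImage::Image(mask), brush)) > 0
    }
    mask <- asMatrix(EBImage::fillHull(EBImage::Image(mask))) > 0
  }
  mask
}

#' Detect low-haematoxylin areas (necrosis / fat candidates)
#'
#' Necrotic and fatty areas have lower haematoxylin optical density than
#' intact parenchyma; candidates are tissue pixels below a threshold,
#' min-area filtered. The default is a fixed OD cut (within tissue the
#' haematoxylin histogram is already multi-modal — nuclei vs parenchyma —
#' so Otsu would find the wrong valley); `mode = "otsu"` is available and
#' protected by a unimodality guard (coefficient-of-variation floor) that
#' returns an empty mask on homogeneous images.
#'
#' @param haemOd haematoxylin OD matrix.
#' @param tissue logical tissue mask (same shape).
#' @param geometry an [FovGeometry-class].
#' @param threshold fixed OD threshold.
#' @param mode `"fixed"` or `"otsu"`.
#' @param minAreaUm2 minimum candidate component area.
#' @param cvGuard coefficient-of-variation floor for the Otsu guard.
#' @param smoothSigma Gaussian smoothing of the OD map before
#'   thresholding (px); suppresses noise-ragged boundaries that would
#'   corrupt downstream shape measurements.
#' @param openRadius radius (px) of a morphological opening applied to
#'   the candidate mask (0 disables).
#' @return Logical candidate mask.
#' @export
detectLowHaematoxylin <- function(haemOd, tissue, geometry, threshold = 0.08,
                                  mode = c("fixed", "otsu"), minAreaUm2 = 50,
                                  cvGuard = 0.2, smoothSigma = 1, openRadius = 2L) {
  mode <- match.arg(mode)
  haemOd <- asMatrix(haemOd)
  if (!identical(dim(haemOd), dim(tissue))) stop("haemOd and tissue shapes differ")
  if (smoothSigma > 0)
    haemOd <- asMatrix(EBImage::gblur(EBImage::Image(haemOd), sigma = smoothSigma))
  vals <- haemOd[tissue]
  if (!length(vals)) return(tissue)
  thr <- if (mode == "fixed") threshold else {
    if (coefVar(vals) < cvGuard) return(tissue & FALSE)
    otsuThreshold(vals)
  }
  if (!is.finite(thr)) return(tissue & FALSE)
  mask <- tissue & (haemOd < thr)
  if (any(mask) && openRadius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(openRadius) + 1L, "disc")
    mask <- asMatrix(EBImage::opening(EBImage::Image(mask), brush)) > 0
  }
  minAreaFilter(mask, max(1L, round(minAreaUm2 / pixelAreaUm2(geometry))))
}

#' Split low-haematoxylin candidates into fat and necrosis
#'
#' Steatotic vacuoles are round and bounded in size; confluent necrosis is
#' irregular and/or large. Connected components with circularity
#' `4*pi*A/P^2 >= circularityMin` and equivalent diameter within
#' `diamRangeUm` are fat; all remaining components are necrosis. The two
#' masks are disjoint by construction.
#'
#' @param candidate logical candidate mask from [detectLowHaematoxylin()].
#' @param geometry an [FovGeometry-class].
#' @param circularityMin minimum circularity for a vacuole.
#' @param diamRangeUm allowed vacuole equivalent-diameter range (um).
#' @return List of logical matrices `fat` and `necrosis`.
#' @export
splitFatVsNecrosis <- function(candidate, geometry, circularityMin = 0.7,
                               diamRangeUm = c(5, 100)) {
  out <- list(fat = candidate & FALSE, necrosis = candidate & FALSE)
  if (!any(candidate)) return(out)
  lab <- EBImage::bwlabel(EBImage::Image(candidate))
  feats <- EBImage::computeFeatures.shape(lab)
  lab <- asMatrix(EBImage::imageData(lab))
  area <- feats[, "s.area"]
  per <- pmax(feats[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / per^2, 1.5)     # digitised perimeters overshoot
  diamUm <- 2 * sqrt(area / pi) * geometry@micronsPerPixel
  isFat <- circ >= circularityMin & diamUm >= diamRangeUm[1] & diamUm <= diamRangeUm[2]
  fatIds <- which(isFat)
  out$fat <- matrix(lab %in% fatIds & lab > 0L, nrow(lab), ncol(lab))
  out$necrosis <- candidate & !out$fat
  out
}

#' Detect collagen deposition from Sirius Red optical density
#'
#' Collagen has higher Sirius Red OD than collagen-free tissue; the mask
#' is a threshold on the Sirius Red map within tissue, min-area filtered.
#'
#' @param siriusOd Sirius Red OD matrix.
#' @param tissue logical tissue mask.
#' @param geometry an [FovGeometry-class].
#' @param threshold fixed OD threshold.
#' @param mode `"fixed"` or `"otsu"` (guarded as in
#'   [detectLowHaematoxylin()]).
#' @param minAreaUm2 minimum component area.
#' @param cvGuard unimodality guard for otsu mode.
#' @return List: `mask` (logical) and `fraction` (collagen area over
#'   tissue area).
#' @export
detectCollagen <- function(siriusOd, tissue, geometry, threshold = 0.3,
                           mode = c("fixed", "otsu"), minAreaUm2 = 20,
                           cvGuard = 0.2) {
  mode <- match.arg(mode)
  siriusOd <- asMatrix(siriusOd)
  if (!identical(dim(siriusOd), dim(tissue))) stop("siriusOd and tissue shapes differ")
  vals <- siriusOd[tissue]
  thr <- if (mode == "fixed") threshold else {
    if (!length(vals) || coefVar(vals) < cvGuard) Inf else otsuThreshold(vals)
  }
  mask <- tissue & (siriusOd > thr)
  mask <- minAreaFilter(mask, max(1L, round(minAreaUm2 / pixelAreaUm2(geometry))))
  tp <- sum(tissue)
  list(mask = mask, fraction = if (tp) sum(mask) / tp else 0)
}

#' Group inflammatory cells into foci by single-linkage clustering
#'
#' Cells whose centroids chain together at `linkingDistanceUm` form one
#' cluster (single linkage); clusters with at least `minFocusSize` members
#' are inflammatory foci, the rest are counted as single cells. The result
#' is independent of input order.
#'
#' @param cells data frame of (typically CD45-positive) cells with `x`,
#'   `y` centroids in 0-based pixels.
#' @param geometry an [FovGeometry-class].
#' @param linkingDistanceUm linkage distance in micrometres.
#' @param minFocusSize minimum member count for a focus.
#' @return List: `foci` (data frame `focus_id`, `cell_count`, `x`, `y`
#'   centroid in px), `membership` (integer vector, 0 for unclustered
#'   singles, otherwise focus id), `nSingles`.
#' @examples
#' g <- fovGeometry(100, 100, 0.5)
#' cells <- data.frame(x = c(1, 2, 3, 80) * 2, y = c(1, 2, 1, 80) * 2)
#' detectFoci(cells, g, linkingDistanceUm = 10, minFocusSize = 3)$foci
#' @export
detectFoci <- function(cells, geometry, linkingDistanceUm = 30, minFocusSize = 5L) {
  n <- nrow(cells)
  emptyFoci <- data.frame(focus_id = integer(0), cell_count = integer(0),
                          x = numeric(0), y = numeric(0))
  if (n == 0L) return(list(foci = emptyFoci, membership = integer(0), nSingles = 0L))
  if (n == 1L) return(list(foci = emptyFoci, membership = 0L, nSingles = 1L))
  um <- cbind(cells$x, cells$y) * geometry@micronsPerPixel
  cl <- cutree(hclust(dist(um), method = "single"), h = linkingDistanceUm)
  sizes <- tabulate(cl)
  focusCl <- which(sizes >= minFocusSize)
  membership <- integer(n)
  foci <- emptyFoci
  for (k in seq_along(focusCl)) {
    i <- which(cl == focusCl[k])
    membership[i] <- k
    foci <- rbind(foci, data.frame(focus_id = k, cell_count = length(i),
                                   x = mean(cells$x[i]), y = mean(cells$y[i])))
  }
  list(foci = foci, membership = membership, nSingles = sum(membership == 0L))
}

#' Periportal band (limiting-plate zone) around portal regions
#'
#' Morphological dilation of the portal mask by the band width, minus the
#' portal mask itself, clipped to tissue: the zone where piecemeal
#' necrosis (interface hepatitis) is scored.
#'
#' @param portal logical portal mask.
#' @param bandWidthUm band width in micrometres (> 0).
#' @param geometry an [FovGeometry-class].
#' @param tissue optional logical tissue mask to clip to.
#' @return Logical band mask.
#' @export
periportalBand <- function(portal, bandWidthUm, geometry, tissue = NULL) {
  if (!is.numeric(bandWidthUm) || bandWidthUm <= 0)
    stop("'bandWidthUm' must be positive")
  portal <- asMatrix(portal) > 0
  if (!any(portal)) return(portal)
  r <- max(1L, round(bandWidthUm / geometry@micronsPerPixel))
  brush <- EBImage::makeBrush(2L * r + 1L, "disc")
  band <- (asMatrix(EBImage::dilate(EBImage::Image(portal), brush)) > 0) & !portal
  if (!is.null(tissue)) band <- band & (asMatrix(tissue) > 0)
  band
}

#' Build the full region mask set for one FOV
#'
#' Runs tissue detection, low-haematoxylin candidate detection with the
#' fat/necrosis split, optional collagen detection, and derives the
#' periportal band and lobular region from a supplied portal annotation
#' mask.
#'
#' @param rgb RGB image array (0-255).
#' @param haemOd haematoxylin OD matrix.
#' @param geometry an [FovGeometry-class].
#' @param portal optional logical portal annotation mask.
#' @param siriusOd optional Sirius Red OD matrix.
#' @param bandWidthUm periportal band width.
#' @param params optional list of overrides for the detector parameters
#'   (`lowHaemThreshold`, `collagenThreshold`, `tissueOdThreshold`).
#' @return A [RegionMaskSet-class] with masks `necrosis`, `fat`, `portal`,
#'   `periportal_band`, `lobular` and (if Sirius Red supplied) `collagen`.
#' @export
buildRegionMasks <- function(rgb, haemOd, geometry, portal = NULL,
                             siriusOd = NULL, bandWidthUm = 25,
                             params = list()) {
  tissue <- detectTissue(rgb, odThreshold = params$tissueOdThreshold %||% 0.12)
  cand <- detectLowHaematoxylin(haemOd, tissue, geometry,
                                threshold = params$lowHaemThreshold %||% 0.08)
  fn <- splitFatVsNecrosis(cand, geometry)
  masks <- list(necrosis = fn$necrosis, fat = fn$fat)
  if (!is.null(portal)) {
    portal <- (asMatrix(portal) > 0) & tissue
    band <- periportalBand(portal, bandWidthUm, geometry, tissue)
  } else {
    portal <- tissue & FALSE
    band <- portal
  }
  masks$portal <- portal
  masks$periportal_band <- band
  masks$lobular <- tissue & !portal & !band
  if (!is.null(siriusOd))
    masks$collagen <- detectCollagen(siriusOd, tissue, geometry,
                                     threshold = params$collagenThreshold %||% 0.3)$mask
  regionMaskSet(masks, tissue, geometry)
}

#' Write a region summary CSV
#'
#' One row per feature mask: pixel count, area in square micrometres and
#' fraction of tissue.
#'
#' @param masks a [RegionMaskSet-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeRegionSummary <- function(masks, path) {
  g <- masks@geometry
  df <- data.frame(
    feature = names(masks@masks),
    pixels = vapply(masks@masks, sum, numeric(1)),
    area_um2 = vapply(masks@masks, function(m) sum(m) * pixelAreaUm2(g), numeric(1)),
    fraction = areaFractions(masks))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
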