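#' Segment nuclei from a haematoxylin OD (or DAPI intensity) image
#'
#' Deterministic pipeline: optional Gaussian smoothing, threshold on the
#' nuclear signal (Otsu over the image histogram unless a fixed threshold
#' is given), hole filling, removal of objects below the minimum nucleus
#' area, and splitting of touching nuclei by distance-transform watershed.
#'
#' @param nuclear numeric matrix: haematoxylin OD map (brightfield) or
#'   DAPI intensity in \[0,1\] (fluorescence).
#' @param geometry an [FovGeometry-class].
#' @param threshold fixed threshold; `NULL` (default) uses Otsu's method.
#' @param minThreshold floor applied to the data-driven threshold: on a
#'   blank FOV Otsu would cut into sensor noise, so no object dimmer than
#'   this OD (or normalised intensity) is ever segmented. Ignored when a
#'   fixed `threshold` is supplied.
#' @param minAreaUm2 minimum nucleus area in square micrometres (objects
#'   below it are debris).
#' @param smoothSigma pre-threshold Gaussian smoothing in px (0 disables).
#' @param watershedTolerance minimum object-height separation for the
#'   watershed split (passed to [EBImage::watershed()]).
#' @return List with `labels` (integer matrix, background 0, nuclei
#'   1..N) and `cells` (data frame: `id`, `x`, `y` centroids in 0-based
#'   pixel coordinates, `area_px`, `area_um2`); zero rows for a blank
#'   image.
#' @examples
#' g <- fovGeometry(64, 64, 0.5)
#' od <- matrix(0, 64, 64); od[20:30, 20:30] <- 0.8
#' segmentNuclei(od, g)$cells
#' @export
segmentNuclei <- function(nuclear, geometry, threshold = NULL,
                          minThreshold = 0.12, minAreaUm2 = 10,
                          smoothSigma = 1, watershedTolerance = 1) {
  nuclear <- asMatrix(nuclear)
  if (any(!is.finite(nuclear))) stop("nuclear image must be finite")
  sm <- if (smoothSigma > 0)
    asMatrix(EBImage::gblur(EBImage::Image(nuclear), sigma = smoothSigma)) else nuclear
  thr <- threshold %||% max(otsuThreshold(sm), minThreshold)
  empty <- list(labels = matrix(0L, nrow(nuclear), ncol(nuclear)),
                cells = data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                                   area_px = integer(0), area_um2 = numeric(0)))
  if (is.na(thr)) return(empty)
  mask <- sm > thr
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(EBImage::Image(mask))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershedTolerance, ext = 1)
  lab <- asMatrix(EBImage::imageData(labels))
  storage.mode(lab) <- "integer"
  minPx <- max(1L, round(minAreaUm2 / pixelAreaUm2(geometry)))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minPx)
  if (!length(keep)) return(empty)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  n <- length(keep)
  idx <- which(lab > 0L)
  ids <- lab[idx]
  xs <- ((idx - 1L) %% nrow(lab))          # 0-based pixel coordinates
  ys <- ((idx - 1L) %/% nrow(lab))
  areaPx <- tabulate(ids, n)
  cells <- data.frame(
    id = seq_len(n),
    x = as.numeric(rowsum(xs, ids)) / areaPx,
    y = as.numeric(rowsum(ys, ids)) / areaPx,
    area_px = as.integer(areaPx),
    area_um2 = areaPx * pixelAreaUm2(geometry))
  list(labels = lab, cells = cells)
}

#' Measure per-cell stain or channel signals
#'
#' For every labelled nucleus: mean signal of each supplied map over the
#' nucleus mask and over a cytoplasmic ring (geometric dilation of the
#' nucleus by `ringRadiusPx`, clipped at neighbouring cells by
#' nearest-nucleus assignment). Brightfield maps are optical densities
#' (column prefix `od_`); fluorescence channel maps in \[0,1\] use prefix
#' `int_`.
#'
#' @param labels integer label matrix from [segmentNuclei()].
#' @param cells the cell data frame from [segmentNuclei()].
#' @param maps named list of numeric matrices (stain OD maps or channel
#'   intensities), same shape as `labels`.
#' @param geometry an [FovGeometry-class].
#' @param ringRadiusPx cytoplasmic ring width in pixels.
#' @param erodeNucleusPx erosion applied to the nuclear mask before
#'   measuring (guards the mean against partial-volume dimming at the
#'   blurred nucleus boundary); cells that erode away fall back to the
#'   full mask.
#' @param prefix column prefix, `"od"` or `"int"`.
#' @return `cells` with one `<prefix>_<map>_nucleus` and
#'   `<prefix>_<map>_ring` column per map; ring means fall back to the
#'   nucleus mean for cells whose ring is fully occluded by neighbours.
#' @export
measureCells <- function(labels, cells, maps, geometry, ringRadiusPx = 3,
                         erodeNucleusPx = 1L, prefix = c("od", "int")) {
  prefix <- match.arg(prefix)
  if (!length(maps) || is.null(names(maps))) stop("'maps' must be a named list")
  for (m in maps)
    if (!identical(dim(asMatrix(m)), dim(labels)))
      stop("map shape does not match the label image")
  n <- nrow(cells)
  if (n == 0L) {
    for (nm in names(maps)) {
      cells[[paste(prefix, nm, "nucleus", sep = "_")]] <- numeric(0)
      cells[[paste(prefix, nm, "ring", sep = "_")]] <- numeric(0)
    }
    return(cells)
  }
  measLabels <- labels
  if (erodeNucleusPx > 0L) {
    eb <- EBImage::makeBrush(2L * as.integer(erodeNucleusPx) + 1L, "disc")
    interior <- asMatrix(EBImage::erode(EBImage::Image(labels > 0L), eb)) > 0
    lost <- setdiff(seq_len(n), unique(labels[interior & labels > 0L]))
    keepPx <- (interior & labels > 0L) | matrix(labels %in% lost, nrow(labels))
    measLabels[!keepPx] <- 0L
  }
  nucIdx <- which(measLabels > 0L)
  nucIds <- measLabels[nucIdx]
  nucArea <- tabulate(nucIds, n)
  # ring: dilate the nuclear mask, assign new pixels to the nearest nucleus
  brush <- EBImage::makeBrush(2L * as.integer(ringRadiusPx) + 1L, shape = "disc")
  dil <- EBImage::dilate(EBImage::Image(labels > 0L), brush)
  vor <- EBImage::propagate(EBImage::Image(matrix(0, nrow(labels), ncol(labels))),
                            seeds = EBImage::Image(labels), mask = dil)
  ring <- asMatrix(EBImage::imageData(vor))
  storage.mode(ring) <- "integer"
  ring[labels > 0L] <- 0L
  ringIdx <- which(ring > 0L)
  ringIds <- ring[ringIdx]
  ringArea <- tabulate(ringIds, n)
  for (nm in names(maps)) {
    m <- asMatrix(maps[[nm]])
    nucMean <- as.numeric(rowsum(m[nucIdx], nucIds)) / nucArea
    ringMean <- rep(NA_real_, n)
    if (length(ringIdx)) {
      s <- rowsum(m[ringIdx], ringIds)
      ringMean[as.integer(rownames(s))] <- as.numeric(s) / ringArea[as.integer(rownames(s))]
    }
    ringMean[!is.finite(ringMean)] <- nucMean[!is.finite(ringMean)]
    cells[[paste(prefix, nm, "nucleus", sep = "_")]] <- nucMean
    cells[[paste(prefix, nm, "ring", sep = "_")]] <- ringMean
  }
  cells
}

#' Match detected cells to ground-truth positions
#'
#' Greedy nearest-neighbour matching: a detection matches a truth cell
#' when their centroids lie within `maxDistPx`; each truth cell is matched
#' at most once. Returns detection precision and recall, the standard
#' report for segmentation against a known synthetic scene.
#'
#' @param detected data frame with `x`, `y` (0-based px).
#' @param truth data frame with `x`, `y` (0-based px).
#' @param maxDistPx matching radius, typically one nucleus radius.
#' @return List `nMatched`, `precision`, `recall`.
#' @export
matchDetections <- function(detected, truth, maxDistPx) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L)
    return(list(nMatched = 0L, precision = as.numeric(nd == 0L),
                recall = as.numeric(nt == 0L)))
  d2 <- outer(detected$x, truth$x, `-`)^2 + outer(detected$y, truth$y, `-`)^2
  lim <- maxDistPx^2
  matched <- 0L
  usedT <- rep(FALSE, nt); usedD <- rep(FALSE, nd)
  ord <- order(d2)
  for (k in ord) {
    if (d2[k] > lim) break
    i <- (k - 1L) %% nd + 1L; j <- (k - 1L) %/% nd + 1L
    if (usedD[i] || usedT[j]) next
    usedD[i] <- usedT[j] <- TRUE
    matched <- matched + 1L
  }
  list(nMatched = matched, precision = matched / nd, recall = matched / nt)
}

#' Write a cell table as CSV
#'
#' Stable column order: `id`, `x`, `y`, `area_um2`, `area_px`, then
#' measurement (`od_`/`int_`) columns, then phenotype (`pheno_`) columns.
#'
#' @param cells cell data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeCellTable <- function(cells, path) {
  lead <- intersect(c("id", "x", "y", "area_um2", "area_px"), names(cells))
  meas <- sort(grep("^(od|int)_", names(cells), value = TRUE))
  phen <- sort(grep("^pheno_", names(cells), value = TRUE))
  rest <- setdiff(names(cells), c(lead, meas, phen))
  write.csv(cells[, c(lead, meas, phen, rest), drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
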