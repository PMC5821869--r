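#' SceneSpec: parameters of one synthetic field of view
#'
#' Describes a 20x-magnification liver FOV for the synthetic renderer:
#' cell densities and populations, portal tracts, necrosis/fat/collagen
#' burden, marker optical-density distributions and the severity level
#' that jointly scales the inflammatory drivers (CD45 density, focus rate,
#' necrosis fraction). Identical spec + seed reproduce identical truth and
#' pixels.
#'
#' @slot geometry an [FovGeometry-class].
#' @slot seed integer seed; all randomness derives from it.
#' @slot sceneType `"ihc"` (haematoxylin + DAB), `"he"`, `"sirius"` or `"if"`.
#' @slot severity non-negative multiplier applied jointly to `cd45Density`,
#'   `focusRate` and `necrosisFraction`.
#' @slot params named list of scene parameters (see [sceneSpec()]).
#' @slot popParams named list of per-population feature distributions.
#' @export
setClass("SceneSpec",
  representation(geometry = "FovGeometry", seed = "integer",
                 sceneType = "character", severity = "numeric",
                 params = "list", popParams = "list"))

sceneParamDefaults <- function() list(
  tissueFraction     = 1.0,    # tissue area / FOV area
  markerStained      = "pck",  # which marker carries the DAB chromogen:
                               # "pck" (HPC/ductal cells), "cd45", or "none"
  hepatocyteDensity  = 2000,   # parenchymal nuclei per mm^2
  hpcFraction        = 0,      # fraction of parenchymal cells that are PCK+ HPCs
  popOverride        = NA_character_, # force all parenchymal cells to one population
  portalTracts       = 0L,     # number of portal tract discs
  portalRadiusUm     = 40,     # portal tract disc radius
  ductalCellsPerTract = 12L,   # PCK+ ductal cells ringing each tract
  cd45Density        = 0,      # CD45+ singles per mm^2 (scaled by severity)
  focusRate          = 0,      # inflammatory foci per mm^2 lobule (scaled by severity)
  focusSizeMean      = 8,      # mean cells per focus (Poisson, floored at 5)
  focusRadiusUm      = 14,     # focus footprint radius
  fatCount           = 0L,     # steatotic vacuoles
  fatDiamUm          = c(10, 40),
  necrosisFraction   = 0,      # target necrotic fraction of tissue (scaled by severity)
  collagenFraction   = 0,      # target collagen fraction of tissue (sirius scenes)
  ifFractions        = c(green = 0, red = 0, double = 0),
  minSpacingUm       = 9,      # hard-core minimum distance between nuclei
  noiseSd            = 0.02,   # per-pixel Gaussian OD/intensity noise
  blurSigma          = 1,      # optical blur, px
  baseHaemOd         = 0.15,   # parenchyma counterstain background
  maxPlaceTries      = 400L)   # dart-throwing retries per cell before failing

popParamDefaults <- function() list(
  # meanAreaUm2 / haemOd / dabOd define Gaussian per-cell draws (sd = 10% of mean)
  hepatocyte = list(meanAreaUm2 = 38, haemOd = 0.55, dabOd = 0.10),
  hpc        = list(meanAreaUm2 = 25, haemOd = 0.40, dabOd = 0.60),
  ductal     = list(meanAreaUm2 = 60, haemOd = 0.80, dabOd = 0.70),
  cd45       = list(meanAreaUm2 = 20, haemOd = 0.50, dabOd = 0.70),
  ifCell     = list(meanAreaUm2 = 30, dapi = 0.8, hi = 0.70, lo = 0.08))

#' Construct a SceneSpec
#'
#' Unspecified parameters take the package's study-condition defaults
#' (hepatocyte density 2000/mm^2, 9 um hard-core spacing, OD noise sd 0.02,
#' 1 px blur; see `vignette("hepaquant-methods")`).
#'
#' @param width,height FOV size in pixels.
#' @param micronsPerPixel physical scale (default 0.5, a 20x scanner).
#' @param seed integer seed.
#' @param sceneType `"ihc"`, `"he"`, `"sirius"` or `"if"`.
#' @param severity non-negative severity multiplier (default 1).
#' @param ... scene parameters overriding the defaults (see
#'   [SceneSpec-class]); unknown names are an error.
#' @param popParams optional list overriding per-population distributions.
#' @return A [SceneSpec-class].
#' @examples
#' sceneSpec(256, 256, seed = 1, hpcFraction = 0.2)
#' @export
sceneSpec <- function(width = 384, height = 384, micronsPerPixel = 0.5,
                      seed = 1L, sceneType = "ihc", severity = 1, ...,
                      popParams = list()) {
  dots <- list(...)
  defaults <- sceneParamDefaults()
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad)) stop("unknown scene parameter(s): ", paste(bad, collapse = ", "))
  params <- modifyList(defaults, dots)
  pp <- popParamDefaults()
  badp <- setdiff(names(popParams), names(pp))
  if (length(badp)) stop("unknown population(s): ", paste(badp, collapse = ", "))
  for (nm in names(popParams)) pp[[nm]] <- modifyList(pp[[nm]], popParams[[nm]])
  if (!sceneType %in% c("ihc", "he", "sirius", "if"))
    stop("sceneType must be one of 'ihc', 'he', 'sirius', 'if'")
  stopifnot(severity >= 0)
  numFields <- c("tissueFraction", "hepatocyteDensity", "hpcFraction", "cd45Density",
                 "focusRate", "necrosisFraction", "collagenFraction")
  for (nm in numFields) if (params[[nm]] < 0) stop("'", nm, "' must be non-negative")
  for (nm in c("tissueFraction", "hpcFraction", "necrosisFraction", "collagenFraction"))
    if (params[[nm]] > 1) stop("'", nm, "' must not exceed 1")
  if (sum(params$ifFractions) > 1) stop("IF positivity fractions must sum to at most 1")
  if (!params$markerStained %in% c("pck", "cd45", "none"))
    stop("markerStained must be 'pck', 'cd45' or 'none'")
  new("SceneSpec", geometry = fovGeometry(width, height, micronsPerPixel),
      seed = as.integer(seed), sceneType = sceneType, severity = as.numeric(severity),
      params = params, popParams = pp)
}

setMethod("show", "SceneSpec", function(object) {
  p <- object@params
  cat(sprintf("SceneSpec [%s] %dx%d px, seed %d, severity %g\n",
              object@sceneType, object@geometry@width, object@geometry@height,
              object@seed, object@severity))
  cat(sprintf("  hepatocytes %g/mm^2, hpcFraction %g, portal tracts %d, cd45 %g/mm^2\n",
              p$hepatocyteDensity, p$hpcFraction, p$portalTracts,
              p$cd45Density * object@severity))
})

#' SyntheticFov: a rendered FOV with its ground truth
#'
#' @slot image numeric array: `w x h x 3` RGB (0-255, brightfield) or
#'   `w x h x 3` channel intensities in \[0,1\] (IF: DAPI, green, red).
#' @slot truth list with elements `cells` (data frame: one row per rendered
#'   cell with true position, population, marker status and painted feature
#'   values), `masks` (logical matrices: tissue, portal, necrosis, fat,
#'   collagen) and `measures` (named list of true per-FOV summary measures).
#' @slot spec the generating [SceneSpec-class].
#' @export
setClass("SyntheticFov",
  representation(image = "array", truth = "list", spec = "SceneSpec"))

#' @describeIn sceneSpec Rendered image of a [SyntheticFov-class].
#' @param fov a `SyntheticFov`.
#' @export
fovImage <- function(fov) fov@image

#' @describeIn sceneSpec Ground-truth list of a [SyntheticFov-class].
#' @export
fovTruth <- function(fov) fov@truth

setMethod("show", "SyntheticFov", function(object) {
  cat(sprintf("SyntheticFov [%s] %s px, %d cells, tissue %.2f\n",
              object@spec@sceneType, paste(dim(object@image)[1:2], collapse = "x"),
              nrow(object@truth$cells), object@truth$measures$tissueFraction))
})

# ---- placement and painting helpers ----------------------------------------

paintDisc <- function(mat, cx, cy, r, value, mode = "max") {
  idx <- discIndex(cx, cy, r, nrow(mat), ncol(mat))
  if (nrow(idx) == 0L) return(mat)
  cur <- mat[idx]
  mat[idx] <- switch(mode, max = pmax(cur, value), set = value, add = cur + value)
  mat
}

discMask <- function(w, h, cx, cy, r) {
  m <- matrix(FALSE, w, h)
  idx <- discIndex(cx, cy, r, w, h)
  if (nrow(idx)) m[idx] <- TRUE
  m
}

# Dart-throwing hard-core placement: n points uniform over TRUE pixels of
# `allowed`, each at least minDistPx from every previously placed point
# (including `existing`). Errors when packing is infeasible.
placeHardCore <- function(n, allowed, existing, minDistPx, maxTriesPer = 400L) {
  if (n <= 0L) return(matrix(numeric(0), ncol = 2))
  ok <- which(allowed)
  if (!length(ok)) {
    if (n > 0L) stop("hard-core packing infeasible: no admissible area")
  }
  w <- nrow(allowed)
  pts <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  maxTries <- as.integer(maxTriesPer) * n
  d2min <- minDistPx^2
  all_x <- if (nrow(existing)) existing[, 1L] else numeric(0)
  all_y <- if (nrow(existing)) existing[, 2L] else numeric(0)
  while (placed < n && tries < maxTries) {
    tries <- tries + 1L
    lin <- ok[sample.int(length(ok), 1L)]
    x <- ((lin - 1L) %% w) + runif(1) - 0.5       # 0-based pixel-centre + jitter
    y <- ((lin - 1L) %/% w) + runif(1) - 0.5
    if (length(all_x) && min((all_x - x)^2 + (all_y - y)^2) < d2min) next
    placed <- placed + 1L
    pts[placed, ] <- c(x, y)
    all_x <- c(all_x, x); all_y <- c(all_y, y)
  }
  if (placed < n)
    stop(sprintf("hard-core packing infeasible: placed %d of %d cells", placed, n))
  pts
}

truncNorm <- function(n, mean, sd, lo = 0.01) pmax(rnorm(n, mean, sd), lo)

blurNoise <- function(mat, blurSigma, noiseSd, lo = 0, hi = Inf) {
  if (blurSigma > 0) mat <- asMatrix(EBImage::gblur(EBImage::Image(mat), sigma = blurSigma))
  if (noiseSd > 0) mat <- mat + rnorm(length(mat), 0, noiseSd)
  clamp(mat, lo, hi)
}

irregularBlob <- function(w, h, cx, cy, targetPx) {
  # union of jittered discs chained along a random axis: elongated, lobed,
  # decisively non-circular (confluent necrosis tracks zones, not vacuoles)
  R <- 0.85 * sqrt(targetPx / pi)   # union of the chain ~ targetPx
  m <- matrix(FALSE, w, h)
  ndisc <- 10L
  ang <- runif(1, 0, 2 * pi)
  for (i in seq_len(ndisc)) {
    t <- (i - 1) / (ndisc - 1) * 2 - 1            # spread along the axis
    ox <- cx + t * R * 1.7 * cos(ang) + rnorm(1, 0, R * 0.15)
    oy <- cy + t * R * 1.7 * sin(ang) + rnorm(1, 0, R * 0.15)
    m <- m | discMask(w, h, ox, oy, R * runif(1, 0.45, 0.65))
  }
  m
}

segmentBandMask <- function(w, h, p0, p1, halfWidth) {
  x0 <- max(1L, floor(min(p0[1], p1[1]) - halfWidth)); x1 <- min(w, ceiling(max(p0[1], p1[1]) + halfWidth))
  y0 <- max(1L, floor(min(p0[2], p1[2]) - halfWidth)); y1 <- min(h, ceiling(max(p0[2], p1[2]) + halfWidth))
  m <- matrix(FALSE, w, h)
  if (x1 < x0 || y1 < y0) return(m)
  g <- expand.grid(x = x0:x1, y = y0:y1)
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- if (L2 > 0) clamp(((g$x - p0[1]) * v[1] + (g$y - p0[2]) * v[2]) / L2, 0, 1) else 0
  dx <- g$x - (p0[1] + t * v[1]); dy <- g$y - (p0[2] + t * v[2])
  keep <- dx^2 + dy^2 <= halfWidth^2
  m[cbind(g$x[keep], g$y[keep])] <- TRUE
  m
}

# ---- scene assembly ---------------------------------------------------------

buildScene <- function(spec) {
  g <- spec@geometry; p <- spec@params; pp <- spec@popParams
  w <- g@width; h <- g@height; mpp <- g@micronsPerPixel
  um <- function(x) x / mpp                       # micrometres -> pixels
  sev <- spec@severity

  # tissue ---------------------------------------------------------------
  if (p$tissueFraction >= 1) {
    tissue <- matrix(TRUE, w, h)
  } else if (p$tissueFraction <= 0) {
    tissue <- matrix(FALSE, w, h)
  } else {
    a <- sqrt(p$tissueFraction / pi)
    xs <- (seq_len(w) - 0.5 - w / 2) / (a * w)
    ys <- (seq_len(h) - 0.5 - h / 2) / (a * h)
    tissue <- outer(xs^2, ys^2, `+`) <= 1
  }
  tissuePx <- sum(tissue)

  # portal tracts --------------------------------------------------------
  portal <- matrix(FALSE, w, h)
  portalCentres <- matrix(numeric(0), ncol = 2)
  rPortal <- um(p$portalRadiusUm)
  if (p$portalTracts > 0L && tissuePx > 0L) {
    margin <- rPortal + 4
    inner <- tissue
    inner[c(seq_len(min(w, ceiling(margin))), (w - ceiling(margin) + 1):w), ] <- FALSE
    inner[, c(seq_len(min(h, ceiling(margin))), (h - ceiling(margin) + 1):h)] <- FALSE
    portalCentres <- placeHardCore(p$portalTracts, inner,
                                   matrix(numeric(0), ncol = 2),
                                   minDistPx = 2.6 * rPortal,
                                   maxTriesPer = p$maxPlaceTries)
    for (i in seq_len(nrow(portalCentres)))
      portal <- portal | discMask(w, h, portalCentres[i, 1], portalCentres[i, 2], rPortal)
    portal <- portal & tissue
  }

  # necrosis -------------------------------------------------------------
  # pale features are kept clear of the FOV border: a border-truncated
  # unstained zone is indistinguishable from glass
  interiorOf <- function(mask, margin) {
    m <- mask
    margin <- ceiling(margin)
    if (margin >= 1L) {
      mx <- min(margin, floor((w - 1) / 2)); my <- min(margin, floor((h - 1) / 2))
      if (mx >= 1L) m[c(seq_len(mx), (w - mx + 1L):w), ] <- FALSE
      if (my >= 1L) m[, c(seq_len(my), (h - my + 1L):h)] <- FALSE
    }
    m
  }
  necrosis <- matrix(FALSE, w, h)
  nf <- min(p$necrosisFraction * sev, 0.5)
  if (nf > 0 && tissuePx > 0L) {
    lob <- tissue & !portal
    # split large burdens over several patches so each zone fits inside
    # the FOV instead of being clipped at its borders
    nPatch <- max(1L, ceiling(nf / 0.08))
    perPatch <- nf * tissuePx / nPatch
    R <- sqrt(perPatch / pi)
    for (k in seq_len(nPatch)) {
      inner <- interiorOf(lob & !necrosis, min(2.3 * R + 4, (min(w, h) - 8) / 2))
      if (!any(inner)) inner <- lob
      cand <- which(inner)
      lin <- cand[sample.int(length(cand), 1L)]
      cx <- ((lin - 1L) %% w); cy <- ((lin - 1L) %/% w)
      necrosis <- necrosis | (irregularBlob(w, h, cx, cy, perPatch) & lob)
    }
  }

  # fat vacuoles ----------------------------------------------------------
  fat <- matrix(FALSE, w, h)
  fatTruth <- data.frame(x = numeric(0), y = numeric(0), diam_um = numeric(0))
  if (p$fatCount > 0L && tissuePx > 0L) {
    # keep whole vacuoles clear of the necrotic zone so the two features
    # never merge into one low-haematoxylin component
    rMax <- um(max(p$fatDiamUm)) / 2
    allowedFat <- interiorOf(tissue & !portal, rMax + 6)
    if (any(necrosis)) {
      grow <- EBImage::makeBrush(2L * ceiling(rMax + 2) + 1L, "disc")
      allowedFat <- allowedFat &
        !(asMatrix(EBImage::dilate(EBImage::Image(necrosis), grow)) > 0)
    }
    # >= 10 um gap between vacuole rims: adjacent vacuoles must not fuse
    # into one component after optical blur; diameters are drawn first so
    # each vacuole only reserves the space it needs
    diam <- sort(runif(p$fatCount, p$fatDiamUm[1], p$fatDiamUm[2]),
                 decreasing = TRUE)
    ctr <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(p$fatCount)) {
      ctr <- rbind(ctr, placeHardCore(
        1L, allowedFat, ctr,
        minDistPx = um((diam[i] + max(p$fatDiamUm)) / 2 + 10),
        maxTriesPer = p$maxPlaceTries * p$fatCount))
    }
    for (i in seq_len(nrow(ctr)))
      fat <- fat | discMask(w, h, ctr[i, 1], ctr[i, 2], um(diam[i]) / 2)
    fat <- fat & tissue & !necrosis
    fatTruth <- data.frame(x = ctr[, 1], y = ctr[, 2], diam_um = diam)
  }

  # collagen ribbons (sirius scenes) --------------------------------------
  collagen <- matrix(FALSE, w, h)
  cf <- p$collagenFraction
  if (cf > 0 && tissuePx > 0L) {
    halfW <- um(2.5)                               # ~5 um fibre thickness
    guard <- 0L
    while (sum(collagen) < cf * tissuePx && guard < 200L) {
      guard <- guard + 1L
      p0 <- c(runif(1, 1, w), runif(1, 1, h))
      ang <- runif(1, 0, 2 * pi); len <- runif(1, 0.3, 0.7) * max(w, h)
      p1 <- p0 + len * c(cos(ang), sin(ang))
      collagen <- collagen | segmentBandMask(w, h, p0, p1, halfW)
    }
    collagen <- collagen & tissue
  }

  # cells -----------------------------------------------------------------
  lobular <- tissue & !portal & !necrosis & !fat
  lobMm2 <- pxToMm2(sum(lobular), g)
  tisMm2 <- pxToMm2(tissuePx, g)
  spacing <- um(p$minSpacingUm)

  cells <- list()
  placedPts <- matrix(numeric(0), ncol = 2)
  addCells <- function(n, allowed, pop, minDist, focusId = 0L) {
    if (n <= 0L) return(invisible(NULL))
    pts <- placeHardCore(n, allowed, placedPts, minDist, p$maxPlaceTries)
    placedPts <<- rbind(placedPts, pts)
    cells[[length(cells) + 1L]] <<- data.frame(
      x = pts[, 1], y = pts[, 2], population = pop, focus_id = focusId,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }

  # parenchymal cells (hepatocytes / HPCs)
  nPar <- round(p$hepatocyteDensity * lobMm2)
  if (nPar > 0L) {
    pops <- if (!is.na(p$popOverride)) rep(p$popOverride, nPar)
            else ifelse(runif(nPar) < p$hpcFraction, "hpc", "hepatocyte")
    pts <- placeHardCore(nPar, lobular, placedPts, spacing, p$maxPlaceTries)
    placedPts <- rbind(placedPts, pts)
    cells[[length(cells) + 1L]] <- data.frame(
      x = pts[, 1], y = pts[, 2], population = pops, focus_id = 0L,
      stringsAsFactors = FALSE)
  }

  # ductal cells inside portal tracts
  if (nrow(portalCentres) > 0L && p$ductalCellsPerTract > 0L) {
    for (i in seq_len(nrow(portalCentres))) {
      tractDisc <- discMask(w, h, portalCentres[i, 1], portalCentres[i, 2],
                            rPortal * 0.85) & tissue
      addCells(p$ductalCellsPerTract, tractDisc, "ductal", spacing * 0.9)
    }
  }

  # CD45 singles over the whole tissue (portal + lobular)
  cd45Allowed <- tissue & !necrosis & !fat
  nCd45 <- rpois(1L, p$cd45Density * sev * pxToMm2(sum(cd45Allowed), g))
  if (nCd45 > 0L) addCells(nCd45, cd45Allowed, "cd45", spacing * 0.85)

  # inflammatory foci (clusters of CD45 cells in the lobule)
  nFoci <- rpois(1L, p$focusRate * sev * lobMm2)
  if (nFoci > 0L) {
    rFoc <- um(p$focusRadiusUm)
    margin <- ceiling(rFoc + 2)
    inner <- lobular
    if (w > 2 * margin) inner[c(seq_len(margin), (w - margin + 1):w), ] <- FALSE
    if (h > 2 * margin) inner[, c(seq_len(margin), (h - margin + 1):h)] <- FALSE
    fc <- try(placeHardCore(nFoci, inner, matrix(numeric(0), ncol = 2),
                            minDistPx = 3.2 * rFoc, maxTriesPer = p$maxPlaceTries),
              silent = TRUE)
    if (!inherits(fc, "try-error")) {
      for (i in seq_len(nrow(fc))) {
        size <- max(5L, rpois(1L, p$focusSizeMean))
        focDisc <- discMask(w, h, fc[i, 1], fc[i, 2], rFoc) & lobular
        res <- try(addCells(size, focDisc, "cd45", um(5), focusId = i), silent = TRUE)
        if (inherits(res, "try-error")) addCells(5L, focDisc, "cd45", um(4.2), focusId = i)
      }
    }
  }

  cellDf <- if (length(cells)) do.call(rbind, cells)
            else data.frame(x = numeric(0), y = numeric(0),
                            population = character(0), focus_id = integer(0))
  if (nrow(cellDf)) cellDf$id <- seq_len(nrow(cellDf))

  # per-cell feature draws -------------------------------------------------
  n <- nrow(cellDf)
  if (n) {
    area <- haem <- dab <- numeric(n)
    stainedPops <- switch(p$markerStained,
                          pck = c("hpc", "ductal"), cd45 = "cd45", none = character(0))
    for (pop in unique(cellDf$population)) {
      i <- which(cellDf$population == pop)
      q <- pp[[pop]]
      area[i] <- truncNorm(length(i), q$meanAreaUm2, 0.1 * q$meanAreaUm2, lo = 5)
      if (spec@sceneType != "if") {
        haem[i] <- truncNorm(length(i), q$haemOd, 0.1 * q$haemOd)
        # only the stained marker's populations carry the chromogen; all
        # other cells show the nonspecific DAB background
        dabMean <- if (pop %in% stainedPops) q$dabOd else 0.10
        dab[i]  <- truncNorm(length(i), dabMean, 0.1 * dabMean)
      }
    }
    cellDf$area_um2_true <- area
    cellDf$radius_px <- um(sqrt(area / pi))
    cellDf$haem_od <- haem
    cellDf$dab_od <- dab
    cellDf$pck_true <- cellDf$population %in% c("hpc", "ductal")
    cellDf$cd45_true <- cellDf$population == "cd45"
  } else {
    cellDf$area_um2_true <- cellDf$radius_px <- cellDf$haem_od <- cellDf$dab_od <- numeric(0)
    cellDf$pck_true <- cellDf$cd45_true <- logical(0)
  }

  masks <- list(tissue = tissue, portal = portal, necrosis = necrosis,
                fat = fat, collagen = collagen)
  measures <- list(
    nCells = n,
    percentPositive = if (n) 100 * mean(cellDf$pck_true) else 0,
    cd45Count = sum(cellDf$cd45_true),
    cd45Density = if (tisMm2 > 0) sum(cellDf$cd45_true) / tisMm2 else 0,
    fociCount = length(setdiff(unique(cellDf$focus_id), 0L)),
    tissueFraction = tissuePx / (w * h),
    necrosisFraction = if (tissuePx) sum(necrosis) / tissuePx else 0,
    collagenFraction = if (tissuePx) sum(collagen) / tissuePx else 0,
    fatCount = nrow(fatTruth))
  list(cells = cellDf, masks = masks, measures = measures, fat = fatTruth,
       portalCentres = portalCentres)
}

# ---- rendering --------------------------------------------------------------

renderBrightfield <- function(scene, spec) {
  g <- spec@geometry; p <- spec@params
  w <- g@width; h <- g@height
  mk <- scene$masks
  ringPx <- round(1 / g@micronsPerPixel)          # cytoplasm paint margin helpers

  odHaem <- matrix(0, w, h)
  odHaem[mk$tissue] <- p$baseHaemOd
  odHaem[mk$portal] <- p$baseHaemOd + 0.07        # denser portal stroma
  odHaem[mk$necrosis] <- 0.03                     # necrosis: low haematoxylin
  odHaem[mk$fat] <- 0.01                          # vacuoles: unstained
  odSecond <- matrix(0, w, h)                     # DAB / eosin / sirius red

  cells <- scene$cells
  cytoExtra <- 3 + 2                              # ring radius + blur guard, px
  for (i in seq_len(nrow(cells))) {
    r <- cells$radius_px[i]
    # chromogen over the whole cell footprint (cytoplasm + nucleus)
    if (spec@sceneType == "ihc")
      odSecond <- paintDisc(odSecond, cells$x[i], cells$y[i], r + cytoExtra,
                            cells$dab_od[i], "max")
    odHaem <- paintDisc(odHaem, cells$x[i], cells$y[i], r, cells$haem_od[i], "max")
  }
  if (spec@sceneType == "he") odSecond[mk$tissue] <- 0.30     # eosin cytoplasm
  if (spec@sceneType == "sirius") {
    odSecond[mk$tissue] <- 0.05
    odSecond[mk$collagen] <- 0.80
  }
  odHaem <- blurNoise(odHaem, p$blurSigma, p$noiseSd)
  odSecond <- blurNoise(odSecond, p$blurSigma, p$noiseSd)

  stains <- switch(spec@sceneType,
    ihc = defaultStains(c("haematoxylin", "dab")),
    he = defaultStains(c("haematoxylin", "eosin")),
    sirius = defaultStains(c("haematoxylin", "sirius_red")))
  conc <- setNames(list(odHaem, odSecond), stainNames(stains))
  rgb <- round(odToRgb(composeStains(conc, stains)))
  list(image = rgb, stains = stains)
}

renderIf <- function(scene, spec) {
  g <- spec@geometry; p <- spec@params; q <- spec@popParams$ifCell
  w <- g@width; h <- g@height
  cells <- scene$cells
  n <- nrow(cells)
  fr <- p$ifFractions
  lab <- if (n) sample(c("green", "red", "double", "negative"), n, replace = TRUE,
                       prob = c(fr["green"], fr["red"], fr["double"], 1 - sum(fr)))
         else character(0)
  gInt <- rInt <- numeric(n)
  hiG <- lab %in% c("green", "double"); hiR <- lab %in% c("red", "double")
  gInt[hiG] <- truncNorm(sum(hiG), q$hi, 0.1 * q$hi); gInt[!hiG] <- truncNorm(sum(!hiG), q$lo, 0.02)
  rInt[hiR] <- truncNorm(sum(hiR), q$hi, 0.1 * q$hi); rInt[!hiR] <- truncNorm(sum(!hiR), q$lo, 0.02)
  dapi <- matrix(0, w, h); green <- matrix(0, w, h); red <- matrix(0, w, h)
  for (i in seq_len(n)) {
    r <- cells$radius_px[i]
    dapi <- paintDisc(dapi, cells$x[i], cells$y[i], r, q$dapi, "max")
    green <- paintDisc(green, cells$x[i], cells$y[i], r + 5, gInt[i], "max")
    red <- paintDisc(red, cells$x[i], cells$y[i], r + 5, rInt[i], "max")
  }
  dapi <- blurNoise(dapi, p$blurSigma, p$noiseSd, 0, 1)
  green <- blurNoise(green, p$blurSigma, p$noiseSd, 0, 1)
  red <- blurNoise(red, p$blurSigma, p$noiseSd, 0, 1)
  cells$if_label <- lab
  cells$green_true <- gInt
  cells$red_true <- rInt
  list(image = array(c(dapi, green, red), c(w, h, 3L)), cells = cells,
       counts = c(table(factor(lab, levels = c("green", "red", "double", "negative")))))
}

#' Render a synthetic brightfield FOV with ground truth
#'
#' Builds the scene (hard-core nuclei placement, portal tracts with ductal
#' rings, scattered and clustered CD45+ cells, fat vacuoles, irregular
#' low-haematoxylin necrosis, Sirius-Red collagen ribbons), paints
#' per-stain optical-density maps, applies mild blur and Gaussian OD noise,
#' and composes RGB through the scene's stain matrix. Truth is recorded
#' before rendering.
#'
#' @param spec a [SceneSpec-class] with `sceneType` `"ihc"`, `"he"` or
#'   `"sirius"`.
#' @return A [SyntheticFov-class].
#' @examples
#' fov <- generateBrightfield(sceneSpec(192, 192, seed = 7, hepatocyteDensity = 800))
#' nrow(fovTruth(fov)$cells)
#' @export
generateBrightfield <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  if (spec@sceneType == "if") stop("use generateIf() for fluorescence scenes")
  withSeed(spec@seed, {
    scene <- buildScene(spec)
    r <- renderBrightfield(scene, spec)
    new("SyntheticFov", image = r$image,
        truth = list(cells = scene$cells, masks = scene$masks,
                     measures = scene$measures, stains = r$stains),
        spec = spec)
  })
}

#' Render a synthetic 3-channel immunofluorescence FOV
#'
#' DAPI nuclei plus per-cell green/red intensities drawn from bright and
#' dim population distributions according to the spec's four-way label
#' fractions (`ifFractions`: green-only, red-only, double-positive;
#' remainder negative).
#'
#' @param spec a [SceneSpec-class] with `sceneType = "if"`.
#' @return A [SyntheticFov-class]; image channels are DAPI, green, red in
#'   \[0,1\].
#' @export
generateIf <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  if (spec@sceneType != "if") stop("spec@sceneType must be 'if'")
  withSeed(spec@seed, {
    scene <- buildScene(spec)
    r <- renderIf(scene, spec)
    meas <- scene$measures
    meas$ifCounts <- r$counts
    new("SyntheticFov", image = r$image,
        truth = list(cells = r$cells, masks = scene$masks, measures = meas),
        spec = spec)
  })
}

#' Severity ladder of scene specs
#'
#' Returns `levels` copies of the base spec with severity 0 .. levels-1,
#' all other parameters equal and per-level seeds derived deterministically
#' from `seed`. Severity jointly scales CD45 density, focus rate and
#' necrosis fraction, emulating a gradient of necroinflammatory activity.
#'
#' @param baseSpec a [SceneSpec-class].
#' @param levels integer >= 1.
#' @param seed integer base seed.
#' @return List of [SceneSpec-class] objects.
#' @export
severityLadder <- function(baseSpec, levels, seed) {
  stopifnot(is(baseSpec, "SceneSpec"), levels >= 1L)
  lapply(seq_len(levels), function(i) {
    s <- baseSpec
    s@severity <- as.numeric(i - 1L)
    s@seed <- deriveSeed(seed, i)
    s
  })
}
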