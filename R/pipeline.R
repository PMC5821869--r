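#' Analyse one brightfield FOV in memory
#'
#' The full per-FOV pipeline: Beer-Lambert OD conversion, colour
#' deconvolution into per-stain maps, tissue/region detection, nuclei
#' segmentation on the haematoxylin map, per-cell measurement, marker
#' phenotyping, inflammatory-focus detection (when a CD45 rule is
#' supplied) and, when a portal annotation is available, the four
#' surrogate necroinflammatory measures.
#'
#' @param rgb numeric array `w x h x 3`, intensities 0-255.
#' @param geometry an [FovGeometry-class].
#' @param stains a [StainMatrix-class] (must include `haematoxylin`).
#' @param rules list of [PhenotypeRule-class] objects applied in order.
#' @param portal optional logical portal annotation mask.
#' @param params list of detector overrides (see [buildRegionMasks()];
#'   additionally `minAreaUm2`, `ringRadiusPx`, `bandWidthUm`,
#'   `linkingDistanceUm`, `minFocusSize`, `segThreshold`).
#' @return List: `cells` (measured, phenotyped), `labels`, `masks` (a
#'   [RegionMaskSet-class]), `foci`, `measures` (a
#'   [SurrogateScores-class] or `NULL`), `summary` (plain list of counts
#'   and fractions).
#' @export
analyzeFov <- function(rgb, geometry, stains = defaultStains(), rules = list(),
                       portal = NULL, params = list()) {
  if (!"haematoxylin" %in% stainNames(stains))
    stop("the stain system must include 'haematoxylin'")
  od <- rgbToOd(rgb)
  conc <- deconvolveStains(od, stains)
  masks <- buildRegionMasks(rgb, conc$haematoxylin, geometry, portal = portal,
                            siriusOd = conc$sirius_red,
                            bandWidthUm = params$bandWidthUm %||% 25,
                            params = params)
  seg <- segmentNuclei(conc$haematoxylin, geometry,
                       threshold = params$segThreshold,
                       minAreaUm2 = params$minAreaUm2 %||% 10)
  cells <- measureCells(seg$labels, seg$cells, conc, geometry,
                        ringRadiusPx = params$ringRadiusPx %||% 3)
  phenoSummaries <- list()
  for (rule in rules) {
    res <- classifyMarker(cells, rule)
    cells <- res$cells
    phenoSummaries[[rule@marker]] <- res$summary
  }
  foci <- data.frame(focus_id = integer(0), cell_count = integer(0),
                     x = numeric(0), y = numeric(0))
  if ("pheno_cd45" %in% names(cells)) {
    cd45 <- cells[cells$pheno_cd45 == "positive", , drop = FALSE]
    foci <- detectFoci(cd45, geometry,
                       linkingDistanceUm = params$linkingDistanceUm %||% 30,
                       minFocusSize = params$minFocusSize %||% 5L)$foci
  }
  measures <- NULL
  if (!is.null(portal) && "pheno_cd45" %in% names(cells))
    measures <- surrogateMeasures(cells, foci, masks, geometry)
  fr <- areaFractions(masks)
  summary <- list(
    n_cells = nrow(cells),
    phenotypes = lapply(phenoSummaries, as.list),
    area_fractions = as.list(fr),
    tissue_area_mm2 = pxToMm2(sum(masks@tissue), geometry),
    n_foci = nrow(foci))
  if (!is.null(measures)) summary$surrogate_measures <- as.list(measures@measures)
  list(cells = cells, labels = seg$labels, masks = masks, foci = foci,
       measures = measures, summary = summary)
}

#' Analyse one 3-channel immunofluorescence FOV
#'
#' Segments nuclei on the DAPI channel, measures per-cell channel
#' intensities (normalised per channel to \[0,1\] by the 99.9th
#' percentile, making thresholds exposure-invariant) and classifies the
#' four-way double-label phenotype.
#'
#' @param channels numeric array `w x h x 3` (DAPI, green, red) in
#'   \[0,1\], or a named list of three matrices.
#' @param geometry an [FovGeometry-class].
#' @param ruleGreen,ruleRed [PhenotypeRule-class] objects on the
#'   `int_green_ring` / `int_red_ring` features (defaults threshold 0.35).
#' @param params list: `minAreaUm2`, `ringRadiusPx`, `segThreshold`.
#' @return List: `cells`, `labels`, `counts` (green/red/double/negative),
#'   `summary`.
#' @export
analyzeIfFov <- function(channels, geometry,
                         ruleGreen = phenotypeRule("green", "int_green_ring", 0.35),
                         ruleRed = phenotypeRule("red", "int_red_ring", 0.35),
                         params = list()) {
  if (is.list(channels) && !is.array(channels))
    channels <- array(c(channels[[1]], channels[[2]], channels[[3]]),
                      c(dim(channels[[1]]), 3L))
  norm999 <- function(m) {
    q <- quantile(m, 0.999, names = FALSE)
    # only rescale when a real signal is present: normalising a blank
    # channel would amplify noise to full scale
    if (q <= 0.2) m else clamp(m / q, 0, 1)
  }
  maps <- list(dapi = norm999(channels[, , 1L]),
               green = norm999(channels[, , 2L]),
               red = norm999(channels[, , 3L]))
  seg <- segmentNuclei(maps$dapi, geometry, threshold = params$segThreshold,
                       minAreaUm2 = params$minAreaUm2 %||% 10)
  cells <- measureCells(seg$labels, seg$cells, maps, geometry,
                        ringRadiusPx = params$ringRadiusPx %||% 3, prefix = "int")
  dd <- classifyDoubleIf(cells, ruleGreen, ruleRed)
  list(cells = dd$cells, labels = seg$labels, counts = dd$counts,
       summary = list(n_cells = nrow(cells), counts = as.list(dd$counts)))
}

#' Read a run configuration file
#'
#' YAML with top-level keys `input`, `stains`, `geometry`, `rules`,
#' `ductal_model`, `regions`, `binning`, `output_dir`, `seed`,
#' `log_level`; unknown keys are rejected and referenced files must exist.
#'
#' @param path YAML file path.
#' @return Named list (validated).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("input", "stains", "geometry", "rules", "ductal_model",
             "regions", "binning", "output_dir", "seed", "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  mpp <- cfg$geometry$microns_per_pixel %||% 0.5
  if (!is.numeric(mpp) || mpp <= 0) stop("geometry.microns_per_pixel must be positive")
  for (f in c(cfg$ductal_model, cfg$stains$file, cfg$binning$file))
    if (is.character(f) && !file.exists(f)) stop("referenced file not found: ", f)
  cfg
}

configRules <- function(cfg) {
  lapply(cfg$rules, function(r)
    phenotypeRule(r$marker, r$feature, r$threshold %||% 0, r$mode %||% "fixed"))
}

configStains <- function(cfg) {
  if (!is.null(cfg$stains$file)) readStainConfig(cfg$stains$file)
  else defaultStains(unlist(cfg$stains$names %||% c("haematoxylin", "dab")))
}

#' Run the pipeline on one FOV image file
#'
#' Reads the TIFF, runs [analyzeFov()] with the configuration, and writes
#' the result bundle (cell table CSV, 16-bit label TIFF, mask TIFFs and a
#' summary JSON) into `outDir`. Re-running with identical inputs
#' reproduces the outputs byte-for-byte.
#'
#' @param cfg configuration list from [readRunConfig()].
#' @param imagePath path to an 8-bit RGB TIFF.
#' @param outDir output directory (created if needed).
#' @param portal optional portal annotation mask (logical matrix or path
#'   to an 8-bit mask TIFF).
#' @return Invisibly, the [analyzeFov()] result with `$paths` added.
#' @export
runFov <- function(cfg, imagePath, outDir, portal = NULL) {
  if (!file.exists(imagePath)) stop("cannot read image: ", imagePath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rgb <- readFovTiff(imagePath)
  g <- fovGeometry(dim(rgb)[1L], dim(rgb)[2L],
                   cfg$geometry$microns_per_pixel %||% 0.5)
  if (is.character(portal)) portal <- asMatrix(readFovTiff(portal)[, , 1L]) > 127
  res <- analyzeFov(rgb, g, stains = configStains(cfg), rules = configRules(cfg),
                    portal = portal, params = cfg$regions %||% list())
  stem <- sub("\\.[^.]+$", "", basename(imagePath))
  paths <- list(
    cells = file.path(outDir, paste0(stem, "_cells.csv")),
    labels = file.path(outDir, paste0(stem, "_labels.tif")),
    summary = file.path(outDir, paste0(stem, "_summary.json")))
  writeCellTable(res$cells, paths$cells)
  writeImageTiff(res$labels, paths$labels, bits = 16L, max = 65535)
  for (nm in names(res$masks@masks)) {
    p <- file.path(outDir, paste0(stem, "_mask_", nm, ".tif"))
    writeImageTiff(res$masks@masks[[nm]] * 255, p)
    paths[[paste0("mask_", nm)]] <- p
  }
  summary <- res$summary
  summary$image <- basename(imagePath)
  summary$outputs <- lapply(paths, basename)
  jsonlite::write_json(summary, paths$summary, digits = 10, auto_unbox = TRUE,
                       pretty = TRUE)
  res$paths <- paths
  invisible(res)
}

#' Aggregate FOV results into a sample-level report
#'
#' Combines per-FOV surrogate measures with tissue-area weighting
#' ([scoreSample()]) and writes a sample report (JSON + CSV) when
#' `outDir` is given. All FOVs must share one geometry.
#'
#' @param fovResults list of [analyzeFov()]/[runFov()] results (each must
#'   carry surrogate `measures`).
#' @param scheme a [BinningScheme-class].
#' @param outDir optional output directory.
#' @param name sample name used in output file names.
#' @return The sample-level [SurrogateScores-class].
#' @export
runSample <- function(fovResults, scheme = defaultBinningScheme(),
                      outDir = NULL, name = "sample") {
  if (!length(fovResults)) stop("at least one FOV result is required")
  mpp <- vapply(fovResults, function(r) r$masks@geometry@micronsPerPixel, numeric(1))
  if (length(unique(mpp)) != 1L)
    stop("FOVs have inconsistent geometries (microns per pixel differ)")
  has <- vapply(fovResults, function(r) !is.null(r$measures), logical(1))
  if (!all(has)) stop("every FOV must carry surrogate measures (portal mask required)")
  areas <- vapply(fovResults, function(r) r$summary$tissue_area_mm2, numeric(1))
  scores <- scoreSample(lapply(fovResults, `[[`, "measures"), areas, scheme)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeScoreReport(scores, file.path(outDir, paste0(name, "_score.json")))
    writeScoreReport(scores, file.path(outDir, paste0(name, "_score.csv")))
  }
  scores
}

#' Materialise the standard synthetic test battery
#'
#' Writes the fixture sets the package's validation designs use: a
#' 15-FOV IHC series spanning 0-60% marker-positive fraction, a 12-FOV
#' double-IF series, an 11-sample severity ladder and a NAFLD-like fat
#' scene — images as TIFF, truth tables as CSV.
#'
#' @param outDir output directory.
#' @param seed base seed.
#' @param width,height FOV size in px.
#' @return Invisibly, a manifest data frame of the files written.
#' @export
writeFixtures <- function(outDir, seed = 1L, width = 256, height = 256) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(fov, stem) {
    ip <- file.path(outDir, paste0(stem, ".tif"))
    tp <- file.path(outDir, paste0(stem, "_truth.csv"))
    img <- fovImage(fov)
    if (fov@spec@sceneType == "if") {
      tiff::writeTIFF(aperm(img, c(2, 1, 3)), ip, bits.per.sample = 16L)
    } else {
      writeImageTiff(img, ip)
    }
    write.csv(fovTruth(fov)$cells, tp, row.names = FALSE)
    manifest[[length(manifest) + 1L]] <<- data.frame(file = basename(ip), type = "image")
    manifest[[length(manifest) + 1L]] <<- data.frame(file = basename(tp), type = "truth")
  }
  for (i in seq_len(15)) {
    frac <- 0.6 * (i - 1) / 14
    add(generateBrightfield(sceneSpec(width, height, seed = deriveSeed(seed, i),
                                      hpcFraction = frac)),
        sprintf("ihc_fov%02d", i))
  }
  for (i in seq_len(12))
    add(generateIf(sceneSpec(width, height, seed = deriveSeed(seed, 100 + i),
                             sceneType = "if", hepatocyteDensity = 1500,
                             ifFractions = c(green = 0.3, red = 0.2, double = 0.1))),
        sprintf("if_fov%02d", i))
  fovMm2 <- width * height * 0.25 / 1e6
  add(generateBrightfield(sceneSpec(width, height, seed = deriveSeed(seed, 200),
                                    fatCount = max(3L, round(120 * fovMm2)),
                                    fatDiamUm = c(8, 28),
                                    hepatocyteDensity = 1200)),
      "nafld_fat")
  ladder <- severityLadder(ladderBaseSpec(width, height), 11L, deriveSeed(seed, 300))
  for (i in seq_along(ladder))
    add(generateBrightfield(ladder[[i]]), sprintf("ladder_s%02d", i - 1L))
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Base scene of the severity-ladder design
#'
#' The hepatitis-like scene whose inflammatory drivers the severity level
#' scales: one portal tract, CD45 singles at 100 cells/mm^2 per severity
#' unit, foci at 2/mm^2 per unit, necrosis at 3% of tissue per unit.
#'
#' @param width,height FOV size in px.
#' @param seed integer seed.
#' @return A [SceneSpec-class] (severity 1; use [severityLadder()]).
#' @export
ladderBaseSpec <- function(width = 256, height = 256, seed = 1L) {
  sceneSpec(width, height, seed = seed, sceneType = "ihc",
            hepatocyteDensity = 1500, portalTracts = 1L, ductalCellsPerTract = 8L,
            cd45Density = 100, focusRate = 2, focusSizeMean = 7,
            necrosisFraction = 0.03,
            markerStained = "cd45")
}
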