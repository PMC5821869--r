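#' StainMatrix: the colour system of a stained slide
#'
#' Each stain is a unit-norm optical-density vector in RGB space
#' (Beer-Lambert absorbance directions). One to three linearly independent
#' stains define the linear system solved by [deconvolveStains()].
#'
#' @slot vectors numeric matrix, one row per stain, three columns (R, G, B
#'   optical-density components), each row unit Euclidean norm.
#' @export
setClass("StainMatrix", representation(vectors = "matrix"))

setValidity("StainMatrix", function(object) {
  v <- object@vectors
  if (!is.numeric(v) || ncol(v) != 3L) return("vectors must be an n x 3 numeric matrix")
  if (nrow(v) < 1L || nrow(v) > 3L) return("between 1 and 3 stains required")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("stains must carry unique names (rownames)")
  if (any(!is.finite(v)) || any(v < 0)) return("stain vectors must be finite and non-negative")
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-9)) return("each stain vector must have unit Euclidean norm")
  if (nrow(v) > 1L) {
    sv <- svd(v)$d
    if (sv[length(sv)] / sv[1L] < 1e-12) return("stain vectors must be linearly independent")
  }
  TRUE
})

#' Construct a StainMatrix
#'
#' @param vectors numeric matrix (stains x 3) of non-negative OD components;
#'   rows are normalised to unit norm.
#' @param names optional character vector of stain names (otherwise taken
#'   from rownames).
#' @return A [StainMatrix-class] object.
#' @examples
#' stainMatrix(rbind(haematoxylin = c(0.65, 0.70, 0.29),
#'                   dab          = c(0.27, 0.57, 0.78)))
#' @export
stainMatrix <- function(vectors, names = rownames(vectors)) {
  vectors <- as.matrix(vectors)
  if (is.null(names)) stop("stain names are required")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm <= 0)) stop("stain vectors must be non-zero")
  vectors <- vectors / nrm
  rownames(vectors) <- names
  colnames(vectors) <- c("r", "g", "b")
  new("StainMatrix", vectors = vectors)
}

#' @describeIn stainMatrix Names of the stains, in order.
#' @param x a `StainMatrix`.
#' @export
stainNames <- function(x) rownames(x@vectors)

setMethod("show", "StainMatrix", function(object) {
  cat("StainMatrix with", nrow(object@vectors), "stain(s):\n")
  print(round(object@vectors, 4))
})

#' FovGeometry: pixel grid and physical scale of one field of view
#'
#' @slot width,height image size in pixels.
#' @slot micronsPerPixel physical pixel size; constrained to (0.1, 2.0),
#'   the plausible range for a 20x slide scanner.
#' @export
setClass("FovGeometry",
  representation(width = "integer", height = "integer", micronsPerPixel = "numeric"))

setValidity("FovGeometry", function(object) {
  if (object@width < 1L || object@height < 1L) return("width and height must be positive")
  mpp <- object@micronsPerPixel
  if (!is.finite(mpp) || mpp <= 0.1 || mpp >= 2.0)
    return("micronsPerPixel must lie in (0.1, 2.0)")
  TRUE
})

#' Construct an FovGeometry
#'
#' @param width,height image size in pixels.
#' @param micronsPerPixel physical pixel size in micrometres.
#' @return A [FovGeometry-class] object.
#' @export
fovGeometry <- function(width, height, micronsPerPixel = 0.5)
  new("FovGeometry", width = as.integer(width), height = as.integer(height),
      micronsPerPixel = as.numeric(micronsPerPixel))

#' @describeIn fovGeometry Area of one pixel in square micrometres.
#' @param geometry an `FovGeometry`.
#' @export
pixelAreaUm2 <- function(geometry) geometry@micronsPerPixel^2

#' @describeIn fovGeometry Convert a pixel count to square millimetres.
#' @param npx pixel count.
#' @export
pxToMm2 <- function(npx, geometry) npx * geometry@micronsPerPixel^2 / 1e6

setMethod("show", "FovGeometry", function(object) {
  cat(sprintf("FovGeometry %d x %d px at %.3f um/px (%.4f mm^2)\n",
              object@width, object@height, object@micronsPerPixel,
              pxToMm2(object@width * object@height, object)))
})

#' PhenotypeRule: a marker-positivity decision rule
#'
#' Positivity is decided per cell by comparing one measured feature (a
#' column of the cell table, e.g. cytoplasmic DAB optical density) to a
#' threshold. The threshold is either fixed, or found per FOV by Otsu's
#' method or a two-component 1-D Gaussian mixture on the feature
#' distribution; data-driven modes fall back to the fixed threshold when
#' the feature distribution is effectively unimodal.
#'
#' @slot marker marker name (e.g. `"pck"`, `"cd45"`).
#' @slot feature cell-table column the rule thresholds.
#' @slot threshold fixed threshold (also the fall-back for data-driven modes).
#' @slot mode one of `"fixed"`, `"otsu"`, `"gmm2"`.
#' @export
setClass("PhenotypeRule",
  representation(marker = "character", feature = "character",
                 threshold = "numeric", mode = "character"))

setValidity("PhenotypeRule", function(object) {
  if (!object@mode %in% c("fixed", "otsu", "gmm2"))
    return("mode must be one of 'fixed', 'otsu', 'gmm2'")
  if (object@mode == "fixed" && (!is.finite(object@threshold) || object@threshold < 0))
    return("fixed threshold must be a finite non-negative number")
  TRUE
})

#' Construct a PhenotypeRule
#'
#' @param marker marker name.
#' @param feature cell-table column name holding the decision feature.
#' @param threshold fixed threshold / fall-back value.
#' @param mode `"fixed"`, `"otsu"` or `"gmm2"`.
#' @return A [PhenotypeRule-class].
#' @export
phenotypeRule <- function(marker, feature, threshold, mode = "fixed")
  new("PhenotypeRule", marker = marker, feature = feature,
      threshold = as.numeric(threshold), mode = mode)

setMethod("show", "PhenotypeRule", function(object) {
  cat(sprintf("PhenotypeRule '%s': %s > %s (mode %s)\n", object@marker,
              object@feature, format(object@threshold), object@mode))
})

#' DuctalModel: Fisher discriminant for ductal vs non-ductal cells
#'
#' A linear discriminant on three per-cell features (nucleus area,
#' nuclear haematoxylin OD, cytoplasmic DAB OD); the stored direction is
#' oriented so that ductal cells score positive.
#'
#' @slot features character vector of feature (cell-table column) names.
#' @slot weights discriminant weights, one per feature.
#' @slot intercept scalar offset; score = x . w + intercept.
#' @slot classMeans 2 x p matrix of per-class training feature means
#'   (rows `ductal`, `non_ductal`).
#' @export
setClass("DuctalModel",
  representation(features = "character", weights = "numeric",
                 intercept = "numeric", classMeans = "matrix"))

setValidity("DuctalModel", function(object) {
  if (length(object@weights) != length(object@features))
    return("one weight per feature required")
  if (!all(rownames(object@classMeans) == c("ductal", "non_ductal")))
    return("classMeans rows must be 'ductal', 'non_ductal'")
  if (any(!is.finite(object@weights)) || !is.finite(object@intercept))
    return("weights and intercept must be finite")
  TRUE
})

setMethod("show", "DuctalModel", function(object) {
  cat("DuctalModel (Fisher linear discriminant)\n  features:",
      paste(object@features, collapse = ", "), "\n  weights: ",
      paste(signif(object@weights, 4), collapse = ", "),
      "\n  intercept:", signif(object@intercept, 4), "\n")
})

#' RegionMaskSet: binary masks of histological features in one FOV
#'
#' @slot masks named list of logical matrices (e.g. `necrosis`, `fat`,
#'   `collagen`, `portal`, `periportal_band`), each a subset of the tissue.
#' @slot tissue logical matrix; TRUE where tissue (not glass) is present.
#' @slot geometry the FOV geometry.
#' @export
setClass("RegionMaskSet",
  representation(masks = "list", tissue = "matrix", geometry = "FovGeometry"))

setValidity("RegionMaskSet", function(object) {
  d <- dim(object@tissue)
  if (!is.logical(object@tissue)) return("tissue must be a logical matrix")
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), d))
      return(sprintf("mask '%s' must be a logical matrix of the tissue's shape", nm))
    if (any(m & !object@tissue))
      return(sprintf("mask '%s' extends outside the tissue mask", nm))
  }
  if (all(c("fat", "necrosis") %in% names(object@masks)) &&
      any(object@masks$fat & object@masks$necrosis))
    return("fat and necrosis masks must be disjoint")
  TRUE
})

#' Construct a RegionMaskSet
#'
#' Feature masks are clipped to the tissue mask on construction.
#'
#' @param masks named list of logical matrices.
#' @param tissue logical tissue matrix.
#' @param geometry an [FovGeometry-class].
#' @return A [RegionMaskSet-class].
#' @export
regionMaskSet <- function(masks, tissue, geometry) {
  tissue <- asMatrix(tissue) > 0
  masks <- lapply(masks, function(m) (asMatrix(m) > 0) & tissue)
  new("RegionMaskSet", masks = masks, tissue = tissue, geometry = geometry)
}

#' @describeIn regionMaskSet Extract one feature mask (logical matrix).
#' @param x a `RegionMaskSet`.
#' @param name feature name.
#' @export
regionMask <- function(x, name) {
  if (!name %in% names(x@masks)) stop("no mask named '", name, "'")
  x@masks[[name]]
}

#' @describeIn regionMaskSet Area fraction of each feature mask over tissue.
#' @export
areaFractions <- function(x) {
  tp <- sum(x@tissue)
  vapply(x@masks, function(m) if (tp == 0) 0 else sum(m) / tp, numeric(1))
}

setMethod("show", "RegionMaskSet", function(object) {
  fr <- areaFractions(object)
  cat("RegionMaskSet:", paste(sprintf("%s=%.3f", names(fr), fr), collapse = ", "),
      sprintf("(tissue %.1f%%)\n", 100 * mean(object@tissue)))
})

#' BinningScheme: surrogate-measure to ordinal-score mapping
#'
#' Each scoring category carries a strictly increasing threshold vector;
#' a measure maps to the number of thresholds strictly below it, so a
#' measure exactly on a boundary takes the lower bin. Threshold-vector
#' length equals the category's maximum ordinal score.
#'
#' @slot thresholds named list of strictly increasing numeric vectors, one
#'   per category (`piecemeal`, `confluent`, `lobular`, `portal`).
#' @export
setClass("BinningScheme", representation(thresholds = "list"))

setValidity("BinningScheme", function(object) {
  th <- object@thresholds
  if (is.null(names(th)) || any(names(th) == "")) return("categories must be named")
  for (nm in names(th)) {
    t <- th[[nm]]
    if (length(t) < 1L || any(!is.finite(t))) return(sprintf("'%s': finite thresholds required", nm))
    if (any(diff(t) <= 0)) return(sprintf("'%s': thresholds must be strictly increasing", nm))
  }
  TRUE
})

#' Construct a BinningScheme
#'
#' @param thresholds named list of strictly increasing numeric vectors.
#' @return A [BinningScheme-class].
#' @export
binningScheme <- function(thresholds) new("BinningScheme", thresholds = thresholds)

#' Default surrogate-score binning scheme
#'
#' Reads the scheme shipped in `inst/extdata/binning.yaml`: ordinal ranges
#' 0-4 (piecemeal), 0-6 (confluent), 0-4 (lobular), 0-4 (portal), composite
#' 0-18, following the Ishak grading ranges; boundary values calibrated on
#' the synthetic severity-ladder design.
#'
#' @return A [BinningScheme-class].
#' @export
defaultBinningScheme <- function() {
  path <- system.file("extdata", "binning.yaml", package = "hepaquant", mustWork = TRUE)
  binningScheme(lapply(yaml::read_yaml(path), as.numeric))
}

setMethod("show", "BinningScheme", function(object) {
  cat("BinningScheme:\n")
  for (nm in names(object@thresholds))
    cat(sprintf("  %-10s [0..%d]: %s\n", nm, length(object@thresholds[[nm]]),
                paste(object@thresholds[[nm]], collapse = ", ")))
})

#' SurrogateScores: surrogate necroinflammatory measures and composite
#'
#' Holds the four continuous surrogate measures (piecemeal: CD45+ cells
#' per mm^2 of periportal band; confluent: necrotic fraction of tissue;
#' lobular: inflammatory foci per mm^2 of lobular tissue; portal: CD45+
#' cells per mm^2 of portal regions), their ordinal bins and the additive
#' composite (hepatic-activity-index analogue).
#'
#' @slot measures named numeric vector of the four continuous measures.
#' @slot ordinal named integer vector of ordinal scores (may be empty
#'   before binning).
#' @slot composite integer; sum of the ordinals (NA before binning).
#' @export
setClass("SurrogateScores",
  representation(measures = "numeric", ordinal = "integer", composite = "integer"))

surrogateCategories <- c("piecemeal", "confluent", "lobular", "portal")

setValidity("SurrogateScores", function(object) {
  if (!identical(names(object@measures), surrogateCategories))
    return("measures must be named piecemeal, confluent, lobular, portal (in order)")
  if (any(object@measures < 0, na.rm = TRUE)) return("measures must be non-negative")
  if (length(object@ordinal)) {
    if (!identical(names(object@ordinal), surrogateCategories))
      return("ordinal must cover the four categories in order")
    if (!identical(object@composite, sum(object@ordinal)))
      return("composite must equal the sum of the ordinal scores")
  }
  TRUE
})

#' @describeIn binScores Continuous surrogate measures.
#' @export
scoreMeasures <- function(x) x@measures

#' @describeIn binScores Ordinal per-category scores.
#' @export
scoreOrdinal <- function(x) x@ordinal

#' @describeIn binScores The additive composite score.
#' @export
scoreComposite <- function(x) x@composite

setMethod("show", "SurrogateScores", function(object) {
  cat("SurrogateScores\n")
  df <- data.frame(measure = signif(object@measures, 4))
  if (length(object@ordinal)) df$ordinal <- object@ordinal
  print(df)
  if (length(object@ordinal)) cat("composite:", object@composite, "\n")
})
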