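cellsInMask <- function(cells, mask) {
  if (nrow(cells) == 0L) return(logical(0))
  i <- clamp(round(cells$x) + 1L, 1L, nrow(mask))
  j <- clamp(round(cells$y) + 1L, 1L, ncol(mask))
  mask[cbind(i, j)]
}

#' Compute the four surrogate necroinflammatory measures for one FOV
#'
#' The surrogates stand in for the descriptive Ishak-Knodell categories:
#' \describe{
#'   \item{piecemeal}{CD45+ cells per mm^2 of the periportal band
#'     (limiting-plate erosion, interface hepatitis).}
#'   \item{confluent}{necrotic fraction of tissue, in \[0,1\].}
#'   \item{lobular}{inflammatory foci per mm^2 of lobular tissue.}
#'   \item{portal}{CD45+ cells per mm^2 of portal regions.}
#' }
#' A density is 0 when its region is empty.
#'
#' @param cells cell data frame with CD45 phenotypes assigned
#'   (`pheno_cd45` column of `"positive"`/`"negative"`).
#' @param foci focus data frame from [detectFoci()] (`x`, `y` centroids).
#' @param masks a [RegionMaskSet-class] with `necrosis`, `portal`,
#'   `periportal_band` and `lobular` masks.
#' @param geometry an [FovGeometry-class].
#' @return A [SurrogateScores-class] carrying measures only (no ordinal
#'   bins yet).
#' @export
surrogateMeasures <- function(cells, foci, masks, geometry) {
  if (nrow(cells) && !"pheno_cd45" %in% names(cells))
    stop("cells lack a 'pheno_cd45' phenotype column")
  need <- c("necrosis", "portal", "periportal_band", "lobular")
  miss <- setdiff(need, names(masks@masks))
  if (length(miss)) stop("missing region mask(s): ", paste(miss, collapse = ", "))
  cd45 <- if (nrow(cells)) cells[cells$pheno_cd45 == "positive", , drop = FALSE]
          else cells
  areaMm2 <- function(m) pxToMm2(sum(m), geometry)
  density <- function(pts, mask) {
    a <- areaMm2(mask)
    if (a <= 0) 0 else sum(cellsInMask(pts, mask)) / a
  }
  tissuePx <- sum(masks@tissue)
  m <- c(piecemeal = density(cd45, regionMask(masks, "periportal_band")),
         confluent = if (tissuePx) sum(regionMask(masks, "necrosis")) / tissuePx else 0,
         lobular = density(foci, regionMask(masks, "lobular")),
         portal = density(cd45, regionMask(masks, "portal")))
  new("SurrogateScores", measures = m, ordinal = integer(0), composite = NA_integer_)
}

#' Bin surrogate measures to ordinal scores and sum the composite
#'
#' Each ordinal is the number of the category's thresholds strictly below
#' the measure (a measure exactly on a boundary takes the lower bin); the
#' composite is the exact integer sum of the four ordinals, the analogue
#' of summing the category values into the hepatic activity index.
#'
#' @param measures a [SurrogateScores-class] (measures only) or a named
#'   numeric vector over `piecemeal`, `confluent`, `lobular`, `portal`.
#' @param scheme a [BinningScheme-class]; default [defaultBinningScheme()].
#' @return A [SurrogateScores-class] with `ordinal` and `composite` set.
#' @examples
#' m <- c(piecemeal = 350, confluent = 0.02, lobular = 0, portal = 90)
#' scoreComposite(binScores(m))
#' @export
binScores <- function(measures, scheme = defaultBinningScheme()) {
  stopifnot(is(scheme, "BinningScheme"))
  m <- if (is(measures, "SurrogateScores")) measures@measures else measures
  if (!all(surrogateCategories %in% names(m)))
    stop("measures must cover piecemeal, confluent, lobular, portal")
  m <- m[surrogateCategories]
  miss <- setdiff(surrogateCategories, names(scheme@thresholds))
  if (length(miss)) stop("binning scheme lacks category(ies): ", paste(miss, collapse = ", "))
  ord <- vapply(surrogateCategories,
                function(k) sum(scheme@thresholds[[k]] < m[[k]]), integer(1))
  new("SurrogateScores", measures = m, ordinal = ord,
      composite = as.integer(sum(ord)))
}

#' Aggregate per-FOV surrogate measures into a sample-level score
#'
#' Measures are combined as tissue-area-weighted means across the
#' sample's FOVs before binning (a plain mean for the usual equal-size
#' FOV crops), then binned with [binScores()].
#'
#' @param fovScores list of [SurrogateScores-class] (measures from each
#'   FOV).
#' @param tissueAreasMm2 numeric vector of per-FOV tissue areas (weights).
#' @param scheme a [BinningScheme-class].
#' @return A [SurrogateScores-class] with sample-level measures, ordinals
#'   and composite.
#' @export
scoreSample <- function(fovScores, tissueAreasMm2, scheme = defaultBinningScheme()) {
  if (!length(fovScores)) stop("at least one FOV is required")
  if (length(tissueAreasMm2) != length(fovScores))
    stop("one tissue area per FOV is required")
  M <- t(vapply(fovScores, function(s) {
    stopifnot(is(s, "SurrogateScores"))
    s@measures
  }, numeric(4)))
  w <- tissueAreasMm2
  if (all(w <= 0)) w <- rep(1, length(w))
  agg <- colSums(M * w) / sum(w)
  names(agg) <- surrogateCategories
  binScores(agg, scheme)
}

#' Write a sample score report
#'
#' Writes per-category measure, ordinal and the composite as JSON and/or
#' CSV (decided by the file extension).
#'
#' @param scores a binned [SurrogateScores-class].
#' @param path output path ending in `.json` or `.csv`.
#' @return Invisibly, `path`.
#' @export
writeScoreReport <- function(scores, path) {
  df <- data.frame(category = surrogateCategories,
                   measure = as.numeric(scores@measures),
                   ordinal = as.integer(scores@ordinal))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(categories = df, composite = scores@composite),
                         path, digits = NA, auto_unbox = TRUE)
  } else {
    write.csv(rbind(df, data.frame(category = "composite",
                                   measure = NA, ordinal = scores@composite)),
              path, row.names = FALSE)
  }
  invisible(path)
}
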