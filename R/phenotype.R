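resolveThreshold <- function(x, rule, cvGuard = 0.2) {
  if (rule@mode == "fixed") return(rule@threshold)
  # data-driven cuts are undefined on effectively unimodal distributions
  # (e.g. an all-negative FOV); fall back to the rule's fixed threshold
  if (length(x) < 3L || coefVar(x) < cvGuard) return(rule@threshold)
  thr <- switch(rule@mode,
    otsu = otsuThreshold(x),
    gmm2 = gmm2Threshold(x))
  if (!is.finite(thr)) rule@threshold else thr
}

# Two-component equal-variance 1-D Gaussian mixture fitted by EM; returns
# the decision boundary between the component means.
gmm2Threshold <- function(x, maxIter = 200L, tol = 1e-8) {
  mu <- quantile(x, c(0.25, 0.75), names = FALSE)
  s2 <- stats::var(x) / 2
  pi1 <- 0.5
  for (it in seq_len(maxIter)) {
    d1 <- pi1 * stats::dnorm(x, mu[1], sqrt(s2))
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2], sqrt(s2))
    g <- d1 / pmax(d1 + d2, .Machine$double.xmin)
    muNew <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s2New <- sum(g * (x - muNew[1])^2 + (1 - g) * (x - muNew[2])^2) / length(x)
    pi1New <- mean(g)
    if (max(abs(c(muNew - mu, s2New - s2))) < tol) {
      mu <- muNew; s2 <- s2New; pi1 <- pi1New; break
    }
    mu <- muNew; s2 <- max(s2New, 1e-12); pi1 <- min(max(pi1New, 1e-6), 1 - 1e-6)
  }
  mean(sort(mu))
}

#' Classify cells as marker-positive or -negative
#'
#' A cell is positive when the rule's feature exceeds its threshold
#' (strict inequality). The positive-cell summary follows the counting
#' contract of IHC quantification: number of positive cells expressed as
#' a percentage of total cells.
#'
#' @param cells cell data frame (must contain the rule's feature column).
#' @param rule a [PhenotypeRule-class].
#' @return List with `cells` (a `pheno_<marker>` column of
#'   `"positive"`/`"negative"` added), `summary` (data frame: `marker`,
#'   `n_pos`, `n_total`, `percent_pos`) and `threshold` (the cut used).
#' @examples
#' cells <- data.frame(od_dab_ring = c(0.1, 0.1, 0.6, 0.7))
#' classifyMarker(cells, phenotypeRule("pck", "od_dab_ring", 0.3))$summary
#' @export
classifyMarker <- function(cells, rule) {
  stopifnot(is(rule, "PhenotypeRule"))
  if (!rule@feature %in% names(cells))
    stop("feature '", rule@feature, "' missing from the cell table")
  x <- cells[[rule@feature]]
  thr <- resolveThreshold(x, rule)
  pos <- x > thr
  cells[[paste0("pheno_", rule@marker)]] <- ifelse(pos, "positive", "negative")
  nTot <- length(pos); nPos <- sum(pos)
  list(cells = cells,
       summary = data.frame(marker = rule@marker, n_pos = nPos, n_total = nTot,
                            percent_pos = if (nTot) 100 * nPos / nTot else 0),
       threshold = thr)
}

#' Classify double-immunofluorescence labels
#'
#' Applies the green and red rules independently and assigns each cell one
#' of `double`, `green`, `red`, `negative`; double-positive cells are
#' counted in neither single-positive tally, so the counts partition the
#' total.
#'
#' @param cells cell data frame with both channel features.
#' @param ruleGreen,ruleRed [PhenotypeRule-class] objects for the two
#'   channels.
#' @return List with `cells` (an `pheno_if` column added) and `counts`
#'   (named integer vector `green`, `red`, `double`, `negative`).
#' @export
classifyDoubleIf <- function(cells, ruleGreen, ruleRed) {
  for (r in list(ruleGreen, ruleRed))
    if (!r@feature %in% names(cells))
      stop("feature '", r@feature, "' missing from the cell table")
  g <- cells[[ruleGreen@feature]] > resolveThreshold(cells[[ruleGreen@feature]], ruleGreen)
  r <- cells[[ruleRed@feature]] > resolveThreshold(cells[[ruleRed@feature]], ruleRed)
  lab <- ifelse(g & r, "double", ifelse(g, "green", ifelse(r, "red", "negative")))
  cells$pheno_if <- lab
  counts <- vapply(c("green", "red", "double", "negative"),
                   function(k) sum(lab == k), integer(1))
  list(cells = cells, counts = counts)
}

#' Train the ductal / non-ductal Fisher discriminant
#'
#' Fits a Fisher linear discriminant on the three features that separate
#' ductal from non-ductal marker-positive cells (nucleus area, nuclear
#' haematoxylin OD, cytoplasmic DAB OD): `w = Sw^-1 (mu_ductal -
#' mu_nonductal)` with the pooled within-class covariance `Sw`, boundary
#' at the midpoint of the projected class means. The direction is oriented
#' so ductal cells score positive. Training is deterministic.
#'
#' @param exemplars cell data frame containing the feature columns.
#' @param labels character/factor vector, `"ductal"` or `"non_ductal"`,
#'   one per exemplar; at least 5 of each class required.
#' @param features the three feature column names.
#' @return A [DuctalModel-class].
#' @export
trainDuctalModel <- function(exemplars, labels,
                             features = c("area_um2", "od_haematoxylin_nucleus",
                                          "od_dab_ring")) {
  labels <- as.character(labels)
  if (!all(labels %in% c("ductal", "non_ductal")))
    stop("labels must be 'ductal' or 'non_ductal'")
  nD <- sum(labels == "ductal"); nN <- sum(labels == "non_ductal")
  if (nD < 5L || nN < 5L)
    stop("at least 5 exemplars per class are required (got ",
         nD, " ductal, ", nN, " non_ductal)")
  miss <- setdiff(features, names(exemplars))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(exemplars[, features])
  if (any(!is.finite(X))) stop("exemplar features must be finite")
  muD <- colMeans(X[labels == "ductal", , drop = FALSE])
  muN <- colMeans(X[labels == "non_ductal", , drop = FALSE])
  Sw <- ((nD - 1) * stats::cov(X[labels == "ductal", , drop = FALSE]) +
         (nN - 1) * stats::cov(X[labels == "non_ductal", , drop = FALSE])) / (nD + nN - 2)
  Sw <- Sw + diag(1e-8 * mean(diag(Sw)) + 1e-12, ncol(X))   # ridge for degenerate features
  w <- solve(Sw, muD - muN)
  b <- -sum(w * (muD + muN)) / 2
  if (sum(w * muD) + b < 0) { w <- -w; b <- -b }            # ductal scores positive
  new("DuctalModel", features = features, weights = as.numeric(w),
      intercept = as.numeric(b),
      classMeans = rbind(ductal = muD, non_ductal = muN))
}

#' Score cells with a ductal model
#'
#' @param model a [DuctalModel-class].
#' @param cells cell data frame with the model's feature columns.
#' @return Numeric discriminant scores; positive means ductal.
#' @export
ductalScore <- function(model, cells) {
  stopifnot(is(model, "DuctalModel"))
  X <- as.matrix(cells[, model@features, drop = FALSE])
  as.numeric(X %*% model@weights) + model@intercept
}

#' Classify cells as ductal / non-ductal
#'
#' @inheritParams ductalScore
#' @return Character vector `"ductal"`/`"non_ductal"`.
#' @export
classifyDuctal <- function(model, cells)
  ifelse(ductalScore(model, cells) > 0, "ductal", "non_ductal")

#' Classify a whole FOV as portal-like or central-like
#'
#' An FOV is labelled `portal-like` when the majority of its
#' marker-positive cells score ductal under the model (ties break towards
#' portal-like, since the call is about predominance); otherwise
#' `central-like`. An FOV without positive cells gets the explicit
#' sentinel `undetermined`.
#'
#' @param cells marker-positive cells of one FOV.
#' @param model a [DuctalModel-class].
#' @return List: `label`, `nDuctal`, `nPositive`, and `featureMeans` (mean
#'   nucleus area, nuclear haematoxylin OD and cytoplasmic DAB OD of the
#'   positive cells).
#' @export
classifyFovDuctality <- function(cells, model) {
  n <- nrow(cells)
  if (n == 0L)
    return(list(label = "undetermined", nDuctal = 0L, nPositive = 0L,
                featureMeans = setNames(rep(NA_real_, length(model@features)),
                                        model@features)))
  cls <- classifyDuctal(model, cells)
  nd <- sum(cls == "ductal")
  list(label = if (nd >= n / 2) "portal-like" else "central-like",
       nDuctal = nd, nPositive = n,
       featureMeans = colMeans(as.matrix(cells[, model@features, drop = FALSE])))
}

#' Serialise / restore a ductal model as JSON
#'
#' @param model a [DuctalModel-class].
#' @param path file path.
#' @return `writeDuctalModel` invisibly returns `path`;
#'   `readDuctalModel` returns the model.
#' @export
writeDuctalModel <- function(model, path) {
  jsonlite::write_json(list(features = model@features, weights = model@weights,
                            intercept = model@intercept,
                            classMeans = as.data.frame(model@classMeans)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDuctalModel
#' @export
readDuctalModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- as.matrix(j$classMeans)
  rownames(cm) <- c("ductal", "non_ductal")
  colnames(cm) <- j$features
  new("DuctalModel", features = j$features, weights = as.numeric(j$weights),
      intercept = as.numeric(j$intercept), classMeans = cm)
}
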