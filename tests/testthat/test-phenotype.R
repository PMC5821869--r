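test_that("fixed-threshold positivity follows the counting contract", {
  cells <- data.frame(od_dab_ring = c(rep(0.1, 7), rep(0.6, 3)))
  res <- classifyMarker(cells, phenotypeRule("pck", "od_dab_ring", 0.3))
  expect_identical(res$summary$n_pos, 3L)
  expect_identical(res$summary$n_total, 10L)
  expect_equal(res$summary$percent_pos, 30.0)
  # counts partition totals
  tab <- table(res$cells$pheno_pck)
  expect_identical(sum(tab), 10L)
  allNeg <- classifyMarker(data.frame(od_dab_ring = rep(0.1, 5)),
                           phenotypeRule("pck", "od_dab_ring", 0.3))
  expect_equal(allNeg$summary$percent_pos, 0)
  expect_error(classifyMarker(cells, phenotypeRule("pck", "nope", 0.3)), "missing")
})

test_that("fixed thresholds are order- and affine-invariant", {
  set.seed(5)
  x <- runif(40)
  cells <- data.frame(od_dab_ring = x)
  base <- classifyMarker(cells, phenotypeRule("m", "od_dab_ring", 0.4))
  perm <- classifyMarker(cells[sample(40), , drop = FALSE],
                         phenotypeRule("m", "od_dab_ring", 0.4))
  expect_identical(base$summary$n_pos, perm$summary$n_pos)
  scaled <- classifyMarker(data.frame(od_dab_ring = 3 * x + 1),
                           phenotypeRule("m", "od_dab_ring", 3 * 0.4 + 1))
  expect_identical(base$summary$n_pos, scaled$summary$n_pos)
})

test_that("data-driven thresholds separate a bimodal DAB distribution", {
  set.seed(9)
  n <- 300
  truthPos <- runif(n) < 0.4
  x <- ifelse(truthPos, rnorm(n, 0.6, 0.05), rnorm(n, 0.1, 0.05))
  cells <- data.frame(od_dab_ring = pmax(x, 0))
  for (mode in c("otsu", "gmm2")) {
    res <- classifyMarker(cells, phenotypeRule("pck", "od_dab_ring", 0.3, mode))
    acc <- mean((res$cells$pheno_pck == "positive") == truthPos)
    expect_gte(acc, 0.99)
  }
  # unimodal input falls back to the fixed threshold instead of cutting noise
  uni <- data.frame(od_dab_ring = rnorm(200, 0.1, 0.01))
  res <- classifyMarker(uni, phenotypeRule("pck", "od_dab_ring", 0.3, "otsu"))
  expect_identical(res$summary$n_pos, 0L)
})

test_that("double-IF labels partition the total and follow the definitions", {
  cells <- data.frame(int_green_ring = c(0.8, 0.8, 0.2, 0.1),
                      int_red_ring = c(0.7, 0.2, 0.9, 0.2))
  res <- classifyDoubleIf(cells,
                          phenotypeRule("pck", "int_green_ring", 0.5),
                          phenotypeRule("gctm5", "int_red_ring", 0.5))
  expect_identical(res$cells$pheno_if, c("double", "green", "red", "negative"))
  expect_identical(unname(res$counts), c(1L, 1L, 1L, 1L))
  expect_identical(sum(res$counts), nrow(cells))
})

test_that("count-level recovery mirrors the manual-count validation design", {
  # 14+ FOVs spanning 0-60% positive fraction; r^2 against truth >= 0.92
  truth <- pipe <- numeric(14)
  for (i in 1:14) {
    frac <- 0.6 * (i - 1) / 13
    fov <- generateBrightfield(sceneSpec(256, 256, seed = 500 + i,
                                         hpcFraction = frac))
    res <- analyzeFov(fovImage(fov), fov@spec@geometry,
                      rules = list(phenotypeRule("pck", "od_dab_ring", 0.35, "otsu")))
    truth[i] <- fovTruth(fov)$measures$percentPositive
    pipe[i] <- res$summary$phenotypes$pck$percent_pos
  }
  expect_gte(summary(stats::lm(pipe ~ truth))$r.squared, 0.92)
})

test_that("the Fisher discriminant separates well-separated populations", {
  set.seed(13)
  mk <- function(n, area, haem, dab) data.frame(
    area_um2 = rnorm(n, area, 0.1 * area),
    od_haematoxylin_nucleus = rnorm(n, haem, 0.1 * haem),
    od_dab_ring = rnorm(n, dab, 0.1 * dab))
  train <- rbind(mk(50, 60, 0.8, 0.7), mk(50, 25, 0.4, 0.3))
  labs <- rep(c("ductal", "non_ductal"), each = 50)
  mod <- trainDuctalModel(train, labs)
  held <- rbind(mk(100, 60, 0.8, 0.7), mk(100, 25, 0.4, 0.3))
  heldLabs <- rep(c("ductal", "non_ductal"), each = 100)
  expect_gte(mean(classifyDuctal(mod, held) == heldLabs), 0.98)
  # agreement with an independent LDA fit (MASS) on the same data
  skip_if_not_installed("MASS")
  lda <- MASS::lda(train, grouping = labs)
  ldaPred <- as.character(predict(lda, held)$class)
  expect_gte(mean(ldaPred == classifyDuctal(mod, held)), 0.98)
})

test_that("the discriminant is chance-level without signal and rejects bad input", {
  set.seed(17)
  mk <- function(n) data.frame(area_um2 = rnorm(n, 40, 4),
                               od_haematoxylin_nucleus = rnorm(n, 0.5, 0.05),
                               od_dab_ring = rnorm(n, 0.5, 0.05))
  mod <- trainDuctalModel(rbind(mk(100), mk(100)),
                          rep(c("ductal", "non_ductal"), each = 100))
  acc <- mean(classifyDuctal(mod, rbind(mk(500), mk(500))) ==
                rep(c("ductal", "non_ductal"), each = 500))
  expect_lt(abs(acc - 0.5), 0.1)
  expect_error(trainDuctalModel(mk(10), rep("ductal", 10)), "per class")
  expect_error(trainDuctalModel(mk(6), c(rep("ductal", 4), "non_ductal",
                                         "non_ductal")), "per class")
})

test_that("ductal models serialise to JSON and back", {
  set.seed(19)
  train <- data.frame(area_um2 = c(rnorm(10, 60, 5), rnorm(10, 25, 3)),
                      od_haematoxylin_nucleus = c(rnorm(10, 0.8, 0.05), rnorm(10, 0.4, 0.04)),
                      od_dab_ring = c(rnorm(10, 0.7, 0.05), rnorm(10, 0.3, 0.03)))
  mod <- trainDuctalModel(train, rep(c("ductal", "non_ductal"), each = 10))
  p <- withr::local_tempfile(fileext = ".json")
  writeDuctalModel(mod, p)
  mod2 <- readDuctalModel(p)
  expect_equal(mod2@weights, mod@weights)
  expect_equal(mod2@intercept, mod@intercept)
  expect_identical(mod2@features, mod@features)
})

test_that("FOV ductality follows the majority of positive cells", {
  set.seed(23)
  mk <- function(n, area, haem, dab) data.frame(
    area_um2 = rnorm(n, area, 0.1 * area),
    od_haematoxylin_nucleus = rnorm(n, haem, 0.1 * haem),
    od_dab_ring = rnorm(n, dab, 0.1 * dab))
  mod <- trainDuctalModel(rbind(mk(50, 60, 0.8, 0.7), mk(50, 25, 0.4, 0.3)),
                          rep(c("ductal", "non_ductal"), each = 50))
  expect_identical(classifyFovDuctality(mk(10, 60, 0.8, 0.7), mod)$label,
                   "portal-like")
  expect_identical(classifyFovDuctality(mk(10, 25, 0.4, 0.3), mod)$label,
                   "central-like")
  empty <- classifyFovDuctality(mk(0, 60, 0.8, 0.7), mod)
  expect_identical(empty$label, "undetermined")
  expect_identical(empty$nPositive, 0L)
})
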