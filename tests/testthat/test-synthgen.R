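test_that("identical spec and seed reproduce identical truth and pixels", {
  s <- sceneSpec(192, 192, seed = 101, hpcFraction = 0.2, cd45Density = 300,
                 focusRate = 20, necrosisFraction = 0.05, portalTracts = 1L)
  f1 <- generateBrightfield(s); f2 <- generateBrightfield(s)
  expect_identical(fovTruth(f1)$cells, fovTruth(f2)$cells)
  expect_identical(fovImage(f1), fovImage(f2))
  sIf <- sceneSpec(160, 160, seed = 55, sceneType = "if",
                   ifFractions = c(green = 0.3, red = 0.2, double = 0.1))
  g1 <- generateIf(sIf); g2 <- generateIf(sIf)
  expect_identical(fovImage(g1), fovImage(g2))
  expect_identical(fovTruth(g1)$cells$if_label, fovTruth(g2)$cells$if_label)
  # generation does not perturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generateBrightfield(s)); b <- runif(1)
  expect_identical(a, b)
})

test_that("an all-zero spec renders a blank white FOV with empty truth", {
  s <- sceneSpec(64, 64, seed = 1, tissueFraction = 0, hepatocyteDensity = 0,
                 noiseSd = 0, blurSigma = 0)
  fov <- generateBrightfield(s)
  expect_identical(nrow(fovTruth(fov)$cells), 0L)
  expect_true(all(fovImage(fov) == 255))
})

test_that("cell counts follow the spec by construction", {
  # 400 x 400 px at 0.5 um/px = 0.04 mm^2; 2500 /mm^2 -> exactly 100 nuclei
  s <- sceneSpec(400, 400, seed = 3, hepatocyteDensity = 2500)
  expect_identical(nrow(fovTruth(generateBrightfield(s))$cells), 100L)
})

test_that("infeasible hard-core packing raises a generation error", {
  s <- sceneSpec(64, 64, seed = 1, hepatocyteDensity = 60000, maxPlaceTries = 20L)
  expect_error(generateBrightfield(s), "infeasible")
})

test_that("nuclei respect the hard-core minimum spacing", {
  s <- sceneSpec(256, 256, seed = 7, hepatocyteDensity = 2500)
  tr <- fovTruth(generateBrightfield(s))$cells
  d <- as.matrix(dist(cbind(tr$x, tr$y))) * 0.5
  diag(d) <- Inf
  expect_gte(min(d), 9 * 0.85)   # tightest population-specific spacing
})

test_that("truth measures are self-consistent with the truth tables", {
  s <- sceneSpec(256, 256, seed = 11, hpcFraction = 0.3, cd45Density = 200,
                 necrosisFraction = 0.05, portalTracts = 1L)
  fov <- generateBrightfield(s)
  tr <- fovTruth(fov)
  expect_identical(tr$measures$nCells, nrow(tr$cells))
  expect_equal(tr$measures$percentPositive, 100 * mean(tr$cells$pck_true))
  expect_identical(tr$measures$cd45Count, sum(tr$cells$cd45_true))
  expect_equal(tr$measures$necrosisFraction,
               sum(tr$masks$necrosis) / sum(tr$masks$tissue))
  expect_identical(tr$measures$fociCount,
                   length(setdiff(unique(tr$cells$focus_id), 0L)))
})

test_that("IF truth labels equal the recorded multinomial draw", {
  s <- sceneSpec(320, 320, seed = 13, sceneType = "if", hepatocyteDensity = 2000,
                 ifFractions = c(green = 0.3, red = 0.2, double = 0.1))
  fov <- generateIf(s)
  tr <- fovTruth(fov)
  tab <- table(factor(tr$cells$if_label,
                      levels = c("green", "red", "double", "negative")))
  expect_identical(as.integer(tab), as.integer(tr$measures$ifCounts))
  expect_identical(sum(tab), nrow(tr$cells))
  allDouble <- generateIf(sceneSpec(160, 160, seed = 14, sceneType = "if",
                                    hepatocyteDensity = 1000,
                                    ifFractions = c(green = 0, red = 0, double = 1)))
  expect_true(all(fovTruth(allDouble)$cells$if_label == "double"))
  expect_error(sceneSpec(64, 64, sceneType = "if",
                         ifFractions = c(green = 0.6, red = 0.5, double = 0.2)),
               "sum")
})

test_that("the severity ladder scales the inflammatory drivers jointly", {
  base <- ladderBaseSpec(256, 256)
  expect_identical(length(severityLadder(base, 1L, 5)), 1L)
  ladder <- severityLadder(base, 11L, 5)
  sev <- vapply(ladder, function(s) s@severity, numeric(1))
  expect_identical(sev, as.numeric(0:10))
  effCd45 <- vapply(ladder, function(s) s@params$cd45Density * s@severity, numeric(1))
  expect_true(all(diff(effCd45) > 0))
  # realised truth tracks severity for each driver (counts are Poisson, so
  # rank correlation, not strict monotonicity, is the right assertion)
  truths <- lapply(ladder, function(s) fovTruth(generateBrightfield(s))$measures)
  cd45 <- vapply(truths, `[[`, numeric(1), "cd45Density")
  nec <- vapply(truths, `[[`, numeric(1), "necrosisFraction")
  expect_gte(cor(sev, cd45, method = "spearman"), 0.8)
  expect_gte(cor(sev, nec, method = "spearman"), 0.8)
  expect_identical(truths[[1]]$cd45Count, 0L)
  expect_equal(truths[[1]]$necrosisFraction, 0)
  expect_gt(truths[[11]]$necrosisFraction, 0.1)
})

test_that("scene specs reject invalid parameters", {
  expect_error(sceneSpec(64, 64, hpcFraction = 1.2), "exceed")
  expect_error(sceneSpec(64, 64, cd45Density = -1), "non-negative")
  expect_error(sceneSpec(64, 64, bogusParameter = 1), "unknown")
  expect_error(sceneSpec(64, 64, sceneType = "confocal"), "sceneType")
  expect_error(generateIf(sceneSpec(64, 64, sceneType = "ihc")), "if")
})

test_that("fixture materialisation writes a parseable battery", {
  out <- withr::local_tempdir()
  manifest <- writeFixtures(out, seed = 3, width = 192, height = 192)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(all(file.exists(file.path(out, manifest$file))))
  img <- readFovTiff(file.path(out, "ihc_fov01.tif"))
  expect_identical(dim(img), c(192L, 192L, 3L))
  truth <- read.csv(file.path(out, "ihc_fov01_truth.csv"))
  expect_true(all(c("x", "y", "population") %in% names(truth)))
})
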