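geomR <- fovGeometry(200, 200, 0.5)

test_that("tissue detection handles the trivial extremes", {
  white <- array(255, c(60, 60, 3))
  expect_false(any(detectTissue(white)))
  stained <- round(odToRgb(composeStains(
    list(haematoxylin = matrix(0.5, 60, 60)), defaultStains("haematoxylin"))))
  expect_true(all(detectTissue(stained)))
})

test_that("tissue fraction tracks the rendered section", {
  fov <- generateBrightfield(sceneSpec(256, 256, seed = 61, tissueFraction = 0.6,
                                       hepatocyteDensity = 1000))
  det <- mean(detectTissue(fovImage(fov)))
  truth <- fovTruth(fov)$measures$tissueFraction
  expect_lt(abs(det - truth) / truth, 0.05)
})

test_that("low-haematoxylin areas are masked against parenchyma", {
  haem <- matrix(0.5, 200, 200)
  haem <- paintTestDisc(haem, 100, 100, 30, 0.05)
  tissue <- matrix(TRUE, 200, 200)
  mask <- detectLowHaematoxylin(haem, tissue, geomR, smoothSigma = 0, openRadius = 0)
  truthMask <- paintTestDisc(matrix(0, 200, 200), 100, 100, 30, 1) > 0
  # boundary agreement within 2 px: erosion/dilation bounds
  expect_true(all(mask[paintTestDisc(matrix(0, 200, 200), 100, 100, 27, 1) > 0]))
  expect_false(any(mask[!(paintTestDisc(matrix(0, 200, 200), 100, 100, 33, 1) > 0)]))
  # homogeneous image yields nothing under the otsu guard
  uni <- matrix(0.5, 200, 200) + matrix(rnorm(4e4, 0, 0.005), 200, 200)
  expect_false(any(detectLowHaematoxylin(uni, tissue, geomR, mode = "otsu")))
})

test_that("round vacuoles are fat, irregular or large blobs are necrosis", {
  cand <- matrix(FALSE, 200, 200)
  cand <- paintTestDisc(cand, 50, 50, 30, TRUE)            # diam 30 um at 0.5 um/px
  fn <- splitFatVsNecrosis(cand, geomR)
  expect_true(any(fn$fat)); expect_false(any(fn$necrosis))
  # a 0.1 mm^2 blob is far beyond the vacuole size range -> necrosis
  big <- matrix(FALSE, 1000, 1000)
  big <- paintTestDisc(big, 500, 500, 360, TRUE)           # ~0.1 mm^2 at 0.5 um/px
  fnBig <- splitFatVsNecrosis(big, fovGeometry(1000, 1000, 0.5))
  expect_true(any(fnBig$necrosis)); expect_false(any(fnBig$fat))
  # elongated band: low circularity -> necrosis
  band <- matrix(FALSE, 200, 200); band[40:160, 95:105] <- TRUE
  fnBand <- splitFatVsNecrosis(band, geomR)
  expect_true(any(fnBand$necrosis)); expect_false(any(fnBand$fat))
  expect_false(any(fn$fat & fn$necrosis))
})

test_that("planted fat and necrosis are recovered within 10% of truth", {
  fov <- generateBrightfield(sceneSpec(640, 640, seed = 23, fatCount = 20L,
                                       necrosisFraction = 0.12,
                                       hepatocyteDensity = 1200))
  g <- fov@spec@geometry
  conc <- deconvolveStains(rgbToOd(fovImage(fov)),
                           defaultStains(c("haematoxylin", "dab")))
  tissue <- detectTissue(fovImage(fov))
  cand <- detectLowHaematoxylin(conc$haematoxylin, tissue, g)
  fn <- splitFatVsNecrosis(cand, g)
  trm <- fovTruth(fov)$masks
  expect_lt(abs(sum(fn$necrosis) - sum(trm$necrosis)) / sum(trm$necrosis), 0.10)
  # at least 18 of 20 vacuoles assigned to fat
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(trm$fat)))
  hits <- sum(vapply(seq_len(max(lab)), function(k) mean(fn$fat[lab == k]) > 0.5,
                     logical(1)))
  expect_gte(hits, 18L)
})

test_that("collagen fraction matches the painted ribbons and is monotone", {
  stains <- defaultStains(c("haematoxylin", "sirius_red"))
  zero <- detectCollagen(matrix(0, 100, 100), matrix(TRUE, 100, 100),
                         fovGeometry(100, 100, 0.5))
  expect_identical(zero$fraction, 0)
  fracs <- c(0.02, 0.05, 0.08, 0.12, 0.18)
  det <- numeric(length(fracs))
  for (i in seq_along(fracs)) {
    fov <- generateBrightfield(sceneSpec(384, 384, seed = 70 + i,
                                         sceneType = "sirius",
                                         collagenFraction = fracs[i],
                                         hepatocyteDensity = 1200))
    conc <- deconvolveStains(rgbToOd(fovImage(fov)), stains)
    tissue <- detectTissue(fovImage(fov))
    col <- detectCollagen(conc$sirius_red, tissue, fov@spec@geometry)
    truth <- fovTruth(fov)$measures$collagenFraction
    expect_lt(abs(col$fraction - truth) / truth, 0.10)
    det[i] <- col$fraction
  }
  expect_true(all(diff(det) > 0))
})

test_that("focus definitions: five linked cells make a focus, four do not", {
  g <- fovGeometry(400, 400, 0.5)
  inDisc <- data.frame(x = c(100, 110, 120, 105, 115), y = c(100, 108, 100, 92, 96))
  res <- detectFoci(inDisc, g, linkingDistanceUm = 30, minFocusSize = 5)
  expect_identical(nrow(res$foci), 1L)
  expect_identical(res$foci$cell_count, 5L)
  expect_identical(res$nSingles, 0L)
  res4 <- detectFoci(inDisc[1:4, ], g, linkingDistanceUm = 30, minFocusSize = 5)
  expect_identical(nrow(res4$foci), 0L)
  expect_identical(res4$nSingles, 4L)
})

test_that("focus clustering equals the brute-force linkage oracle", {
  g <- fovGeometry(600, 600, 0.5)
  set.seed(29)
  for (rep in 1:5) {
    centres <- matrix(runif(6, 100, 500), 3, 2)
    cells <- do.call(rbind, lapply(1:3, function(k)
      data.frame(x = centres[k, 1] + runif(8, -15, 15),
                 y = centres[k, 2] + runif(8, -15, 15))))
    cells <- rbind(cells, data.frame(x = runif(30, 0, 600), y = runif(30, 0, 600)))
    res <- detectFoci(cells, g, linkingDistanceUm = 30, minFocusSize = 5)
    oracle <- bruteFoci(cells, g, 30, 5)
    # same partition of cells into foci vs singles, same focus sizes
    expect_identical(sum(res$membership == 0L), sum(oracle == 0L))
    expect_identical(sort(as.integer(table(res$membership[res$membership > 0]))),
                     sort(as.integer(table(oracle[oracle > 0]))))
    # order independence
    perm <- sample(nrow(cells))
    res2 <- detectFoci(cells[perm, ], g, linkingDistanceUm = 30, minFocusSize = 5)
    expect_identical(nrow(res2$foci), nrow(res$foci))
    expect_identical(sort(res2$foci$cell_count), sort(res$foci$cell_count))
  }
})

test_that("the periportal band is the dilation annulus and is nested", {
  g <- fovGeometry(200, 200, 0.5)
  portal <- matrix(FALSE, 200, 200); portal[81:120, 81:120] <- TRUE
  band <- periportalBand(portal, 20, g)           # 40 px
  expect_false(any(band & portal))
  # area approximates the dilation arithmetic for a square + disc
  r <- 40
  expected <- 4 * 40 * r + pi * r^2
  expect_lt(abs(sum(band) - expected) / expected, 0.05)
  expect_false(any(periportalBand(matrix(FALSE, 50, 50), 20, g)))
  expect_error(periportalBand(portal, 0, g), "positive")
  set.seed(31)
  for (rep in 1:3) {
    pm <- matrix(runif(2500) < 0.01, 50, 50)
    b1 <- periportalBand(pm, 5, g); b2 <- periportalBand(pm, 12, g)
    expect_true(all(b2[b1]))
  }
})

test_that("region mask sets enforce their invariants", {
  tissue <- matrix(TRUE, 20, 20); tissue[1:5, ] <- FALSE
  feat <- matrix(FALSE, 20, 20); feat[1:10, 1:10] <- TRUE
  rms <- regionMaskSet(list(necrosis = feat), tissue, fovGeometry(20, 20, 0.5))
  expect_false(any(regionMask(rms, "necrosis") & !tissue))
  expect_true(all(areaFractions(rms) >= 0 & areaFractions(rms) <= 1))
  expect_error(regionMask(rms, "fat"), "no mask")
})
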