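mkMasks <- function(w = 200, h = 200, mpp = 0.5) {
  g <- fovGeometry(w, h, mpp)
  tissue <- matrix(TRUE, w, h)
  portal <- matrix(FALSE, w, h); portal[1:40, 1:40] <- TRUE
  band <- periportalBand(portal, 20, g, tissue)
  necrosis <- matrix(FALSE, w, h); necrosis[150:189, 150:189] <- TRUE
  lobular <- tissue & !portal & !band
  list(g = g, masks = regionMaskSet(list(necrosis = necrosis, portal = portal,
                                         periportal_band = band, lobular = lobular),
                                    tissue, g))
}

test_that("surrogate measures are densities over their processing regions", {
  mm <- mkMasks()
  emptyCells <- data.frame(x = numeric(0), y = numeric(0),
                           pheno_cd45 = character(0))
  noFoci <- data.frame(x = numeric(0), y = numeric(0))
  s0 <- surrogateMeasures(emptyCells, noFoci, mm$masks, mm$g)
  expect_equal(unname(scoreMeasures(s0)[c("piecemeal", "lobular", "portal")]),
               c(0, 0, 0))
  # 10 CD45+ cells inside a 0.1 mm^2 portal mask -> 100 cells/mm^2
  w <- 800
  g <- fovGeometry(w, w, 0.5)
  tissue <- matrix(TRUE, w, w)
  portal <- matrix(FALSE, w, w); portal[seq_len(500), ] <- TRUE
  expect_equal(sum(portal) * 0.25 / 1e6, 0.1)   # 500*800 px = 0.1 mm^2
  masks <- regionMaskSet(list(necrosis = matrix(FALSE, w, w), portal = portal,
                              periportal_band = matrix(FALSE, w, w),
                              lobular = tissue & !portal), tissue, g)
  cells <- data.frame(x = seq(10, 100, 10), y = rep(50, 10),
                      pheno_cd45 = "positive")
  s <- surrogateMeasures(cells, noFoci, masks, g)
  expect_equal(unname(scoreMeasures(s)["portal"]), 100)
  expect_error(surrogateMeasures(data.frame(x = 1, y = 1), noFoci, mm$masks, mm$g),
               "pheno_cd45")
})

test_that("confluent measure equals the necrotic fraction of tissue", {
  mm <- mkMasks()
  cells <- data.frame(x = 100, y = 100, pheno_cd45 = "negative")
  s <- surrogateMeasures(cells, data.frame(x = numeric(0), y = numeric(0)),
                         mm$masks, mm$g)
  expect_equal(unname(scoreMeasures(s)["confluent"]), 1600 / 40000)
})

test_that("ordinal binning counts thresholds strictly below the measure", {
  scheme <- binningScheme(list(piecemeal = c(100, 300, 500, 800),
                               confluent = c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25),
                               lobular = c(1, 4, 8, 14),
                               portal = c(100, 300, 500, 800)))
  s <- binScores(c(piecemeal = 350, confluent = 0.3, lobular = 2, portal = 90),
                 scheme)
  expect_identical(unname(scoreOrdinal(s)), c(2L, 6L, 1L, 0L))
  expect_identical(scoreComposite(s), 9L)
  z <- binScores(c(piecemeal = 0, confluent = 0, lobular = 0, portal = 0), scheme)
  expect_identical(scoreComposite(z), 0L)
  # boundary values take the lower bin: brute-force scan over all boundaries
  for (cat in names(scheme@thresholds)) {
    for (t in scheme@thresholds[[cat]]) {
      m <- c(piecemeal = 0, confluent = 0, lobular = 0, portal = 0)
      m[cat] <- t
      below <- sum(scheme@thresholds[[cat]] < t)          # oracle: strict count
      expect_identical(unname(scoreOrdinal(binScores(m, scheme))[cat]), below)
      m[cat] <- t + 1e-9
      expect_identical(unname(scoreOrdinal(binScores(m, scheme))[cat]), below + 1L)
    }
  }
  expect_error(binningScheme(list(piecemeal = c(3, 2, 1))), "increasing")
})

test_that("ordinals are non-decreasing step functions of their measures", {
  scheme <- defaultBinningScheme()
  for (cat in surrogateCategories <- c("piecemeal", "confluent", "lobular", "portal")) {
    hi <- max(scheme@thresholds[[cat]]) * 1.5
    xs <- seq(0, hi, length.out = 200)
    ords <- vapply(xs, function(v) {
      m <- c(piecemeal = 0, confluent = 0, lobular = 0, portal = 0); m[cat] <- v
      scoreOrdinal(binScores(m, scheme))[[cat]]
    }, integer(1))
    expect_true(all(diff(ords) >= 0))
    expect_identical(max(ords), length(scheme@thresholds[[cat]]))
  }
  # composite identity holds for random measures
  set.seed(37)
  for (i in 1:20) {
    m <- c(piecemeal = runif(1, 0, 1000), confluent = runif(1),
           lobular = runif(1, 0, 20), portal = runif(1, 0, 1000))
    s <- binScores(m, scheme)
    expect_identical(scoreComposite(s), as.integer(sum(scoreOrdinal(s))))
    expect_lte(scoreComposite(s), 18L)
  }
})

test_that("sample aggregation is the area-weighted mean of FOV measures", {
  scheme <- defaultBinningScheme()
  m1 <- c(piecemeal = 100, confluent = 0.1, lobular = 2, portal = 200)
  s1 <- new("SurrogateScores", measures = m1, ordinal = integer(0),
            composite = NA_integer_)
  s3 <- new("SurrogateScores", measures = 3 * m1, ordinal = integer(0),
            composite = NA_integer_)
  single <- scoreSample(list(s1), 1, scheme)
  expect_equal(scoreMeasures(single), scoreMeasures(binScores(m1, scheme)))
  both <- scoreSample(list(s1, s3), c(1, 1), scheme)
  expect_equal(unname(scoreMeasures(both)), unname(2 * m1))
  weighted <- scoreSample(list(s1, s3), c(3, 1), scheme)
  expect_equal(unname(scoreMeasures(weighted)), unname(1.5 * m1))
  expect_error(scoreSample(list(), numeric(0), scheme), "at least one")
})

test_that("score reports serialise to JSON and CSV", {
  s <- binScores(c(piecemeal = 350, confluent = 0.02, lobular = 0, portal = 90))
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  writeScoreReport(s, pj); writeScoreReport(s, pc)
  j <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_identical(as.integer(j$composite), scoreComposite(s))
  csv <- read.csv(pc)
  expect_identical(csv$ordinal[csv$category == "composite"],
                   as.integer(scoreComposite(s)))
})
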