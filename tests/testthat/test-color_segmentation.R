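# HSI conversion and quadric plant / non-plant segmentation.

test_that("RGB to HSI follows the intensity-mean formulation", {
  expect_equal(rgbToHsi(c(0.5, 0.5, 0.5)), c(H = 0, S = 0, I = 0.5))
  expect_equal(rgbToHsi(c(0, 1, 0)), c(H = 1 / 3, S = 1, I = 1 / 3),
               tolerance = 1e-12)
  expect_equal(rgbToHsi(c(0, 0, 0)), c(H = 0, S = 0, I = 0))
  expect_error(rgbToHsi(c(1.2, 0, 0)), "\\[0, 1\\]")
  # hue stays in [0, 1)
  set.seed(41)
  m <- matrix(runif(300), 100, 3)
  hsi <- rgbToHsi(m)
  expect_true(all(hsi[, 1] >= 0 & hsi[, 1] < 1))
})

test_that("HSI to RGB inverts the forward conversion", {
  set.seed(42)
  m <- matrix(runif(600), 200, 3)
  hsi <- rgbToHsi(m)
  back <- hsiToRgb(hsi)
  expect_lt(max(abs(back - m)), 1e-9)
})

test_that("quadric surfaces evaluate to the published constants and values", {
  model <- quadricSegModel()
  expect_equal(evalQuadric(model@plantCoeffs, 0, 0), 1.114)
  expect_equal(evalQuadric(model@nonplantCoeffs, 0, 0), 0.6475)
  expect_equal(evalQuadric(model@plantCoeffs, 0.35, 0.6), 0.036959,
               tolerance = 1e-12)
  expect_equal(evalQuadric(model@nonplantCoeffs, 0, 0.5), 0.535975,
               tolerance = 1e-12)
  expect_equal(evalQuadric(model@nonplantCoeffs, 0.35, 0.6), 0.031329,
               tolerance = 1e-12)
})

test_that("point classification separates plant, non-plant and ambiguous", {
  expect_identical(classifyHsi(c(0.35, 0.6, 0.4)), "plant")
  expect_identical(classifyHsi(c(0, 0.5, 0.5)), "nonplant")
  expect_identical(classifyHsi(c(0.35, 0.6, 0.034)), "ambiguous")
  # low saturation is always non-plant regardless of hue
  expect_identical(classifyHsi(c(0.33, 0.05, 0.8)), "nonplant")
  # when both tests would pass, plant wins
  model <- quadricSegModel()
  H <- 0.35; S <- 0.12
  I <- max(evalQuadric(model@plantCoeffs, H, S) + 1e-4, 0.051)
  if (I <= evalQuadric(model@nonplantCoeffs, H, S))
    expect_identical(classifyHsi(c(H, S, I)), "plant")
})

test_that("color smoothing returns references without touching the cloud", {
  # uniform cloud: references equal originals
  set.seed(43)
  pts <- matrix(runif(90, 0, 0.01), 30, 3)
  uni <- pointCloud(pts, matrix(rep(c(0.2, 0.6, 0.3), each = 30), 30, 3))
  ref <- smoothColors(uni, 0.005)
  expect_equal(ref, cloudColors(uni), tolerance = 1e-12)
  # isolated point keeps its own color
  iso <- pointCloud(rbind(c(0, 0, 0), c(1, 1, 1)),
                    rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(smoothColors(iso, 0.005), cloudColors(iso))
  # alternating two-color cloud with a large radius approaches the mean
  n <- 200
  line <- cbind(seq(0, 0.01, length.out = n), 0, 0)
  cols <- matrix(rep(c(1, 0), length.out = n), n, 3)
  mixed <- pointCloud(line, cols)
  ref2 <- smoothColors(mixed, 0.05)
  expect_lt(max(abs(ref2 - 0.5)), 0.05)
  expect_identical(cloudColors(mixed), cols)  # originals untouched
})

test_that("cloud segmentation partitions exhaustively and matches per-point labels", {
  sc <- genScene("small", seed = 44, ambiguousFrac = 0.02)
  seg <- segmentCloud(sc$cloud)
  n <- nPoints(sc$cloud)
  expect_identical(nPoints(seg$plant) + nPoints(seg$nonplant) +
                     nPoints(seg$ambiguous), n)
  # consistency with per-point classification of the smoothed references
  ref <- smoothColors(sc$cloud, 0.005)
  labels <- classifyHsi(rgbToHsi(ref))
  expect_identical(seg$labels, labels)
  # original colors are preserved on the outputs
  expect_identical(cloudColors(seg$plant),
                   cloudColors(sc$cloud)[labels == "plant", , drop = FALSE])
  # an all-gray cloud is entirely non-plant (S <= 0.1)
  gray <- pointCloud(matrix(runif(60), 20, 3), matrix(0.4, 20, 3))
  sg <- segmentCloud(gray, smoothRadius = 0)
  expect_identical(nPoints(sg$nonplant), 20L)
  expect_error(segmentCloud(pointCloud(matrix(numeric(0), 0, 3))), "empty")
})

test_that("colors drawn inside the acceptance regions are classified perfectly", {
  sc <- genScene("small", seed = 45, soilRoughnessSd = 0)
  seg <- segmentCloud(sc$cloud)
  truth <- c(rep("nonplant", nPoints(sc$pot) + nPoints(sc$soil)),
             rep("plant", nPoints(sc$canopy)))
  sc_scores <- segmentationScores(seg$labels, truth, "plant")
  expect_equal(sc_scores$TPR, 100)
  expect_equal(sc_scores$TNR, 100)
})

test_that("segmentation scores are 100/100 on perfect and 0/0 on inverted predictions", {
  truth <- rep(c("plant", "nonplant"), each = 10)
  expect_equal(segmentationScores(truth, truth), list(TPR = 100, TNR = 100))
  inverted <- rev(truth)
  expect_equal(segmentationScores(inverted, truth), list(TPR = 0, TNR = 0))
})

test_that("quadric boundary fitting recovers the published coefficients from its own surface", {
  model <- quadricSegModel()
  set.seed(46)
  H <- runif(100, 0.1, 0.5); S <- runif(100, 0.1, 0.9)
  I <- evalQuadric(model@plantCoeffs, H, S)
  fit <- fitQuadricBoundary(cbind(H, S, I))
  expect_equal(fit, model@plantCoeffs, tolerance = 1e-6)
  # planar samples give a constant-only quadric
  flat <- fitQuadricBoundary(cbind(H, S, 0.2))
  expect_equal(flat, c(0.2, 0, 0, 0, 0, 0), tolerance = 1e-9)
  expect_error(fitQuadricBoundary(cbind(H, S, I)[1:5, ]), "at least 6")
  expect_error(fitQuadricBoundary(cbind(rep(0.3, 10), rep(0.5, 10),
                                        runif(10))), "rank")
})
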