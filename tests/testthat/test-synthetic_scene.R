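# Synthetic scene generator and its ground-truth oracles.

test_that("pot points lie exactly on the cone with the similar-triangle radii", {
  apex <- c(0, 0, -0.085)
  pot <- genPot(apex, 18.4349, c(0.03, 0.1), 2000, seed = 91)
  P <- cloudPoints(pot)
  r <- sqrt(P[, 1]^2 + P[, 2]^2)
  expect_lt(max(abs(r - tan(18.4349 * pi / 180) * (P[, 3] + 0.085))), 1e-9)
  # two slabs: radii scale like their apex distances
  s1 <- extractSlab(pot, 0.035, 0.002)
  s2 <- extractSlab(pot, 0.095, 0.002)
  r1 <- mean(sqrt(rowSums(cloudPoints(s1)[, 1:2]^2)))
  r2 <- mean(sqrt(rowSums(cloudPoints(s2)[, 1:2]^2)))
  expect_equal(r1 / r2, 0.12 / 0.18, tolerance = 0.02)
  expect_identical(nPoints(genPot(apex, 20, c(0, 0.1), 0)), 0L)
  expect_error(genPot(apex, 20, c(0.1, 0.1), 10), "degenerate")
})

test_that("soil disks respect roughness and radius contracts", {
  flat <- genSoil(0.14, 0.05, 0, 500, seed = 92)
  expect_true(all(cloudPoints(flat)[, 3] == 0.14))
  rough <- genSoil(0.14, 0.05, 0.002, 10000, seed = 93)
  expect_lt(abs(mean(cloudPoints(rough)[, 3]) - 0.14), 1e-4)
  axis <- genSoil(0.14, 0, 0, 10, seed = 94)
  expect_true(all(cloudPoints(axis)[, 1:2] == 0))
})

test_that("leaf areas follow the analytic values for flat and tilted patches", {
  flat <- leafPatch(0.05, 0.03, 0, 0, 0, c(0, 0, 0.2))
  expect_equal(leafArea(flat), pi * 0.05 * 0.03, tolerance = 1e-6)
  expect_equal(canopyProjectedArea(list(flat)), pi * 0.05 * 0.03,
               tolerance = 0.002)
  tilted <- leafPatch(0.05, 0.03, 0, 60, 25, c(0, 0, 0.2))
  expect_equal(leafArea(tilted), pi * 0.05 * 0.03, tolerance = 1e-6)
  expect_equal(canopyProjectedArea(list(tilted)),
               pi * 0.05 * 0.03 * cos(pi / 3), tolerance = 0.005)
})

test_that("canopy truth keeps projected area below total area with overlap", {
  can <- genCanopy(5, 0.04, seed = 95)
  expect_lt(can$truth@leafAreaProjected, can$truth@leafAreaTotal)
  expect_gt(can$truth@leafAreaProjected, 0)
  # the lowest sampled point matches the stem-base truth and the top the apex
  z <- cloudPoints(can$cloud)[, 3]
  expect_equal(min(z), can$truth@stemBaseZ, tolerance = 1e-12)
  expect_equal(max(z), can$truth@plantTopZ, tolerance = 1e-12)
})

test_that("scenes are bit-identical under the same seed", {
  a <- genScene("small", seed = 96)
  b <- genScene("small", seed = 96)
  expect_identical(cloudPoints(a$cloud), cloudPoints(b$cloud))
  expect_identical(cloudColors(a$cloud), cloudColors(b$cloud))
  expect_identical(a$truth@leafAreaTotal, b$truth@leafAreaTotal)
  c <- genScene("small", seed = 97)
  expect_false(identical(cloudPoints(a$cloud), cloudPoints(c$cloud)))
})

test_that("multiview duplication superposes exactly when artifact-free", {
  scene <- genCanopy(2, 0.03, seed = 98, sampleSpacing = 0.004)$cloud
  views <- genMultiview(scene, nViews = 18L, seed = 99)
  expect_length(views, 18L)
  angles <- vapply(views, function(v) v$markers@nominalAngle, numeric(1))
  expect_equal(angles, seq(0, 340, by = 20))
  for (k in c(1, 7, 18)) {
    undone <- applyTransform(rotationZ((k - 1) * 20), views[[k]]$cloud)
    expect_lt(max(abs(cloudPoints(undone) - cloudPoints(scene))), 1e-12)
  }
})

test_that("the layered artifact produces two parallel sheets at the offset", {
  # flat horizontal leaf: normals are vertical, so displaced points form a
  # parallel sheet exactly layer_offset away
  flat <- leafPatch(0.04, 0.024, 0, 0, 0, c(0, 0, 0.2))
  set.seed(100)
  pts <- leafPoints(flat, 0.001)
  cloud <- pointCloud(pts, matrix(c(0.1, 0.5, 0.1), nrow(pts), 3,
                                  byrow = TRUE))
  views <- genMultiview(cloud, nViews = 2L, layerOffset = 0.004,
                        seed = 101, layerMask = rep(TRUE, nrow(pts)))
  z <- cloudPoints(views[[1]]$cloud)[, 3]
  expect_true(all(abs(z - 0.2) < 1e-9 | abs(abs(z - 0.2) - 0.004) < 1e-9))
  expect_gt(sum(abs(abs(z - 0.2) - 0.004) < 1e-9), nrow(pts) * 0.4)
  # Gaussian noise perturbs every point
  vn <- genMultiview(cloud, nViews = 2L, noiseSd = 5e-4, seed = 102)
  expect_gt(sd(cloudPoints(vn[[1]]$cloud)[, 3] - 0.2), 3e-4)
  expect_warning(genMultiview(cloud, nViews = 7L, seed = 103), "360")
})

test_that("generated colors fall strictly inside their acceptance regions", {
  sc <- genScene("small", seed = 104, ambiguousFrac = 0)
  lab_can <- classifyHsi(rgbToHsi(cloudColors(sc$canopy)))
  expect_true(all(lab_can == "plant"))
  lab_pot <- classifyHsi(rgbToHsi(cloudColors(sc$pot)))
  lab_soil <- classifyHsi(rgbToHsi(cloudColors(sc$soil)))
  expect_true(all(c(lab_pot, lab_soil) == "nonplant"))
  amb <- genCanopy(2, 0.03, seed = 105, ambiguousFrac = 0.1)
  lab <- classifyHsi(rgbToHsi(cloudColors(amb$cloud)))
  expect_gt(mean(lab == "ambiguous"), 0.05)
  expect_lt(mean(lab == "ambiguous"), 0.15)
})

test_that("the thickened-canopy volume oracle matches the analytic slab volume", {
  # flat elliptical slab of thickness t: area * t plus the half-tube of
  # radius t/2 around the rim
  flat <- leafPatch(0.03, 0.018, 0, 0, 0, c(0, 0, 0.2))
  a <- 0.03; b <- 0.018; t <- 0.004
  perim <- pi * (3 * (a + b) / 2 - sqrt(a * b))  # Ramanujan approximation
  expected <- leafArea(flat) * t + perim * pi * (t / 2)^2 / 2
  v <- canopyVolumeTruth(list(flat), thickness = t, voxel = 0.001)
  expect_equal(v, expected, tolerance = 0.05)
})
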