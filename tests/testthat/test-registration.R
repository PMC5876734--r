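# Plane/circle fitting, turntable-frame transformation, marker-based
# registration and outlier filters.

test_that("robust plane fit rejects far outliers and recovers noisy planes", {
  set.seed(31)
  n <- 300
  base <- cbind(runif(n, 0, 0.3), runif(n, 0, 0.3), 0.01)
  spikes <- cbind(runif(5, 0, 0.3), runif(5, 0, 0.3), runif(5, 0.05, 0.2))
  fit <- fitPlane(pointCloud(rbind(base, spikes)), inlierTol = 0.003)
  expect_equal(fit$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fit$offset, 0.01, tolerance = 1e-9)
  expect_true(all(fit$inliers <= n))
  # Gaussian noise: offset recovered within 0.2 mm
  noisy <- base
  noisy[, 3] <- noisy[, 3] + rnorm(n, 0, 5e-4)
  fit2 <- fitPlane(pointCloud(noisy), inlierTol = 0.003)
  expect_lt(abs(fit2$offset - 0.01), 2e-4)
  # three points give their exact plane
  tri <- pointCloud(rbind(c(0, 0, 0.02), c(0.1, 0, 0.02), c(0, 0.1, 0.02)))
  fit3 <- fitPlane(tri, iterations = 10L)
  expect_equal(fit3$offset, 0.02, tolerance = 1e-12)
  # collinear input fails
  col <- pointCloud(cbind(seq(0, 1, length.out = 10), 0, 0))
  expect_error(fitPlane(col), "collinear")
})

test_that("circle fit is exact on circles and matches the circumcircle on 3 points", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(1 + 0.05 * cos(th), 2 + 0.05 * sin(th))
  fit <- fitCircle2d(pts)
  expect_equal(fit$center, c(1, 2), tolerance = 1e-9)
  expect_equal(fit$radius, 0.05, tolerance = 1e-9)
  # circumcircle oracle on 3 points: equidistance to all three
  p3 <- rbind(c(0, 0), c(0.1, 0.02), c(0.03, 0.09))
  f3 <- fitCircle2d(p3)
  d <- sqrt(rowSums((p3 - matrix(f3$center, 3, 2, byrow = TRUE))^2))
  expect_lt(diff(range(d)), 1e-12)
  expect_equal(d[1], f3$radius, tolerance = 1e-12)
  # noisy circle: radius within 0.5 mm
  set.seed(32)
  th <- runif(200, 0, 2 * pi)
  noisy <- cbind(0.05 * cos(th), 0.05 * sin(th)) +
    matrix(rnorm(400, 0, 1e-3), 200, 2)
  expect_lt(abs(fitCircle2d(noisy)$radius - 0.05), 5e-4)
  expect_error(fitCircle2d(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("turntable-frame transformation undoes a known table pose", {
  set.seed(33)
  scene <- pointCloud(matrix(rnorm(90, sd = 0.05), 30, 3))
  markers0 <- markerSet(2L, 18L, rbind(c(0.25, 0, 0), c(0, 0.25, 0),
                                       c(-0.25, 0, 0), c(0, -0.25, 0)))
  # camera pose: tilt + shift, after the view-k turntable rotation
  pose <- composeTransforms(
    rigidTransform(diag(3), c(0.05, -0.02, 0.6)),
    composeTransforms(rotationZ(25),
      rigidTransform(matrix(c(1, 0, 0,
                              0, cos(0.4), -sin(0.4),
                              0, sin(0.4), cos(0.4)), 3, 3, byrow = TRUE))))
  turned <- applyTransform(rotationZ(-40), scene)  # view 2 of 18
  view <- applyTransform(pose, turned)
  mk <- applyTransform(pose, applyTransform(rotationZ(-40), markers0))
  # table plane and center as seen in the view frame
  nrm <- pose@rotation %*% c(0, 0, 1)
  ctr <- pose@translation
  res <- toTurntableFrame(view, mk, list(normal = as.vector(nrm),
                                         offset = sum(nrm * ctr)), ctr,
                          viewDir = as.vector(pose@rotation %*% c(0, 1, 0)))
  expect_lt(max(abs(cloudPoints(res$cloud) - cloudPoints(scene))), 1e-9)
  # output table plane is z = 0
  expect_lt(max(abs(res$markers@markers[, 3])), 1e-9)
  expect_error(toTurntableFrame(view, markerSet(2L, 18L, mk@markers[1:2, ]),
                                list(normal = c(0, 0, 1), offset = 0),
                                c(0, 0, 0)), "3 markers")
})

test_that("marker-based global registration superposes noise-free views", {
  set.seed(34)
  scene <- genCanopy(2, 0.03, seed = 1, sampleSpacing = 0.003)$cloud
  views <- genMultiview(scene, nViews = 6L, seed = 2)
  reg_in <- lapply(views, function(v)
    toTurntableFrame(v$cloud, v$markers,
                     list(normal = c(0, 0, 1), offset = 0), c(0, 0, 0)))
  reg <- globalRegister(reg_in)
  expect_lt(max(reg$markerRMS), 1e-9)
  for (cl in reg$clouds)
    expect_lt(max(abs(cloudPoints(cl) - cloudPoints(scene))), 1e-9)
  # a 1-degree rotation error is recovered to well under 0.01 degrees
  pert <- reg_in
  pert[[3]]$cloud <- applyTransform(rotationZ(1), pert[[3]]$cloud)
  pert[[3]]$markers <- applyTransform(rotationZ(1), pert[[3]]$markers)
  reg2 <- globalRegister(pert)
  ang <- acos((sum(diag(reg2$transforms[[3]]@rotation)) - 1) / 2) * 180 / pi
  expect_lt(abs(ang - 1), 0.01)
  expect_lt(max(abs(cloudPoints(reg2$clouds[[3]]) - cloudPoints(scene))),
            1e-9)
  # single view is returned unchanged
  reg1 <- globalRegister(reg_in[1])
  expect_equal(cloudPoints(reg1$clouds[[1]]),
               cloudPoints(reg_in[[1]]$cloud), tolerance = 1e-12)
})

test_that("registration preserves point counts and colors", {
  scene <- genCanopy(2, 0.03, seed = 5, sampleSpacing = 0.003)$cloud
  views <- genMultiview(scene, nViews = 4L, seed = 6)
  reg_in <- lapply(views, function(v)
    toTurntableFrame(v$cloud, v$markers,
                     list(normal = c(0, 0, 1), offset = 0), c(0, 0, 0)))
  reg <- globalRegister(reg_in)
  for (k in seq_along(views)) {
    expect_identical(nPoints(reg$clouds[[k]]), nPoints(views[[k]]$cloud))
    expect_identical(cloudColors(reg$clouds[[k]]),
                     cloudColors(views[[k]]$cloud))
  }
})

test_that("outlier removal keeps exactly the well-connected points and is idempotent", {
  set.seed(35)
  dense <- matrix(rnorm(300, sd = 0.002), 100, 3)
  iso <- c(0.1, 0.1, 0.1)
  pc <- pointCloud(rbind(dense, iso))
  out <- removeOutliers(pc, radius = 0.005, minNeighbors = 4L)
  expect_identical(nPoints(out), 100L)
  # all-isolated cloud empties
  spread <- pointCloud(matrix(seq(0, 3, length.out = 30), 10, 3))
  expect_identical(nPoints(removeOutliers(spread, 0.005, 1L)), 0L)
  # equality with the brute-force neighbor-count filter on random clouds
  P <- matrix(runif(600, 0, 0.05), 200, 3)
  counts <- bruteNeighborCounts(P, 0.005)
  kept <- removeOutliers(pointCloud(P), 0.005, 3L)
  expect_equal(cloudPoints(kept), P[counts >= 3L, , drop = FALSE])
  # idempotence on a well-connected cloud: removing the stragglers does
  # not disturb the dense cluster
  again <- removeOutliers(out, 0.005, 4L)
  expect_identical(cloudPoints(again), cloudPoints(out))
})

test_that("pre-denoising removes spikes but keeps smooth surfaces and empty clouds", {
  # the local-centroid deviation is asymmetric at a patch rim, so the
  # smoothness check is made on the interior points
  g <- expand.grid(x = seq(0, 0.05, 0.002), y = seq(0, 0.05, 0.002))
  plane <- cbind(g$x, g$y, 0)
  interior <- plane[, 1] >= 0.006 & plane[, 1] <= 0.044 &
    plane[, 2] >= 0.006 & plane[, 2] <= 0.044
  pc <- pointCloud(plane)
  kept <- cloudPoints(preDenoise(pc, 0.005, 0.002))
  for (i in which(interior))
    expect_true(any(kept[, 1] == plane[i, 1] & kept[, 2] == plane[i, 2]))
  # 5 mm spikes over the interior are removed, the interior plane stays
  spikes <- cbind(c(0.02, 0.03), c(0.02, 0.03), 0.005)
  both <- pointCloud(rbind(plane, spikes))
  cleaned <- cloudPoints(preDenoise(both, 0.006, 0.002))
  expect_true(all(cleaned[, 3] == 0))
  empty <- pointCloud(matrix(numeric(0), 0, 3))
  expect_identical(nPoints(preDenoise(empty, 0.005, 0.002)), 0L)
})
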