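# Heights, areas, tetrahedral volume and calibration.

test_that("relative height is the maximum z with a warning below zero", {
  expect_equal(relativeHeight(pointCloud(rbind(c(0, 0, 0.3)))), 0.3)
  expect_error(relativeHeight(pointCloud(matrix(numeric(0), 0, 3))), "empty")
  expect_warning(hr <- relativeHeight(pointCloud(rbind(c(0, 0, -0.1)))),
                 "below")
  expect_equal(hr, -0.1)
})

test_that("soil-method height subtracts mean soil z and respects MinSoilPoints", {
  soil9 <- pointCloud(cbind(0, 0, seq(0.13, 0.15, length.out = 9)))
  expect_true(is.na(absoluteHeightSoil(0.3, soil9, 10L)))
  soil <- pointCloud(cbind(runif(50), runif(50), 0.14))
  expect_equal(absoluteHeightSoil(0.30, soil, 10L), 0.16)
  top <- pointCloud(cbind(0, 0, rep(0.3, 12)))
  expect_equal(absoluteHeightSoil(0.3, top, 10L), 0)
})

test_that("plant-bottom height subtracts the lowest in-pot point", {
  ip <- pointCloud(cbind(0, 0, c(0.12, 0.2, 0.3)))
  expect_equal(absoluteHeightBottom(0.30, ip), 0.18)
  expect_equal(absoluteHeightBottom(0.30, ip[3]), 0)
  expect_error(absoluteHeightBottom(0.3, ip[integer(0)]), "empty")
})

test_that("total leaf area sums the triangle areas", {
  tri <- triangleMesh(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0)),
                      rbind(c(1, 2, 3)))
  expect_equal(totalLeafArea(tri), 0.005)
  expect_equal(totalLeafArea(triangleMesh(matrix(0, 0, 3),
                                          matrix(integer(0), 0, 3))), 0)
  sq <- triangleMesh(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.1, 0.1, 0),
                           c(0, 0.1, 0)), rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(totalLeafArea(sq), 0.01)
})

test_that("projected area counts grid cell centers inside any projected triangle", {
  sq <- triangleMesh(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.1, 0.1, 0),
                           c(0, 0.1, 0)), rbind(c(1, 2, 3), c(1, 3, 4)))
  pa <- projectedLeafArea(sq, 0.001)
  expect_identical(pa$nInside, 10000)
  expect_equal(pa$area, 0.01)
  # two coincident copies: union semantics, no double counting
  dup <- triangleMesh(meshVertices(sq),
                      rbind(meshTriangles(sq), meshTriangles(sq)))
  expect_equal(projectedLeafArea(dup, 0.001)$area, 0.01)
  # a mesh in a vertical plane projects to nothing
  vert <- triangleMesh(rbind(c(0, 0, 0), c(0, 0.1, 0), c(0, 0.05, 0.1)),
                       rbind(c(1, 2, 3)))
  expect_equal(projectedLeafArea(vert, 0.001)$area, 0)
})

test_that("overlapped tetrahedra enumerate every close 4-subset", {
  # 5 points with only P4-P5 beyond the threshold: exactly the two
  # overlapped tetrahedra P1P2P3P4 and P1P2P3P5
  P <- rbind(c(0, 0, 0), c(0.005, 0, 0), c(0, 0.005, 0),
             c(0.002, 0.002, 0.004), c(0.002, 0.002, -0.004))
  tt <- buildTetrahedra(P, 0.008)
  expect_identical(nrow(tt), 2L)
  keys <- apply(tt, 1, function(r) paste(sort(r), collapse = ""))
  expect_setequal(keys, c("1234", "1235"))
  # 4 mutually close points: one tetrahedron
  expect_identical(nrow(buildTetrahedra(P[1:4, ], 0.008)), 1L)
  # one point beyond the threshold: none
  far <- rbind(P[1:3, ], c(0.02, 0.02, 0.02))
  expect_identical(nrow(buildTetrahedra(far, 0.008)), 0L)
  # near-degenerate (coplanar) 4-subsets are dropped
  flat <- rbind(c(0, 0, 0), c(0.004, 0, 0), c(0, 0.004, 0),
                c(0.004, 0.004, 0))
  expect_identical(nrow(buildTetrahedra(flat, 0.008)), 0L)
})

test_that("grid volume approximates the analytic tetrahedron volume", {
  V <- rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0), c(0, 0, 0.01))
  tv <- tetraVolume(V, matrix(1:4, 1), 0.0005)
  expect_lt(abs(tv$volume - 1e-6 / 6) / (1e-6 / 6), 0.05)
  # overlapping duplicates count once
  tv2 <- tetraVolume(V, rbind(1:4, 1:4), 0.0005)
  expect_equal(tv2$volume, tv$volume)
  expect_equal(tetraVolume(V, matrix(integer(0), 0, 4), 5e-4)$volume, 0)
})

test_that("the convergence study reports zero error at the reference spacing", {
  sq <- triangleMesh(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.1, 0.1, 0),
                           c(0, 0.1, 0)), rbind(c(1, 2, 3), c(1, 3, 4)))
  cs <- convergenceStudy(sq, c(0.002, 0.001, 1e-4), 1e-4)
  expect_equal(cs$relError[3], 0)
  expect_lt(cs$relError[2], 0.002)
  # rotated square: error shrinks as the grid refines
  R <- matrix(c(cos(0.5), -sin(0.5), 0, sin(0.5), cos(0.5), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  rot <- triangleMesh(meshVertices(sq) %*% t(R), meshTriangles(sq))
  cs2 <- convergenceStudy(rot, c(0.004, 0.0005), 1e-4)
  expect_lt(cs2$relError[2], cs2$relError[1])
})

test_that("calibration models apply forward and invert algebraically", {
  cal <- defaultCalibrations()
  expect_equal(applyCalibration(1.252, cal$projectedLeafArea, "inverse"), 0)
  expect_equal(applyCalibration(100, cal$projectedLeafArea), 80.052)
  # forward-then-inverse identity for linear and power kinds
  for (m in cal[c("relativeHeight", "volume")]) {
    y <- applyCalibration(12, m)
    expect_equal(applyCalibration(y, m, "inverse"), 12, tolerance = 1e-9)
  }
  ident <- calibrationModel("linear", c(slope = 1, intercept = 0))
  expect_equal(applyCalibration(3.7, ident), 3.7)
  expect_error(applyCalibration(-100, cal$volume, "inverse"), "undefined")
})

test_that("calibration fitting recovers known linear and power laws", {
  x <- seq(5, 400, length.out = 30)
  lin <- fitCalibration(x, 0.788 * x + 1.252, "linear")
  expect_equal(unname(lin@coefficients["slope"]), 0.788, tolerance = 1e-6)
  expect_equal(unname(lin@coefficients["intercept"]), 1.252,
               tolerance = 1e-6)
  set.seed(81)
  y <- 4.726 * x^0.5121 - 3.911 + rnorm(30, 0, 0.05)
  pw <- fitCalibration(x, y, "power")
  expect_lt(abs(pw@coefficients[["b"]] - 0.5121), 0.02)
  expect_error(fitCalibration(1:2, 1:2, "linear"), "3 pairs")
  expect_error(fitCalibration(1:3, 1:3, "power"), "4 pairs")
})

test_that("growth reports assemble all measures in cm units with calibration", {
  sq <- triangleMesh(rbind(c(0, 0, 0.2), c(0.1, 0, 0.2), c(0.1, 0.1, 0.21),
                           c(0, 0.1, 0.21)), rbind(c(1, 2, 3), c(1, 3, 4)))
  plant <- pointCloud(meshVertices(sq))
  soil <- pointCloud(cbind(runif(20, -0.02, 0.02), runif(20, -0.02, 0.02),
                           0.14))
  rep <- measureGrowth(plant, sq, soil, plant,
                       calibrations = defaultCalibrations())
  expect_equal(rep@hR, 21)
  expect_equal(rep@hAS, 21 - 14)
  expect_equal(rep@hAP, 1)
  expect_gt(rep@totalLeafArea, 99)
  expect_gt(rep@projectedLeafArea, 99)
  expect_true("projectedLeafArea.calibrated" %in% names(rep@calibrated))
  lst <- reportAsList(rep)
  expect_equal(lst$hR_cm, 21)
  # below MinSoilPoints the soil height is absent, not zero
  rep2 <- measureGrowth(plant, sq, soil[1:5], plant)
  expect_true(is.na(rep2@hAS))
})
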