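# Domain types, point-cloud I/O and spatial queries.

test_that("point cloud validity enforces matched lengths, finite coords and color range", {
  expect_error(pointCloud(matrix(1, 2, 3), matrix(0.5, 3, 3)), "equal length")
  expect_error(pointCloud(matrix(c(1, NA, 1), 1, 3)), "finite")
  expect_error(pointCloud(matrix(1, 1, 3), matrix(1.5, 1, 3)), "\\[0, 1\\]")
  pc <- pointCloud(matrix(rnorm(9), 3, 3))
  expect_identical(nPoints(pc), 3L)
  expect_true(all(cloudColors(pc) == 0))
})

test_that("triangle mesh validity rejects bad indices and repeated vertices", {
  v <- matrix(rnorm(9), 3, 3)
  expect_error(triangleMesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(triangleMesh(v, rbind(c(1, 2, 2))), "repeated")
  expect_silent(triangleMesh(v, rbind(c(1, 2, 3))))
})

test_that("rigid transforms require a proper rotation and compose/invert correctly", {
  expect_error(rigidTransform(diag(c(1, 1, -1))), "determinant")
  tf <- composeTransforms(rotationZ(40), rigidTransform(diag(3), c(0.1, 0, 0)))
  pts <- matrix(rnorm(30), 10, 3)
  back <- applyTransform(invertTransform(tf), applyTransform(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-12)
})

test_that("marker sets tie the nominal angle to the view index", {
  ms <- markerSet(3L, 18L, matrix(rnorm(12), 4, 3))
  expect_equal(ms@nominalAngle, 60)
  expect_error(markerSet(18L, 18L, matrix(0, 3, 3)), "viewIndex")
})

test_that("ASCII PLY round-trips cloud coordinates bit-exactly", {
  set.seed(11)
  n <- 500
  cols <- matrix(sample(0:255, 3 * n, replace = TRUE) / 255, n, 3)
  pc <- pointCloud(matrix(rnorm(3 * n, sd = 0.1), n, 3), cols)
  f <- tempfile(fileext = ".ply")
  writePointCloud(pc, f)
  back <- readPointCloud(f)
  expect_identical(cloudPoints(back), cloudPoints(pc))
  expect_equal(cloudColors(back), cloudColors(pc))
})

test_that("binary PLY round-trips within 1e-6 m", {
  set.seed(12)
  pc <- pointCloud(matrix(rnorm(300, sd = 0.1), 100, 3),
                   matrix(runif(300), 100, 3))
  f <- tempfile(fileext = ".ply")
  writePointCloud(pc, f, binary = TRUE)
  back <- readPointCloud(f)
  expect_lt(max(abs(cloudPoints(back) - cloudPoints(pc))), 1e-6)
  expect_lt(max(abs(cloudColors(back) - cloudColors(pc))), 1 / 255)
})

test_that("empty and malformed PLY files are handled as contracted", {
  f <- tempfile(fileext = ".ply")
  writePointCloud(pointCloud(matrix(numeric(0), 0, 3)), f)
  expect_identical(nPoints(readPointCloud(f)), 0L)
  writeLines(c("ply", "format ascii 1.0", "end_header"), f)
  expect_error(readPointCloud(f), "vertex")
  writeLines("not a ply", f)
  expect_error(readPointCloud(f), "ply")
})

test_that("PCD v0.7 ASCII files with packed rgb are read", {
  f <- tempfile(fileext = ".pcd")
  # one red point: 0x00FF0000 packed into a float
  packed <- readBin(writeBin(as.integer(0xFF0000), raw(), size = 4L,
                             endian = "little"),
                    "double", n = 1, size = 4L, endian = "little")
  writeLines(c("# .PCD v0.7 - Point Cloud Data file format",
               "VERSION 0.7", "FIELDS x y z rgb", "SIZE 4 4 4 4",
               "TYPE F F F F", "COUNT 1 1 1 1", "WIDTH 2", "HEIGHT 1",
               "VIEWPOINT 0 0 0 1 0 0 0", "POINTS 2", "DATA ascii",
               sprintf("0.1 0.2 0.3 %.10g", packed),
               sprintf("0.4 0.5 0.6 %.10g", packed)), f)
  pc <- readPointCloud(f)
  expect_equal(cloudPoints(pc)[1, ], c(0.1, 0.2, 0.3), tolerance = 1e-6)
  expect_equal(cloudColors(pc)[1, ], c(1, 0, 0))
})

test_that("mesh PLY/OBJ writing and PLY reading round-trip", {
  mesh <- stripMesh()
  f <- tempfile(fileext = ".ply")
  writeMesh(mesh, f)
  back <- readMesh(f)
  expect_equal(meshVertices(back), meshVertices(mesh), tolerance = 1e-8)
  expect_identical(meshTriangles(back), meshTriangles(mesh))
  fo <- tempfile(fileext = ".obj")
  writeMesh(mesh, fo)
  expect_true(any(grepl("^f ", readLines(fo))))
})

test_that("markers files round-trip through the plain-text format", {
  ms <- list(markerSet(0L, 18L, matrix(rnorm(12), 4, 3)),
             markerSet(1L, 18L, matrix(rnorm(12), 4, 3)))
  f <- tempfile(fileext = ".txt")
  writeMarkers(ms, f)
  back <- readMarkers(f, nViews = 18L)
  expect_equal(back[[2]]@markers, ms[[2]]@markers, tolerance = 1e-12)
  expect_equal(back[[2]]@nominalAngle, 20)
})

test_that("radius neighbor queries match the brute-force oracle", {
  # isolated point returns only itself
  pc <- pointCloud(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_identical(nearestNeighbors(pc, c(0, 0, 0), 0.1), 1L)
  # regular 1 mm grid: radius 1.2 mm catches the 4-neighborhood plus self
  # (1.5 mm would also include the diagonals at sqrt(2) mm)
  g <- expand.grid(x = seq(0, 0.01, 1e-3), y = seq(0, 0.01, 1e-3))
  grid <- pointCloud(cbind(g$x, g$y, 0))
  ctr <- c(0.005, 0.005, 0)
  nb <- nearestNeighbors(grid, ctr, 1.2e-3)
  expect_length(nb, 5L)
  expect_identical(nb, bruteNeighbors(cloudPoints(grid), ctr, 1.2e-3))
  nb2 <- nearestNeighbors(grid, ctr, 1.5e-3)
  expect_identical(nb2, bruteNeighbors(cloudPoints(grid), ctr, 1.5e-3))
  # random clouds up to 2000 points, exact agreement including order
  set.seed(21)
  for (n in c(50, 500, 2000)) {
    P <- matrix(runif(3 * n), n, 3)
    pc <- pointCloud(P)
    for (k in 1:5) {
      q <- runif(3)
      expect_identical(nearestNeighbors(pc, q, 0.1),
                       bruteNeighbors(P, q, 0.1))
    }
  }
})

test_that("pipeline configuration carries the canonical defaults and reads YAML", {
  cfg <- pipelineConfig()
  expect_identical(cfg@iterationTimes, 6L)
  expect_equal(cfg@mlsRadius, 0.01)
  expect_equal(cfg@pointSpacing, 0.002)
  expect_equal(cfg@triEdgeLength, 0.008)
  expect_equal(cfg@boundarySmoothR, 0.015)
  expect_identical(cfg@minSoilPoints, 10L)
  expect_equal(cfg@projAreaPrecision, 0.001)
  expect_equal(cfg@volumePrecision, 0.0005)
  expect_equal(cfg@tetraEdgeLength, 0.008)
  f <- tempfile(fileext = ".yaml")
  writeLines(c("IterationTimes: 3", "MlsRadius: 0.005"), f)
  cfg2 <- readPipelineConfig(f)
  expect_identical(cfg2@iterationTimes, 3L)
  expect_equal(cfg2@mlsRadius, 0.005)
  expect_equal(cfg2@pointSpacing, 0.002)
  f2 <- tempfile(fileext = ".yaml")
  writePipelineConfig(cfg2, f2)
  expect_equal(readPipelineConfig(f2)@mlsRadius, 0.005)
  expect_error(pipelineConfig(NoSuchKey = 1), "unknown configuration")
})
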