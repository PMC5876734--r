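# Down-sampling, triangulation, mesh filters and boundary smoothing.

test_that("down-sampling merges to centroids and enforces the minimum spacing", {
  two <- pointCloud(rbind(c(0, 0, 0), c(0.001, 0, 0)))
  out <- downsampleCloud(two, 0.002)
  expect_identical(nPoints(out), 1L)
  expect_equal(cloudPoints(out)[1, ], c(5e-4, 0, 0))
  # already-spaced points are unchanged
  spaced <- pointCloud(rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0)))
  expect_equal(cloudPoints(downsampleCloud(spaced, 0.002)),
               cloudPoints(spaced))
  # 1 mm grid at 2 mm spacing: no output pair closer than 2 mm (brute force)
  g <- expand.grid(x = seq(0, 0.02, 0.001), y = seq(0, 0.02, 0.001))
  ds <- downsampleCloud(pointCloud(cbind(g$x, g$y, 0)), 0.002)
  P <- cloudPoints(ds)
  dmin <- min(dist(P))
  expect_gte(dmin, 0.002)
  # colors are averaged with the merged points
  cols <- matrix(c(0, 1, 0, 1, 0, 1), 2, 3)
  out2 <- downsampleCloud(pointCloud(rbind(c(0, 0, 0), c(0.001, 0, 0)),
                                     cols), 0.002)
  expect_equal(cloudColors(out2)[1, ], colMeans(cols))
})

test_that("triangulation respects the edge bound and the empty-ball criterion", {
  tri3 <- pointCloud(rbind(c(0, 0, 0), c(0.005, 0, 0), c(0.0025, 0.0043, 0)))
  m <- triangulateCloud(tri3, 0.008)
  expect_identical(nTriangles(m), 1L)
  # same three points under a 4 mm bound: no triangle
  expect_identical(nTriangles(triangulateCloud(tri3, 0.004)), 0L)
  # fewer than 3 points: empty mesh, no error
  expect_identical(nTriangles(triangulateCloud(tri3[1:2], 0.008)), 0L)
  # dense plane samples reproduce the sampled extent's area within 2%
  set.seed(61)
  g <- expand.grid(x = seq(0, 0.1, by = 0.002), y = seq(0, 0.1, by = 0.002))
  jit <- matrix(runif(2 * nrow(g), -4e-4, 4e-4), nrow(g), 2)
  plane <- pointCloud(cbind(g$x + jit[, 1], g$y + jit[, 2], 0))
  mesh <- triangulateCloud(plane, 0.008)
  expect_lt(abs(totalLeafArea(mesh) / 0.01 - 1), 0.02)
})

test_that("triangle filters remove duplicates, suspended and perpendicular triangles", {
  # flat sheet with defects injected
  mesh <- stripMesh()
  v <- meshVertices(mesh)
  tr <- meshTriangles(mesh)
  nv <- nrow(v)
  # vertical fin on an interior edge + far-away isolated triangle + duplicate
  v2 <- rbind(v, c(0.022, 0, 0.004),                       # fin top
              c(0.3, 0.3, 0), c(0.304, 0.3, 0), c(0.3, 0.304, 0))
  fin <- c(6L, 7L, nv + 1L)
  iso <- c(nv + 2L, nv + 3L, nv + 4L)
  tr2 <- rbind(tr, tr[1, ], fin, iso)
  bad <- triangleMesh(v2, tr2)
  normals <- matrix(rep(c(0, 0, 1), each = nrow(v2)), nrow(v2), 3)
  filtered <- filterTriangles(bad, normals, perpAngleDeg = 70)
  ft <- meshTriangles(filtered)
  keys <- apply(ft, 1, function(r) paste(sort(r), collapse = "-"))
  expect_identical(anyDuplicated(keys), 0L)
  expect_false(paste(sort(iso), collapse = "-") %in% keys)
  expect_false(paste(sort(fin), collapse = "-") %in% keys)
  expect_identical(nrow(ft), nrow(tr))
  # after filtering no edge is shared by more than two triangles
  e <- rbind(ft[, 1:2], ft[, 2:3], ft[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_lte(max(table(ekey)), 2L)
})

test_that("small components are removed by total area", {
  sheet <- stripMesh()
  v <- meshVertices(sheet)
  nv <- nrow(v)
  # detached 2-triangle speck of ~3 mm^2
  v2 <- rbind(v, c(0.5, 0.5, 0), c(0.502, 0.5, 0), c(0.5, 0.503, 0),
              c(0.502, 0.503, 0))
  tr2 <- rbind(meshTriangles(sheet),
               c(nv + 1L, nv + 2L, nv + 3L), c(nv + 2L, nv + 4L, nv + 3L))
  both <- triangleMesh(v2, tr2)
  out <- removeSmallComponents(both, 1e-4)
  expect_identical(nTriangles(out), nTriangles(sheet))
  # minArea = 0 is the identity
  expect_identical(nTriangles(removeSmallComponents(both, 0)),
                   nTriangles(both))
  # a single large sheet passes unchanged
  expect_identical(nTriangles(removeSmallComponents(sheet, 1e-4)),
                   nTriangles(sheet))
})

test_that("three-edge holes are closed and larger holes left alone", {
  # tetrahedron missing one face
  v <- rbind(c(0, 0, 0), c(0.004, 0, 0), c(0.002, 0.004, 0),
             c(0.002, 0.002, 0.004))
  open3 <- triangleMesh(v, rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4)))
  closed <- fillTriHoles(open3)
  expect_identical(nTriangles(closed), 4L)
  # closing again changes nothing (watertight input)
  expect_identical(nTriangles(fillTriHoles(closed)), 4L)
  # a square pyramid without its base: the 4-edge hole stays open
  pyr <- triangleMesh(rbind(c(0, 0, 0), c(0.004, 0, 0), c(0.004, 0.004, 0),
                            c(0, 0.004, 0), c(0.002, 0.002, 0.004)),
                      rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5)))
  expect_identical(nTriangles(fillTriHoles(pyr)), 4L)
})

test_that("boundary smoothing straightens jagged edges but not straight ones", {
  straight <- stripMesh(nx = 26, dx = 0.004)
  out <- smoothBoundary(straight, 0.015)
  # central bottom-row vertices (away from the corners) are unmoved
  mid <- which(meshVertices(straight)[, 2] == 0 &
                 meshVertices(straight)[, 1] > 0.03 &
                 meshVertices(straight)[, 1] < 0.07)
  disp <- sqrt(rowSums((meshVertices(out)[mid, , drop = FALSE] -
                          meshVertices(straight)[mid, , drop = FALSE])^2))
  expect_lt(max(disp), 1e-6)
  # sawtooth boundary of 3 mm amplitude is flattened below 1 mm
  jag <- stripMesh(nx = 26, dx = 0.004, zigzag = 0.003)
  sm <- smoothBoundary(jag, 0.015)
  bottom <- 4:23   # away from the corners, which round off
  amp <- function(m) {
    y <- meshVertices(m)[bottom, 2]
    max(abs(y - mean(y)))
  }
  expect_gt(amp(jag), 0.0029)
  expect_lt(amp(sm), 0.001)
  # connectivity never changes
  expect_identical(meshTriangles(sm), meshTriangles(jag))
  # a closed (boundary-free) mesh is untouched
  v <- rbind(c(0, 0, 0), c(0.004, 0, 0), c(0.002, 0.004, 0),
             c(0.002, 0.002, 0.004))
  tet <- triangleMesh(v, rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4),
                               c(1, 3, 4)))
  expect_identical(meshVertices(smoothBoundary(tet, 0.015)),
                   meshVertices(tet))
})

test_that("the composed meshing pipeline reproduces a hemisphere's area within 3%", {
  set.seed(62)
  n <- 30000; r <- 0.06
  u <- runif(n); v <- runif(n)
  th <- 2 * pi * u; ph <- acos(v)
  hemi <- pointCloud(cbind(r * sin(ph) * cos(th), r * sin(ph) * sin(th),
                           r * cos(ph) + 0.2))
  mesh <- meshPipeline(hemi, pipelineConfig())
  expect_lt(abs(totalLeafArea(mesh) / (2 * pi * r^2) - 1), 0.03)
  # manifold after filtering: no edge belongs to more than two triangles
  ft <- meshTriangles(mesh)
  e <- rbind(ft[, 1:2], ft[, 2:3], ft[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_lte(max(table(ekey)), 2L)
})
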