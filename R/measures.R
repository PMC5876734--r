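# Growth parameter measurement: heights from the point clouds, total leaf
# area from the mesh, projected leaf area by 2D grid counting
# (S_PA = N_PA * spacing^2), and volume as the grid-sampled union of
# overlapped tetrahedra (V = N_V * spacing^3).  Grids are anchored at the
# bounding-box minimum plus half a spacing (cell centers), and the
# point-in-triangle / point-in-tetrahedron tests are boundary inclusive
# with tolerance 1e-12 so ties cannot depend on enumeration order.

#' Relative plant height (pot bottom to plant top)
#'
#' Maximum z of the denoised plant cloud; the pot bottom sits at z = 0 in
#' the turntable frame.
#'
#' @param plant the denoised plant [ColoredPointCloud-class], non-empty.
#' @return Height in meters.
#' @export
relativeHeight <- function(plant) {
  if (nPoints(plant) == 0L) stop("empty plant cloud")
  hR <- max(plant@points[, 3])
  if (hR < 0)
    warning("all plant points below z = 0; is the cloud in the turntable frame?")
  hR
}

#' Absolute height by the soil method
#'
#' `h_AS = h_R - mean(soil z)`.  When fewer than `minSoilPoints` soil
#' points are visible (soil hidden by leaves) the measurement is not
#' performed and `NA` is returned.
#'
#' @param hR relative height (m).
#' @param soil the soil [ColoredPointCloud-class].
#' @param minSoilPoints minimum allowed soil point count, default 10.
#' @return Height in meters, or `NA_real_`.
#' @export
absoluteHeightSoil <- function(hR, soil, minSoilPoints = 10L) {
  if (nPoints(soil) < minSoilPoints) return(NA_real_)
  hR - mean(soil@points[, 3])
}

#' Absolute height by the plant-bottom method
#'
#' `h_AP = h_R - min(in-pot plant z)`; the lowest in-pot plant point
#' stands in for the stem base (outside leaves may hang lower, which is
#' why the in-pot subset is used).
#'
#' @param hR relative height (m).
#' @param inPotPlant the in-pot plant [ColoredPointCloud-class], non-empty.
#' @return Height in meters.
#' @export
absoluteHeightBottom <- function(hR, inPotPlant) {
  if (nPoints(inPotPlant) == 0L) stop("empty in-pot plant cloud")
  hR - min(inPotPlant@points[, 3])
}

#' Total leaf area of a mesh
#'
#' Sum of all triangle areas (half cross-product norms).
#'
#' @param mesh a [TriangleMesh-class].
#' @return Area in m^2 (0 for an empty mesh).
#' @export
totalLeafArea <- function(mesh) {
  sum(.tri_areas(mesh@vertices, mesh@triangles))
}

#' Projected leaf area by grid counting
#'
#' The mesh is projected onto the x-y plane; a grid of points with spacing
#' `spacing` (offset spacing/2 from the bounding-box minimum, i.e. cell
#' centers) is tested against the projected triangles and
#' `S_PA = N_PA * spacing^2` where `N_PA` counts grid points inside at
#' least one triangle (edges inclusive; overlaps are not double counted).
#'
#' @param mesh a [TriangleMesh-class].
#' @param spacing grid spacing (m), default 0.001.
#' @return List with `area` (m^2) and `nInside` (N_PA).
#' @export
projectedLeafArea <- function(mesh, spacing = 0.001) {
  stopifnot(spacing > 0)
  tr <- mesh@triangles
  if (nrow(tr) == 0L) return(list(area = 0, nInside = 0L))
  v <- mesh@vertices
  tris <- cbind(v[tr[, 1], 1], v[tr[, 1], 2],
                v[tr[, 2], 1], v[tr[, 2], 2],
                v[tr[, 3], 1], v[tr[, 3], 2])
  res <- cpp_grid_area(tris, spacing)
  list(area = res$count * spacing^2, nInside = res$count)
}

#' Build overlapped tetrahedra
#'
#' Enumerates every 4-point subset of `vertices` whose six pairwise
#' distances are all below `tetraEdgeLength`.  Overlap is deliberate: it
#' involves every point and represents the leaf shape more fully than a
#' disjoint subdivision.  Near-degenerate tetrahedra (volume < `minVol`)
#' are dropped.
#'
#' @param vertices n x 3 matrix of points (typically mesh vertices).
#' @param tetraEdgeLength maximum edge (m), default 0.008.
#' @param minVol degeneracy threshold (m^3), default 1e-12.
#' @return m x 4 integer matrix of 1-based vertex indices.
#' @export
buildTetrahedra <- function(vertices, tetraEdgeLength = 0.008,
                            minVol = 1e-12) {
  stopifnot(tetraEdgeLength > 0)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) < 4L) return(matrix(integer(0), 0, 4))
  cpp_build_tetrahedra(vertices, tetraEdgeLength, minVol)
}

#' Volume of a tetrahedra union by 3D grid counting
#'
#' A 3D grid with spacing `spacing` (cell centers over the tetrahedra's
#' bounding box) is tested against all tetrahedra; `V = N_V * spacing^3`
#' where `N_V` counts grid points inside at least one tetrahedron
#' (boundary inclusive, union semantics so overlaps are not double
#' counted).
#'
#' @param vertices n x 3 matrix of points.
#' @param tetrahedra m x 4 integer matrix from [buildTetrahedra()].
#' @param spacing grid spacing (m), default 0.0005.
#' @return List with `volume` (m^3) and `nInside` (N_V).
#' @export
tetraVolume <- function(vertices, tetrahedra, spacing = 0.0005) {
  stopifnot(spacing > 0)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(tetrahedra) == 0L) return(list(volume = 0, nInside = 0L))
  res <- cpp_grid_volume(vertices, tetrahedra, spacing)
  list(volume = res$count * spacing^3, nInside = res$count)
}

#' Grid-precision convergence study
#'
#' Recomputes the projected area (for a mesh) or volume (for a tetrahedra
#' set) at each requested grid spacing and reports the relative error
#' against the value at a finer reference spacing.
#'
#' @param x a [TriangleMesh-class], or a list with `vertices` and
#'   `tetrahedra` for the volume study.
#' @param spacings numeric vector of grid spacings (m).
#' @param referenceSpacing reference spacing (m), no larger than any of
#'   `spacings`.
#' @return data.frame with columns `spacing`, `value`, `relError`.
#' @export
convergenceStudy <- function(x, spacings, referenceSpacing) {
  stopifnot(referenceSpacing <= min(spacings))
  eval1 <- if (is(x, "TriangleMesh")) {
    function(h) projectedLeafArea(x, h)$area
  } else {
    function(h) tetraVolume(x$vertices, x$tetrahedra, h)$volume
  }
  ref <- eval1(referenceSpacing)
  vals <- vapply(spacings, eval1, numeric(1))
  data.frame(spacing = spacings, value = vals,
             relError = abs(vals - ref) / ref)
}

#' Assemble a growth report
#'
#' Runs all growth measurements on the processed data and converts to the
#' customary reporting units (cm, cm^2, cm^3).  Calibration models, when
#' supplied, add calibrated estimates named `<measure>.calibrated`.
#'
#' @param plant denoised plant cloud (turntable frame).
#' @param mesh leaf-surface [TriangleMesh-class].
#' @param soil soil cloud from [segmentInPot()].
#' @param inPotPlant in-pot plant cloud from [segmentInPot()].
#' @param config a [PipelineConfig-class].
#' @param calibrations named list of [CalibrationModel-class], or `NULL`;
#'   recognized names: `relativeHeight`, `absoluteHeightSoil`,
#'   `absoluteHeightBottom`, `totalLeafArea`, `projectedLeafArea`,
#'   `volume`.
#' @return A [GrowthReport-class].
#' @export
measureGrowth <- function(plant, mesh, soil, inPotPlant,
                          config = pipelineConfig(), calibrations = NULL) {
  hR <- relativeHeight(plant)
  hAS <- absoluteHeightSoil(hR, soil, config@minSoilPoints)
  hAP <- absoluteHeightBottom(hR, inPotPlant)
  tla <- totalLeafArea(mesh)
  pla <- projectedLeafArea(mesh, config@projAreaPrecision)$area
  tets <- buildTetrahedra(mesh@vertices, config@tetraEdgeLength)
  vol <- tetraVolume(mesh@vertices, tets, config@volumePrecision)$volume
  meas <- c(relativeHeight = 100 * hR,
            absoluteHeightSoil = 100 * hAS,
            absoluteHeightBottom = 100 * hAP,
            totalLeafArea = 1e4 * tla,
            projectedLeafArea = 1e4 * pla,
            volume = 1e6 * vol)
  calibrated <- list()
  for (nm in names(calibrations)) {
    if (!nm %in% names(meas) || !is.finite(meas[[nm]])) next
    calibrated[[paste0(nm, ".calibrated")]] <-
      applyCalibration(meas[[nm]], calibrations[[nm]])
  }
  new("GrowthReport", hR = unname(meas["relativeHeight"]),
      hAS = unname(meas["absoluteHeightSoil"]),
      hAP = unname(meas["absoluteHeightBottom"]),
      totalLeafArea = unname(meas["totalLeafArea"]),
      projectedLeafArea = unname(meas["projectedLeafArea"]),
      volume = unname(meas["volume"]),
      soilPointsUsed = nPoints(soil), calibrated = calibrated)
}

#' Convert a growth report to a plain list
#' @param report a [GrowthReport-class].
#' @return Named list suitable for JSON serialization.
#' @export
reportAsList <- function(report) {
  list(hR_cm = report@hR,
       hAS_cm = if (is.finite(report@hAS)) report@hAS else NULL,
       hAP_cm = report@hAP,
       totalLeafArea_cm2 = report@totalLeafArea,
       projectedLeafArea_cm2 = report@projectedLeafArea,
       volume_cm3 = report@volume,
       soilPointsUsed = report@soilPointsUsed,
       calibrated = report@calibrated)
}
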