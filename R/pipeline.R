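# End-to-end orchestration: register -> segment -> denoise -> mesh ->
# pot segmentation -> measure, with intermediate artifacts optionally
# written to disk.

#' Run the full measurement pipeline
#'
#' Executes the whole chain on multi-view input (list of
#' `list(cloud=, markers=)`) or on an already merged turntable-frame
#' cloud: marker-based global registration and outlier removal, HSI
#' plant/non-plant segmentation, MIE + MLS denoising, meshing, pot cone
#' fitting with soil / in-pot segmentation, and growth measurement.
#'
#' @param views list of per-view `list(cloud=, markers=)` in the turntable
#'   frame, or `NULL` when `merged` is given.
#' @param merged a merged [ColoredPointCloud-class]; bypasses registration.
#' @param config a [PipelineConfig-class].
#' @param potCfg a [PotSegConfig-class].
#' @param calibrations optional named list of [CalibrationModel-class].
#' @param outDir optional directory; when given, every intermediate cloud
#'   and mesh plus the report JSON are written there.
#' @param verbose print per-stage point/triangle counts.
#' @return List with `report` ([GrowthReport-class]), `mesh`, `potModel`
#'   and the intermediate clouds.
#' @export
runPipeline <- function(views = NULL, merged = NULL,
                        config = pipelineConfig(), potCfg = potSegConfig(),
                        calibrations = NULL, outDir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(merged)) {
    if (is.null(views)) stop("either views or a merged cloud is required")
    reg <- globalRegister(views)
    merged <- mergeClouds(reg$clouds)
    say("registered %d views: %d points, marker RMS %.2g m",
        length(views), nPoints(merged), max(reg$markerRMS))
  }
  merged <- removeOutliers(merged, config@outlierRadius,
                           config@outlierMinNeighbors)
  say("after outlier removal: %d points", nPoints(merged))
  seg <- segmentCloud(merged, smoothRadius = config@smoothColorRadius)
  say("segmented: %d plant, %d non-plant, %d ambiguous",
      nPoints(seg$plant), nPoints(seg$nonplant), nPoints(seg$ambiguous))
  if (nPoints(seg$plant) == 0L)
    stop("no plant detected: the plant point set is empty after segmentation")
  plant <- mieDenoise(seg$plant, config@iterationTimes, config@mieSearchDist,
                      config@mieOppositionCos, config@mieStep)
  plant <- mlsSmooth(plant, config@mlsRadius, config@mlsPolyOrder)
  say("denoised plant cloud: %d points", nPoints(plant))
  mesh <- meshPipeline(plant, config)
  say("mesh: %d vertices, %d triangles", nrow(mesh@vertices),
      nTriangles(mesh))
  potModel <- fitPotCone(seg$nonplant, potCfg)
  inpot <- segmentInPot(seg$nonplant, plant, potModel, potCfg)
  say("pot model: apex z %.4f m; %d soil points, %d in-pot plant points",
      potModel@apex[3], nPoints(inpot$soil), nPoints(inpot$inPotPlant))
  report <- measureGrowth(plant, mesh, inpot$soil, inpot$inPotPlant,
                          config, calibrations)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePointCloud(merged, file.path(outDir, "merged.ply"))
    writePointCloud(seg$plant, file.path(outDir, "plant.ply"))
    writePointCloud(seg$nonplant, file.path(outDir, "nonplant.ply"))
    writePointCloud(seg$ambiguous, file.path(outDir, "ambiguous.ply"))
    writePointCloud(plant, file.path(outDir, "plant_denoised.ply"))
    writePointCloud(inpot$soil, file.path(outDir, "soil.ply"))
    writePointCloud(inpot$inPotPlant, file.path(outDir, "inpot.ply"))
    writeMesh(mesh, file.path(outDir, "plant_mesh.ply"))
    jsonlite::write_json(reportAsList(report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(report = report, mesh = mesh, potModel = potModel, merged = merged,
       plant = plant, nonplant = seg$nonplant, soil = inpot$soil,
       inPotPlant = inpot$inPotPlant)
}

#' Grid-precision study on three synthetic plants
#'
#' Recreates the precision experiment behind the default grid spacings:
#' three synthetic plants of different sizes are meshed at the canonical
#' settings, then the projected leaf area is evaluated at
#' `projSpacings` and the tetrahedra-union volume at `volSpacings`, each
#' against its `reference` spacing.  Returns the per-plant relative errors
#' in percent.
#'
#' @param seeds length-3 integer seeds for the small/medium/large plants.
#' @param projSpacings projected-area grid spacings to test (m).
#' @param volSpacings volume grid spacings to test (m).
#' @param reference reference spacing (m), default 1e-4.
#' @param tetraEdgeLength maximum tetrahedron edge (m), default 0.008.
#' @param verbose print progress.
#' @return data.frame with columns `plant`, `measure`, `spacing`, `value`,
#'   `relErrorPct` and `size` (triangle or tetrahedron count).
#' @export
gridPrecisionStudy <- function(seeds = c(101L, 102L, 103L),
                               projSpacings = 0.001,
                               volSpacings = 0.0005,
                               reference = 1e-4,
                               tetraEdgeLength = 0.008,
                               verbose = FALSE) {
  sizes <- c("small", "medium", "large")
  out <- list()
  for (i in seq_along(sizes)) {
    sp <- syntheticPlantMesh(sizes[i], seed = seeds[i])
    mesh <- sp$mesh
    if (verbose)
      message(sprintf("%s plant: %d vertices, %d triangles",
                      sizes[i], nrow(mesh@vertices), nTriangles(mesh)))
    cs <- convergenceStudy(mesh, projSpacings, reference)
    out[[length(out) + 1L]] <- data.frame(
      plant = sizes[i], measure = "projectedArea", spacing = cs$spacing,
      value = cs$value, relErrorPct = 100 * cs$relError,
      size = nTriangles(mesh))
    tets <- buildTetrahedra(mesh@vertices, tetraEdgeLength)
    if (verbose)
      message(sprintf("%s plant: %d tetrahedra", sizes[i], nrow(tets)))
    cs <- convergenceStudy(list(vertices = mesh@vertices, tetrahedra = tets),
                           volSpacings, reference)
    out[[length(out) + 1L]] <- data.frame(
      plant = sizes[i], measure = "volume", spacing = cs$spacing,
      value = cs$value, relErrorPct = 100 * cs$relError, size = nrow(tets))
  }
  do.call(rbind, out)
}
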