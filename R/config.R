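# Pipeline configuration: the key tunable parameters of every stage.
# The canonical defaults are the reference operating point for Kinect-scale
# lettuce scans; the config file uses the same names, so a parameter table
# written as flat YAML key/value pairs is a valid config.

#' Pipeline configuration
#'
#' All lengths in meters.  Canonical parameters (with their reference
#' defaults): `IterationTimes` (6) maximum iterations of MIE;
#' `MlsRadius` (0.01) MLS smoothing radius; `PointSpacing` (0.002) minimum
#' down-sampling spacing; `TriEdgeLength` (0.008) maximum triangle edge;
#' `BoundarySmoothR` (0.015) boundary smoothing radius; `MinSoilPoints` (10)
#' minimum soil points for the soil-method height; `ProjAreaPrecision`
#' (0.001) projected-area grid spacing; `VolumePrecision` (0.0005) volume
#' grid spacing; `TetraEdgeLength` (0.008) maximum tetrahedron edge.
#' Additional stage tunables (defaults chosen by this package): outlier
#' removal radius/min-neighbor count, pre-denoise radius and local-deviation
#' bound, color-smoothing radius, normal-estimation radius, MIE search
#' distance / opposition cosine / contraction step, mesh-filter
#' perpendicular-angle and minimum component area, and the RANSAC settings
#' of the plane fit.
#'
#' @slot iterationTimes integer.
#' @slot mlsRadius,pointSpacing,triEdgeLength,boundarySmoothR numeric (m).
#' @slot minSoilPoints integer.
#' @slot projAreaPrecision,volumePrecision,tetraEdgeLength numeric (m).
#' @slot outlierRadius numeric (m); @slot outlierMinNeighbors integer.
#' @slot preDenoiseRadius,preDenoiseMaxDev numeric (m).
#' @slot smoothColorRadius,normalRadius numeric (m).
#' @slot mieSearchDist,mieOppositionCos,mieStep numeric.
#' @slot mlsPolyOrder integer.
#' @slot perpAngleDeg numeric (degrees); @slot minComponentArea numeric (m^2).
#' @slot planeInlierTol numeric (m); @slot ransacIterations integer.
#' @export
setClass("PipelineConfig",
  representation(
    iterationTimes = "integer", mlsRadius = "numeric",
    pointSpacing = "numeric", triEdgeLength = "numeric",
    boundarySmoothR = "numeric", minSoilPoints = "integer",
    projAreaPrecision = "numeric", volumePrecision = "numeric",
    tetraEdgeLength = "numeric",
    outlierRadius = "numeric", outlierMinNeighbors = "integer",
    preDenoiseRadius = "numeric", preDenoiseMaxDev = "numeric",
    smoothColorRadius = "numeric", normalRadius = "numeric",
    mieSearchDist = "numeric", mieOppositionCos = "numeric",
    mieStep = "numeric", mlsPolyOrder = "integer",
    perpAngleDeg = "numeric", minComponentArea = "numeric",
    planeInlierTol = "numeric", ransacIterations = "integer"),
  prototype(
    iterationTimes = 6L, mlsRadius = 0.01, pointSpacing = 0.002,
    triEdgeLength = 0.008, boundarySmoothR = 0.015, minSoilPoints = 10L,
    projAreaPrecision = 0.001, volumePrecision = 0.0005,
    tetraEdgeLength = 0.008,
    outlierRadius = 0.005, outlierMinNeighbors = 4L,
    preDenoiseRadius = 0.005, preDenoiseMaxDev = 0.002,
    smoothColorRadius = 0.005, normalRadius = 0.006,
    mieSearchDist = 0.006, mieOppositionCos = 0.5, mieStep = 0.5,
    mlsPolyOrder = 2L, perpAngleDeg = 70, minComponentArea = 1e-4,
    planeInlierTol = 0.003, ransacIterations = 200L))

setValidity("PipelineConfig", function(object) {
  lens <- c("mlsRadius", "pointSpacing", "triEdgeLength", "boundarySmoothR",
            "projAreaPrecision", "volumePrecision", "tetraEdgeLength",
            "outlierRadius", "preDenoiseRadius", "smoothColorRadius",
            "normalRadius", "mieSearchDist")
  for (nm in lens)
    if (slot(object, nm) <= 0) return(paste(nm, "must be > 0"))
  if (object@iterationTimes < 0L) return("iterationTimes must be >= 0")
  TRUE
})

# map between config-file keys and slot names
.cfg_key_map <- c(
  IterationTimes = "iterationTimes", MlsRadius = "mlsRadius",
  PointSpacing = "pointSpacing", TriEdgeLength = "triEdgeLength",
  BoundarySmoothR = "boundarySmoothR", MinSoilPoints = "minSoilPoints",
  ProjAreaPrecision = "projAreaPrecision",
  VolumePrecision = "volumePrecision", TetraEdgeLength = "tetraEdgeLength",
  OutlierRadius = "outlierRadius", OutlierMinNeighbors = "outlierMinNeighbors",
  PreDenoiseRadius = "preDenoiseRadius", PreDenoiseMaxDev = "preDenoiseMaxDev",
  SmoothColorRadius = "smoothColorRadius", NormalRadius = "normalRadius",
  MieSearchDist = "mieSearchDist", MieOppositionCos = "mieOppositionCos",
  MieStep = "mieStep", MlsPolyOrder = "mlsPolyOrder",
  PerpAngleDeg = "perpAngleDeg", MinComponentArea = "minComponentArea",
  PlaneInlierTol = "planeInlierTol", RansacIterations = "ransacIterations")

#' Construct a pipeline configuration
#'
#' @param ... named overrides, either by slot name (`pointSpacing = 0.001`)
#'   or by config-file key (`PointSpacing = 0.001`).
#' @return A [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg@triEdgeLength        # 0.008
#' @export
pipelineConfig <- function(...) {
  cfg <- new("PipelineConfig")
  ov <- list(...)
  for (nm in names(ov)) {
    slotnm <- if (nm %in% names(.cfg_key_map)) .cfg_key_map[[nm]] else nm
    if (!slotnm %in% slotNames("PipelineConfig"))
      stop("unknown configuration parameter: ", nm)
    val <- ov[[nm]]
    slot(cfg, slotnm) <- if (getSlots("PipelineConfig")[[slotnm]] == "integer")
      as.integer(val) else as.numeric(val)
  }
  validObject(cfg)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file is flat key/value YAML using the canonical parameter names
#' (`IterationTimes: 6`, `MlsRadius: 0.01`, ...); unknown keys are an error.
#'
#' @param path file path.
#' @return A [PipelineConfig-class] object.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

#' Write a pipeline configuration to a YAML file
#' @param config a [PipelineConfig-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  vals <- lapply(stats::setNames(names(.cfg_key_map), names(.cfg_key_map)),
                 function(k) slot(config, .cfg_key_map[[k]]))
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @importFrom methods slotNames getSlots
NULL
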