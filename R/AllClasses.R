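# Central S4 data types shared by every pipeline stage.
# All coordinates are in meters, in a right-handed frame with z up; the
# turntable frame puts the turntable surface at z = 0 with the origin at the
# table center, so the pot bottom sits at z = 0.

#' Colored point cloud
#'
#' The pipeline's universal currency: an n x 3 matrix of positions in meters
#' plus per-point RGB colors in \[0, 1\].  `frame` records whether the cloud
#' still lives in a view-local frame or has been brought into the common
#' turntable frame (origin at the table center, z up).
#'
#' @slot points numeric matrix (n x 3), finite coordinates in meters.
#' @slot colors numeric matrix (n x 3), RGB in \[0, 1\].
#' @slot frame character, `"view-local"` or `"turntable"`.
#' @export
setClass("ColoredPointCloud",
  representation(points = "matrix", colors = "matrix", frame = "character"),
  prototype(points = matrix(numeric(0), 0, 3),
            colors = matrix(numeric(0), 0, 3),
            frame = "turntable"))

setValidity("ColoredPointCloud", function(object) {
  p <- object@points; cl <- object@colors
  if (ncol(p) != 3L) return("points must have 3 columns")
  if (ncol(cl) != 3L) return("colors must have 3 columns")
  if (nrow(p) != nrow(cl)) return("points and colors must have equal length")
  if (nrow(p) && !all(is.finite(p))) return("all coordinates must be finite")
  if (nrow(cl) && (min(cl) < 0 || max(cl) > 1))
    return("colors must lie in [0, 1]")
  if (!object@frame %in% c("view-local", "turntable"))
    return("frame must be 'view-local' or 'turntable'")
  TRUE
})

#' Construct a colored point cloud
#'
#' @param points n x 3 numeric matrix of positions (m).
#' @param colors n x 3 numeric matrix of RGB in \[0, 1\]; defaults to black.
#' @param frame `"turntable"` (default) or `"view-local"`.
#' @return A [ColoredPointCloud-class] object.
#' @examples
#' pc <- pointCloud(matrix(rnorm(30), 10, 3))
#' nPoints(pc)
#' @export
pointCloud <- function(points, colors = NULL, frame = "turntable") {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0, 3)
  storage.mode(points) <- "double"
  if (is.null(colors)) colors <- matrix(0, nrow(points), 3)
  colors <- as.matrix(colors)
  storage.mode(colors) <- "double"
  dimnames(points) <- NULL
  dimnames(colors) <- NULL
  new("ColoredPointCloud", points = points, colors = colors, frame = frame)
}

#' Triangular surface mesh
#'
#' Vertices (m) plus triangles as 1-based vertex index triples.  The mesh
#' represents the visible leaf surfaces and is the source of all area
#' measures and of the tetrahedralization vertices.
#'
#' @slot vertices numeric matrix (n x 3).
#' @slot triangles integer matrix (m x 3) of vertex indices.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", triangles = "matrix"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            triangles = matrix(integer(0), 0, 3)))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; tr <- object@triangles
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(tr) != 3L) return("triangles must have 3 columns")
  if (nrow(tr)) {
    if (min(tr) < 1L || max(tr) > nrow(v))
      return("triangle indices out of range")
    if (any(tr[, 1] == tr[, 2] | tr[, 1] == tr[, 3] | tr[, 2] == tr[, 3]))
      return("triangle with a repeated vertex")
  }
  TRUE
})

#' Construct a triangle mesh
#' @param vertices n x 3 numeric matrix (m).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return A [TriangleMesh-class] object.
#' @export
triangleMesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  if (length(triangles) == 0L) triangles <- matrix(integer(0), 0, 3)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  new("TriangleMesh", vertices = vertices, triangles = triangles)
}

#' Rigid transform (rotation + translation)
#'
#' @slot rotation 3 x 3 orthonormal matrix with det +1.
#' @slot translation length-3 numeric (m).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (abs(det(R) - 1) > 1e-9) return("rotation determinant must be +1")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal")
  TRUE
})

#' Construct a rigid transform
#' @param rotation 3 x 3 rotation matrix (det +1).
#' @param translation length-3 numeric (m).
#' @return A [RigidTransform-class] object.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.matrix(rotation),
      translation = as.numeric(translation))
}

#' Per-view marker set
#'
#' Marker 3D coordinates for one turntable view, together with the view
#' index and its nominal turning angle (view_index * 360 / n_views degrees).
#'
#' @slot viewIndex integer, 0-based view number.
#' @slot nViews integer, number of views in the scan.
#' @slot nominalAngle numeric, degrees.
#' @slot markers numeric matrix (k x 3) of marker coordinates (m).
#' @export
setClass("MarkerSet",
  representation(viewIndex = "integer", nViews = "integer",
                 nominalAngle = "numeric", markers = "matrix"))

setValidity("MarkerSet", function(object) {
  if (object@viewIndex < 0L || object@viewIndex >= object@nViews)
    return("viewIndex must satisfy 0 <= viewIndex < nViews")
  expect <- object@viewIndex * 360 / object@nViews
  if (abs(object@nominalAngle - expect) > 1e-6)
    return("nominalAngle must equal viewIndex * 360 / nViews")
  if (ncol(object@markers) != 3L) return("markers must have 3 columns")
  TRUE
})

#' Construct a marker set
#' @param viewIndex 0-based view number.
#' @param nViews number of views in the scan (18 in the reference setup).
#' @param markers k x 3 matrix of marker coordinates (m).
#' @return A [MarkerSet-class] object.
#' @export
markerSet <- function(viewIndex, nViews, markers) {
  markers <- as.matrix(markers)
  storage.mode(markers) <- "double"
  dimnames(markers) <- NULL
  new("MarkerSet", viewIndex = as.integer(viewIndex),
      nViews = as.integer(nViews),
      nominalAngle = viewIndex * 360 / nViews, markers = markers)
}

#' HSI quadric segmentation model
#'
#' Plant / non-plant decision surfaces in Hue-Saturation-Intensity space.
#' A point is *plant* when S > 0.1, I > 0.05 and I >= f(H, S); *non-plant*
#' when S <= 0.1 or I <= g(H, S); *ambiguous* otherwise.  f and g are
#' quadrics c0 + c1 H + c2 S + c3 H^2 + c4 H S + c5 S^2 whose default
#' coefficients were fitted to manually segmented lettuce training clouds.
#'
#' @slot plantCoeffs numeric(6), coefficients of f (order: const, H, S, H^2,
#'   H*S, S^2).
#' @slot nonplantCoeffs numeric(6), coefficients of g.
#' @slot sMinPlant,iMinPlant,sMaxNonplant scalar thresholds.
#' @export
setClass("QuadricSegModel",
  representation(plantCoeffs = "numeric", nonplantCoeffs = "numeric",
                 sMinPlant = "numeric", iMinPlant = "numeric",
                 sMaxNonplant = "numeric"),
  prototype(
    plantCoeffs = c(1.114, -4.9, -0.229, 6.066, -0.1638, 0.1852),
    nonplantCoeffs = c(0.6475, -2.777, -0.2797, 3.714, 0.1326, 0.1133),
    sMinPlant = 0.1, iMinPlant = 0.05, sMaxNonplant = 0.1))

setValidity("QuadricSegModel", function(object) {
  if (length(object@plantCoeffs) != 6L) return("plantCoeffs must be length 6")
  if (length(object@nonplantCoeffs) != 6L)
    return("nonplantCoeffs must be length 6")
  TRUE
})

#' Default HSI segmentation model
#' @param plantCoeffs,nonplantCoeffs optional coefficient overrides.
#' @return A [QuadricSegModel-class] with the published lettuce coefficients.
#' @examples
#' m <- quadricSegModel()
#' evalQuadric(m@plantCoeffs, 0, 0)   # 1.114
#' @export
quadricSegModel <- function(plantCoeffs = NULL, nonplantCoeffs = NULL) {
  m <- new("QuadricSegModel")
  if (!is.null(plantCoeffs)) m@plantCoeffs <- as.numeric(plantCoeffs)
  if (!is.null(nonplantCoeffs)) m@nonplantCoeffs <- as.numeric(nonplantCoeffs)
  validObject(m)
  m
}

#' Truncated-cone pot model
#'
#' Cone through two fitted horizontal section circles (O1, r1) and (O2, r2);
#' the apex F is where the linearly extrapolated radius vanishes.  For
#' segmentation the cone is shrunk by `eta` and points are conically
#' projected from F onto the datum plane at z = z_F + 1, where the adjusted
#' section circle has center Om and radius ra = eta * |r1 / (z_O1 - z_F)|.
#'
#' @slot O1,O2 numeric(3), section circle centers (m).
#' @slot r1,r2 numeric, section radii (m).
#' @slot apex numeric(3), cone apex F (m).
#' @slot eta numeric, shrink coefficient.
#' @slot ra numeric, adjusted-cone radius on the datum plane (m).
#' @slot Om numeric(3), datum-plane center.
#' @export
setClass("PotConeModel",
  representation(O1 = "numeric", O2 = "numeric", r1 = "numeric",
                 r2 = "numeric", apex = "numeric", eta = "numeric",
                 ra = "numeric", Om = "numeric"))

setValidity("PotConeModel", function(object) {
  if (isTRUE(all.equal(object@r1, object@r2))) return("r1 must differ from r2")
  TRUE
})

#' Pot segmentation configuration
#'
#' z-intervals and shrink coefficient for pot-shape-based segmentation.
#' Defaults are the reference values for the truncated-cone pots used with
#' the lettuce scans: section slabs at z1 = 0.035 and z2 = 0.095 (half-width
#' dz = 0.005), shrink eta = 0.9, soil z in \[0.11, 0.168\] and in-pot plant
#' z in \[0.12, 1\] (all meters).
#'
#' @slot z1,z2,dz numeric, section slab centers and half-width (m).
#' @slot eta numeric, cone shrink coefficient.
#' @slot soilZ numeric(2), soil z-interval (m).
#' @slot plantZ numeric(2), in-pot-plant z-interval (m).
#' @export
setClass("PotSegConfig",
  representation(z1 = "numeric", z2 = "numeric", dz = "numeric",
                 eta = "numeric", soilZ = "numeric", plantZ = "numeric"),
  prototype(z1 = 0.035, z2 = 0.095, dz = 0.005, eta = 0.9,
            soilZ = c(0.11, 0.168), plantZ = c(0.12, 1)))

#' Construct a pot segmentation configuration
#' @param ... named overrides of the slots of [PotSegConfig-class].
#' @return A [PotSegConfig-class] object.
#' @export
potSegConfig <- function(...) {
  cfg <- new("PotSegConfig")
  ov <- list(...)
  for (nm in names(ov)) slot(cfg, nm) <- ov[[nm]]
  validObject(cfg)
  cfg
}

#' Calibration model mapping sensor measurements to reference scale
#'
#' Linear (`y = slope * x + intercept`) or power (`y = a * x^b + c`) maps
#' fitted between sensor and reference measurements.  The default models
#' shipped by [defaultCalibrations()] were fitted to the reference lettuce
#' data set and are only appropriate for comparable plants and setups.
#'
#' @slot kind `"linear"` or `"power"`.
#' @slot coefficients named numeric: `slope`/`intercept` or `a`/`b`/`c`.
#' @export
setClass("CalibrationModel",
  representation(kind = "character", coefficients = "numeric"))

setValidity("CalibrationModel", function(object) {
  if (!object@kind %in% c("linear", "power"))
    return("kind must be 'linear' or 'power'")
  need <- if (object@kind == "linear") c("slope", "intercept") else
    c("a", "b", "c")
  if (!all(need %in% names(object@coefficients)))
    return(paste("coefficients must be named", paste(need, collapse = ", ")))
  TRUE
})

#' Construct a calibration model
#' @param kind `"linear"` or `"power"`.
#' @param coefficients named numeric vector (`slope`, `intercept` for linear;
#'   `a`, `b`, `c` for power).
#' @return A [CalibrationModel-class] object.
#' @export
calibrationModel <- function(kind, coefficients) {
  new("CalibrationModel", kind = kind, coefficients = coefficients)
}

#' Analytic ground truth of a synthetic scene
#'
#' Quantities a perfect measurement would recover, computed by oracles
#' (quadrature, rasterization, dense grids) that are independent of the
#' measurement code.
#'
#' @slot potApex numeric(3) or length 0 when the scene has no pot.
#' @slot potHalfAngle numeric, degrees.
#' @slot soilHeight numeric (m).
#' @slot plantTopZ numeric (m).
#' @slot stemBaseZ numeric (m).
#' @slot leafAreaTotal numeric (m^2).
#' @slot leafAreaProjected numeric (m^2).
#' @slot canopyVolume numeric (m^3).
#' @slot viewTransforms list of [RigidTransform-class].
#' @export
setClass("SceneTruth",
  representation(potApex = "numeric", potHalfAngle = "numeric",
                 soilHeight = "numeric", plantTopZ = "numeric",
                 stemBaseZ = "numeric", leafAreaTotal = "numeric",
                 leafAreaProjected = "numeric", canopyVolume = "numeric",
                 viewTransforms = "list"),
  prototype(potApex = numeric(0), potHalfAngle = NA_real_,
            soilHeight = NA_real_, plantTopZ = NA_real_,
            stemBaseZ = NA_real_, leafAreaTotal = NA_real_,
            leafAreaProjected = NA_real_, canopyVolume = NA_real_,
            viewTransforms = list()))

setValidity("SceneTruth", function(object) {
  if (is.finite(object@leafAreaProjected) && is.finite(object@leafAreaTotal) &&
      object@leafAreaProjected > object@leafAreaTotal + 1e-12)
    return("projected leaf area cannot exceed total leaf area")
  TRUE
})

#' Growth measurement report
#'
#' All reported quantities are in the field's customary units: heights in
#' cm, areas in cm^2, volume in cm^3.  `hAS` is `NA` when fewer than
#' `minSoilPoints` soil points were visible (the soil-method height is then
#' not computed rather than reported as zero).
#'
#' @slot hR numeric, relative height (cm), pot bottom to plant top.
#' @slot hAS numeric, absolute height by the soil method (cm) or `NA`.
#' @slot hAP numeric, absolute height by the plant-bottom method (cm).
#' @slot totalLeafArea numeric (cm^2).
#' @slot projectedLeafArea numeric (cm^2).
#' @slot volume numeric (cm^3).
#' @slot soilPointsUsed integer.
#' @slot calibrated named list of calibrated estimates.
#' @export
setClass("GrowthReport",
  representation(hR = "numeric", hAS = "numeric", hAP = "numeric",
                 totalLeafArea = "numeric", projectedLeafArea = "numeric",
                 volume = "numeric", soilPointsUsed = "integer",
                 calibrated = "list"),
  prototype(hR = NA_real_, hAS = NA_real_, hAP = NA_real_,
            totalLeafArea = NA_real_, projectedLeafArea = NA_real_,
            volume = NA_real_, soilPointsUsed = 0L, calibrated = list()))

setValidity("GrowthReport", function(object) {
  for (nm in c("hR", "hAP", "totalLeafArea", "projectedLeafArea", "volume"))
    if (is.finite(slot(object, nm)) && slot(object, nm) < -1e-9)
      return(paste(nm, "must be non-negative"))
  if (is.finite(object@hAS) && is.finite(object@hR) &&
      object@hAS > object@hR + 1e-9)
    return("hAS cannot exceed hR")
  if (is.finite(object@hAP) && is.finite(object@hR) &&
      object@hAP > object@hR + 1e-9)
    return("hAP cannot exceed hR")
  TRUE
})
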