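# Plant point-cloud noise reduction: multi-view interference elimination
# (MIE) collapses the duplicated "layered" leaf surfaces created by
# time-of-flight multipath across views, then moving least squares (MLS)
# removes the remaining local surface noise.

#' Estimate per-point surface normals
#'
#' Normal of each point is the smallest eigenvector of its radius
#' neighborhood's covariance; signs are made locally consistent by
#' propagation over the neighborhood graph.  Points with fewer than 3
#' neighborhood points get an undefined normal (`NaN` row).
#'
#' @param cloud a [ColoredPointCloud-class].
#' @param radius neighborhood radius (m), default 0.006.
#' @return n x 3 matrix of unit normals (NaN rows where undefined).
#' @export
estimateNormals <- function(cloud, radius = 0.006) {
  stopifnot(radius > 0)
  if (nPoints(cloud) == 0L) return(matrix(numeric(0), 0, 3))
  cpp_estimate_normals(cloud@points, radius)
}

#' Multi-view interference elimination (MIE)
#'
#' Iteratively collapses layered duplicate surfaces: a point's
#' opposing-layer neighborhood is the set of points within
#' `layerSearchDist` whose offset direction lies within
#' `acos(oppositionCos)` of the point's surface normal (i.e. off-surface,
#' across the layer gap, on either side).  Each iteration moves every such
#' point by fraction `step` toward the midpoint of itself and the
#' neighborhood centroid; points without an opposing layer do not move.
#' At most `iterationTimes` iterations are run (6 recovers a two-layer
#' artifact into one layer; more buys little at extra cost).
#'
#' @param cloud a [ColoredPointCloud-class].
#' @param iterationTimes maximum iterations, default 6.
#' @param layerSearchDist opposing-layer search distance (m), default 0.006.
#' @param oppositionCos minimum |cos| between offset and normal, default 0.5.
#' @param step contraction fraction per iteration, default 0.5.
#' @param normals optional precomputed n x 3 normals; estimated at radius
#'   `layerSearchDist` when missing.
#' @return The denoised [ColoredPointCloud-class] (same point count and
#'   colors).
#' @export
mieDenoise <- function(cloud, iterationTimes = 6L, layerSearchDist = 0.006,
                       oppositionCos = 0.5, step = 0.5, normals = NULL) {
  stopifnot(iterationTimes >= 0L)
  if (nPoints(cloud) == 0L || iterationTimes == 0L) return(cloud)
  if (is.null(normals)) normals <- estimateNormals(cloud, layerSearchDist)
  pts <- cpp_mie(cloud@points, normals, as.integer(iterationTimes),
                 layerSearchDist, oppositionCos, step)
  pointCloud(pts, cloud@colors, frame = cloud@frame)
}

#' Moving-least-squares surface smoothing
#'
#' Projects each point onto the local weighted polynomial surface fit of
#' its radius neighborhood (Gaussian weights, sigma = radius / 2).  Points
#' whose neighborhood is too small for the fit pass through unchanged.
#' Planes are reproduced exactly and quadratic surfaces are reproduced by
#' the default order-2 fit.
#'
#' @param cloud a [ColoredPointCloud-class].
#' @param mlsRadius smoothing radius (m), default 0.01.
#' @param polyOrder polynomial order, 1 or 2 (default 2).
#' @return The smoothed [ColoredPointCloud-class] (same count and colors).
#' @export
mlsSmooth <- function(cloud, mlsRadius = 0.01, polyOrder = 2L) {
  stopifnot(mlsRadius > 0, polyOrder %in% c(1L, 2L))
  if (nPoints(cloud) == 0L) return(cloud)
  pts <- cpp_mls(cloud@points, mlsRadius, as.integer(polyOrder))
  pointCloud(pts, cloud@colors, frame = cloud@frame)
}
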