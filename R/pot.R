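# Pot-shape-based segmentation: model the truncated-cone pot from two
# fitted section circles, construct the shrunk ("adjusted") cone, and
# segment soil and in-pot plant points by conical projection onto the
# datum plane 1 m above the apex.

#' Extract a horizontal slab of points
#'
#' @param cloud a [ColoredPointCloud-class].
#' @param zCenter slab center (m).
#' @param dz slab half-width (m), > 0.
#' @return The [ColoredPointCloud-class] of points with |z - zCenter| <= dz.
#' @export
extractSlab <- function(cloud, zCenter, dz) {
  stopifnot(dz > 0)
  cloud[abs(cloud@points[, 3] - zCenter) <= dz]
}

#' Fit the 3D section circle of a horizontal slab
#'
#' 2D least-squares circle on the (x, y) coordinates; the 3D center takes
#' the slab's mean z.
#'
#' @param slab a [ColoredPointCloud-class] with at least 3 points.
#' @return List with `center` (length 3) and `radius`.
#' @export
fitSectionCircle <- function(slab) {
  if (nPoints(slab) < 3L) stop("section circle fit needs at least 3 points")
  fc <- fitCircle2d(slab@points[, 1:2, drop = FALSE])
  list(center = c(fc$center, mean(slab@points[, 3])), radius = fc$radius)
}

#' Cone apex from two section circles
#'
#' The apex is where the linearly extrapolated section radius vanishes:
#' `F = (O1 - O2) * r2 / (r2 - r1) + O2`.
#'
#' @param O1,O2 length-3 circle centers (m).
#' @param r1,r2 section radii (m), r1 != r2.
#' @return Length-3 apex coordinates.
#' @examples
#' coneApex(c(0, 0, 0.035), 0.04, c(0, 0, 0.095), 0.06)  # apex at z=-0.085
#' @export
coneApex <- function(O1, r1, O2, r2) {
  if (isTRUE(all.equal(r1, r2)))
    stop("equal section radii: the surface is a cylinder, not a cone")
  (O1 - O2) * r2 / (r2 - r1) + O2
}

#' Conical projection onto the datum plane
#'
#' Projects points through the apex F onto the plane 1 m above it:
#' `px = xF + (xQ - xF) / (zQ - zF)` and analogously for y.
#'
#' @param Q length-3 point or n x 3 matrix.
#' @param apex length-3 cone apex F.
#' @return Length-2 `(px, py)` or an n x 2 matrix.
#' @export
conicalProject <- function(Q, apex) {
  m <- if (is.matrix(Q)) Q else matrix(Q, 1, 3)
  dz <- m[, 3] - apex[3]
  if (any(abs(dz) < 1e-12))
    stop("undefined projection: point at the apex height")
  out <- cbind(px = apex[1] + (m[, 1] - apex[1]) / dz,
               py = apex[2] + (m[, 2] - apex[2]) / dz)
  if (is.matrix(Q)) out else drop(out)
}

#' Fit the truncated-cone pot model from the non-plant cloud
#'
#' Extracts the two sample slabs at z1 and z2, fits their section circles,
#' computes the apex, and derives the adjusted (shrunk) cone's datum-plane
#' circle: radius `ra = eta * |r1 / (z_O1 - z_F)|` and center `Om` the
#' conical projection of O1.
#'
#' @param nonplant the non-plant [ColoredPointCloud-class].
#' @param cfg a [PotSegConfig-class].
#' @return A [PotConeModel-class].
#' @export
fitPotCone <- function(nonplant, cfg = potSegConfig()) {
  s1 <- extractSlab(nonplant, cfg@z1, cfg@dz)
  s2 <- extractSlab(nonplant, cfg@z2, cfg@dz)
  if (nPoints(s1) < 3L || nPoints(s2) < 3L)
    stop("not enough pot-wall points in the sample slabs")
  c1 <- fitSectionCircle(s1)
  c2 <- fitSectionCircle(s2)
  apex <- coneApex(c1$center, c1$radius, c2$center, c2$radius)
  ra <- cfg@eta * abs(c1$radius / (c1$center[3] - apex[3]))
  Om <- c(conicalProject(c1$center, apex), apex[3] + 1)
  new("PotConeModel", O1 = c1$center, O2 = c2$center, r1 = c1$radius,
      r2 = c2$radius, apex = apex, eta = cfg@eta, ra = ra, Om = Om)
}

#' Segment soil and in-pot plant points with the adjusted cone
#'
#' A point belongs to the respective set when its conical projection onto
#' the datum plane falls strictly inside the adjusted circle (center Om,
#' radius ra) and its z lies in the configured interval: soil from the
#' non-plant cloud in `soilZ`, in-pot plant from the denoised plant cloud
#' in `plantZ`.
#'
#' @param nonplant the non-plant [ColoredPointCloud-class].
#' @param plant the denoised plant [ColoredPointCloud-class].
#' @param model a [PotConeModel-class].
#' @param cfg a [PotSegConfig-class].
#' @return List with `soil` and `inPotPlant` clouds.
#' @export
segmentInPot <- function(nonplant, plant, model, cfg = potSegConfig()) {
  inside <- function(cloud, zint) {
    if (nPoints(cloud) == 0L) return(cloud)
    P <- cloud@points
    zok <- P[, 3] >= zint[1] & P[, 3] <= zint[2] &
      abs(P[, 3] - model@apex[3]) > 1e-12
    idx <- which(zok)
    if (!length(idx)) return(cloud[integer(0)])
    pr <- conicalProject(P[idx, , drop = FALSE], model@apex)
    rad <- sqrt((pr[, 1] - model@Om[1])^2 + (pr[, 2] - model@Om[2])^2)
    cloud[idx[rad < model@ra]]
  }
  list(soil = inside(nonplant, cfg@soilZ),
       inPotPlant = inside(plant, cfg@plantZ))
}
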