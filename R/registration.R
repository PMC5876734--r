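# Registration stage: robust plane and circle fits, transformation of
# per-view clouds into the turntable frame, marker-based global refinement,
# and gross-outlier removal.

#' Robust plane fit (consensus + total-least-squares refit)
#'
#' Random-sample consensus maximizes the inlier count at tolerance
#' `inlierTol`, then the plane is refit by total least squares on the
#' inliers (centroid plus smallest covariance eigenvector).  The normal is
#' oriented toward +z.  Uses the current RNG state; seed with `set.seed()`
#' for reproducibility.
#'
#' @param cloud a [ColoredPointCloud-class] with at least 3 non-collinear
#'   points.
#' @param inlierTol inlier distance tolerance (m), default 0.003.
#' @param iterations number of RANSAC draws.
#' @return List with `normal` (unit, +z oriented), `offset` (plane is
#'   `normal . x = offset`) and `inliers` (integer indices).
#' @examples
#' set.seed(1)
#' pc <- pointCloud(cbind(runif(100), runif(100), 0.01))
#' fitPlane(pc)$offset   # ~0.01
#' @export
fitPlane <- function(cloud, inlierTol = 0.003, iterations = 200L) {
  P <- cloud@points
  n <- nrow(P)
  if (n < 3L) stop("plane fit needs at least 3 points")
  best_inl <- integer(0)
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, 3L)
    v1 <- P[idx[2], ] - P[idx[1], ]
    v2 <- P[idx[3], ] - P[idx[1], ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    L <- sqrt(sum(nrm^2))
    if (L < 1e-14) next
    nrm <- nrm / L
    d <- abs(P %*% nrm - sum(nrm * P[idx[1], ]))
    inl <- which(d <= inlierTol)
    if (length(inl) > length(best_inl)) best_inl <- inl
  }
  if (length(best_inl) < 3L) stop("degenerate input: points are collinear")
  Q <- P[best_inl, , drop = FALSE]
  ctr <- colMeans(Q)
  ev <- eigen(crossprod(sweep(Q, 2, ctr)), symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  if (ev$values[2] < 1e-20) stop("degenerate input: points are collinear")
  if (nrm[3] < 0) nrm <- -nrm
  list(normal = nrm, offset = sum(nrm * ctr), inliers = best_inl)
}

#' Algebraic least-squares circle fit in 2D
#'
#' Minimizes the algebraic residual of `x^2 + y^2 = a x + b y + c`
#' (Kasa fit); exact on noise-free circular data.
#'
#' @param pointsXY k x 2 matrix, k >= 3, not all collinear.
#' @return List with `center` (length 2) and `radius`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' fitCircle2d(cbind(1 + 0.05 * cos(th), 2 + 0.05 * sin(th)))
#' @export
fitCircle2d <- function(pointsXY) {
  pointsXY <- as.matrix(pointsXY)
  if (nrow(pointsXY) < 3L) stop("circle fit needs at least 3 points")
  x <- pointsXY[, 1]; y <- pointsXY[, 2]
  A <- cbind(x, y, 1)
  if (qr(A)$rank < 3L) stop("degenerate input: points are collinear")
  sol <- qr.solve(A, x^2 + y^2)
  center <- sol[1:2] / 2
  r2 <- sol[[3]] + sum(center^2)
  if (r2 <= 0) stop("degenerate circle fit")
  list(center = unname(center), radius = unname(sqrt(r2)))
}

#' Transform a view-local cloud into the turntable frame
#'
#' Orients the detected table plane to z = 0 (normal to +z), moves the
#' table center to the origin, aligns the horizontal projection of the
#' first viewing direction with +y, and undoes the turntable rotation of
#' the view's nominal angle.
#'
#' @param view a [ColoredPointCloud-class] in the view-local frame.
#' @param markers the view's [MarkerSet-class] (at least 3 markers).
#' @param tablePlane list with `normal` and `offset` as returned by
#'   [fitPlane()].
#' @param tableCenter length-3 numeric, table center in the view frame.
#' @param viewDir length-3 numeric, first viewing direction in the oriented
#'   frame; its horizontal projection becomes +y.  Default `c(0, 1, 0)`.
#' @return List with `cloud` and `markers`, both in the turntable frame.
#' @export
toTurntableFrame <- function(view, markers, tablePlane, tableCenter,
                             viewDir = c(0, 1, 0)) {
  if (nrow(markers@markers) < 3L)
    stop("at least 3 markers are required")
  nrm <- tablePlane$normal / sqrt(sum(tablePlane$normal^2))
  if (nrm[3] < 0) nrm <- -nrm
  # rotation taking the plane normal to +z
  z <- c(0, 0, 1)
  v <- c(nrm[2] * z[3] - nrm[3] * z[2],
         nrm[3] * z[1] - nrm[1] * z[3],
         nrm[1] * z[2] - nrm[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(nrm * z)
  R1 <- if (s < 1e-14) diag(3) else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  base <- rigidTransform(R1, as.vector(-R1 %*% tableCenter))
  # y-axis convention: horizontal projection of the first viewing direction
  vd <- as.vector(R1 %*% viewDir); vd[3] <- 0
  if (sqrt(sum(vd^2)) > 1e-12) {
    ang <- atan2(vd[1], vd[2]) * 180 / pi  # rotate so vd maps onto +y
    base <- composeTransforms(rotationZ(ang), base)
  }
  # undo the turntable rotation of this view
  tf <- composeTransforms(rotationZ(markers@nominalAngle), base)
  cl <- applyTransform(tf, view)
  cl@frame <- "turntable"
  list(cloud = cl, markers = applyTransform(tf, markers))
}

#' Marker-based global registration of turntable-frame views
#'
#' Refines each view with the rigid transform minimizing the summed squared
#' distance between its markers and the reference markers (view 0), solved
#' in closed form on the known correspondences and iterated to convergence.
#' With `correspondence = FALSE`, marker identities are ignored and
#' closest-point matching (classic ICP) is used instead.
#'
#' @param views list of `list(cloud=, markers=)` pairs in the turntable
#'   frame, as produced by [toTurntableFrame()].
#' @param correspondence use known marker correspondences (default TRUE).
#' @param maxIter,tol ICP iteration control.
#' @return List with `clouds` (registered [ColoredPointCloud-class]s),
#'   `transforms`, and `markerRMS` (post-registration RMS distance, m).
#' @export
globalRegister <- function(views, correspondence = TRUE, maxIter = 50L,
                           tol = 1e-12) {
  stopifnot(length(views) >= 1L)
  ref <- views[[1]]$markers@markers
  if (nrow(ref) < 3L) stop("at least 3 common markers are required")
  out_clouds <- vector("list", length(views))
  out_tf <- vector("list", length(views))
  rms <- numeric(length(views))
  for (k in seq_along(views)) {
    mk <- views[[k]]$markers@markers
    tf <- rigidTransform()
    cur <- mk
    for (it in seq_len(maxIter)) {
      tgt <- if (correspondence) ref else {
        # closest-point correspondences
        ref[apply(cur, 1, function(p)
          which.min(colSums((t(ref) - p)^2))), , drop = FALSE]
      }
      step <- .kabsch(cur, tgt)
      cur <- applyTransform(step, cur)
      tf <- composeTransforms(step, tf)
      delta <- max(abs(step@rotation - diag(3)), abs(step@translation))
      if (correspondence || delta < tol) break
    }
    resid <- cur - (if (correspondence) ref else
      ref[apply(cur, 1, function(p)
        which.min(colSums((t(ref) - p)^2))), , drop = FALSE])
    rms[k] <- sqrt(mean(rowSums(resid^2)))
    out_clouds[[k]] <- applyTransform(tf, views[[k]]$cloud)
    out_tf[[k]] <- tf
  }
  if (any(rms > 1e-4))
    warning(sprintf("marker RMS after registration up to %.2g m", max(rms)))
  list(clouds = out_clouds, transforms = out_tf, markerRMS = rms)
}

#' Merge clouds into one
#' @param clouds list of [ColoredPointCloud-class] in a common frame.
#' @return A single concatenated [ColoredPointCloud-class].
#' @export
mergeClouds <- function(clouds) {
  pointCloud(do.call(rbind, lapply(clouds, cloudPoints)),
             do.call(rbind, lapply(clouds, cloudColors)),
             frame = clouds[[1]]@frame)
}

#' Neighbor-checking outlier removal
#'
#' Keeps exactly the points with at least `minNeighbors` other points
#' within `radius`.
#'
#' @param cloud a [ColoredPointCloud-class].
#' @param radius search radius (m), default 0.005.
#' @param minNeighbors minimum neighbor count, default 4.
#' @return The filtered [ColoredPointCloud-class].
#' @export
removeOutliers <- function(cloud, radius = 0.005, minNeighbors = 4L) {
  stopifnot(radius > 0)
  if (nPoints(cloud) == 0L) return(cloud)
  counts <- cpp_neighbor_counts(cloud@points, radius)
  cloud[counts >= minNeighbors]
}

#' Pre-denoising of flying pixels and violently fluctuating points
#'
#' Removes points whose distance to the centroid of their radius
#' neighborhood exceeds `maxLocalDev` — isolated spikes sit far from their
#' local centroid while surface points sit near it.
#'
#' @param cloud a [ColoredPointCloud-class].
#' @param radius neighborhood radius (m), default 0.005.
#' @param maxLocalDev maximum allowed deviation (m), default 0.002.
#' @return The filtered [ColoredPointCloud-class].
#' @export
preDenoise <- function(cloud, radius = 0.005, maxLocalDev = 0.002) {
  stopifnot(radius > 0)
  if (nPoints(cloud) == 0L) return(cloud)
  dev <- cpp_local_centroid_dev(cloud@points, radius)
  cloud[dev <= maxLocalDev]
}
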