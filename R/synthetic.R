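# Synthetic potted-plant scenes with analytic ground truth.
#
# A scene is a truncated-cone pot, a soil disk, and a canopy of curved
# parametric leaf patches.  Every ground-truth quantity is computed by an
# oracle independent of the measurement code: total leaf area by Gauss-
# Legendre quadrature of the first fundamental form, projected area by
# point-in-polygon rasterization of the projected leaf rims, and canopy
# volume by a dense occupancy grid over the thickened surfaces.  Colors are
# sampled in HSI strictly inside the plant / non-plant acceptance regions
# (with an optional ambiguous fraction between the two quadric surfaces)
# and snapped to the 8-bit RGB grid that survives file round-trips.

# run expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.snap8 <- function(rgb) round(pmin(pmax(rgb, 0), 1) * 255) / 255

# sample n colors in HSI inside the requested class region, return RGB
.sample_colors <- function(n, class = c("plant", "nonplant-pot",
                                        "nonplant-soil", "ambiguous"),
                           model = quadricSegModel()) {
  class <- match.arg(class)
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  H <- S <- I <- numeric(n)
  if (class == "plant") {
    H <- runif(n, 0.27, 0.36)
    S <- runif(n, 0.4, 0.6)
    f <- evalQuadric(model@plantCoeffs, H, S)
    I <- runif(n, pmax(f, model@iMinPlant) + 0.05, 0.7)
  } else if (class == "ambiguous") {
    # between the non-plant surface g and the plant surface f
    H <- runif(n, 0.28, 0.34)
    S <- runif(n, 0.45, 0.6)
    f <- evalQuadric(model@plantCoeffs, H, S)
    g <- evalQuadric(model@nonplantCoeffs, H, S)
    I <- g + (f - g) * runif(n, 0.35, 0.65)
  } else if (class == "nonplant-pot") {
    H <- runif(n, 0.02, 0.06)       # terracotta
    S <- runif(n, 0.32, 0.48)
    g <- evalQuadric(model@nonplantCoeffs, H, S)
    I <- runif(n, 0.12, pmin(g - 0.08, 0.33))
  } else {
    H <- runif(n, 0.05, 0.09)       # brown soil
    S <- runif(n, 0.25, 0.45)
    I <- runif(n, 0.08, 0.22)
  }
  .snap8(hsiToRgb(cbind(H, S, I)))
}

#' Generate a truncated-cone pot wall
#'
#' Points sampled exactly on the cone with the given apex and half-angle,
#' between the two z levels; terracotta (non-plant) colors.
#'
#' @param apex length-3 cone apex (m); the pot widens upward from it.
#' @param halfAngle cone half-angle in degrees, 0 < halfAngle < 90.
#' @param zRange length-2 z interval (m), above the apex.
#' @param nPoints number of points.
#' @param seed RNG seed (caller's RNG state is preserved).
#' @return A [ColoredPointCloud-class] on the cone (within 1e-9).
#' @export
genPot <- function(apex, halfAngle, zRange, nPoints, seed = NULL) {
  stopifnot(halfAngle > 0, halfAngle < 90)
  if (diff(zRange) <= 0) stop("degenerate z range")
  if (min(zRange) <= apex[3]) stop("z range must lie above the apex")
  .with_seed(seed, {
    z <- runif(nPoints, zRange[1], zRange[2])
    th <- runif(nPoints, 0, 2 * pi)
    r <- tan(halfAngle * pi / 180) * (z - apex[3])
    pts <- cbind(apex[1] + r * cos(th), apex[2] + r * sin(th), z)
    pointCloud(pts, .sample_colors(nPoints, "nonplant-pot"))
  })
}

#' Generate a soil disk
#'
#' Uniform samples on a horizontal disk with Gaussian surface roughness in
#' z; brown (non-plant) colors.
#'
#' @param centerZ disk height (m).
#' @param radius disk radius (m), >= 0.
#' @param roughnessSd z roughness standard deviation (m).
#' @param nPoints number of points.
#' @param seed RNG seed.
#' @return A [ColoredPointCloud-class].
#' @export
genSoil <- function(centerZ, radius, roughnessSd, nPoints, seed = NULL) {
  stopifnot(radius >= 0)
  .with_seed(seed, {
    r <- radius * sqrt(runif(nPoints))
    th <- runif(nPoints, 0, 2 * pi)
    z <- centerZ + if (roughnessSd > 0) rnorm(nPoints, 0, roughnessSd) else 0
    pointCloud(cbind(r * cos(th), r * sin(th), z),
               .sample_colors(nPoints, "nonplant-soil"))
  })
}

#' Parametric leaf patch
#'
#' A curved elliptical patch emulating a lettuce leaf: over the unit-disk
#' parameter domain (r, theta), the local surface is
#' `(a (r cos(theta) + 1), b r sin(theta), -droop max(r cos(theta), 0)^2)` —
#' an ellipse with semi-axes a, b whose inner tip sits at the attachment
#' point; the outer half bends down quadratically along the leaf axis (a
#' cylindrical droop) while the inner half and the side rims stay in the
#' tilt plane, so stacked leaves keep their vertical clearance — pitched
#' up by
#' `tiltDeg` about the attachment and swung to `azimuthDeg`.
#'
#' Sinusoidal ruffling components (amplitude `amp`, wavelength `len`,
#' random-looking phases) can be superimposed to emulate the curled,
#' ruffled blades of mature lettuce; they thicken the overlapped-
#' tetrahedra union the way residual surface structure does in real
#' scans.
#'
#' @param a,b semi-axes (m).
#' @param droop quadratic droop depth (m) at the rim.
#' @param tiltDeg pitch of the leaf axis above horizontal, degrees.
#' @param azimuthDeg azimuth of the leaf axis, degrees.
#' @param attach length-3 attachment point (m).
#' @param waves optional data.frame with columns `amp`, `len`, `phiU`,
#'   `phiV` describing sinusoidal ruffles added to the local height.
#' @return A list describing the patch (`a`, `b`, `droop`, `M` rotation,
#'   `attach`, `waves`).
#' @export
leafPatch <- function(a, b, droop, tiltDeg, azimuthDeg, attach,
                      waves = NULL) {
  tau <- tiltDeg * pi / 180
  phi <- azimuthDeg * pi / 180
  # local +u pitched up by tau: z' = u sin(tau) + w cos(tau)
  Ry <- matrix(c(cos(tau), 0, -sin(tau),
                 0, 1, 0,
                 sin(tau), 0, cos(tau)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(phi), -sin(phi), 0,
                 sin(phi), cos(phi), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  list(a = a, b = b, droop = droop, tilt = tau, M = Rz %*% Ry,
       attach = as.numeric(attach), waves = waves)
}

# local height w(u, v) over the (u, v) ellipse, and its partials
.leaf_w <- function(patch, u, v) {
  w <- -patch$droop * pmax((u - patch$a) / patch$a, 0)^2
  if (!is.null(patch$waves))
    for (k in seq_len(nrow(patch$waves))) {
      wv <- patch$waves[k, ]
      kk <- 2 * pi / wv$len
      w <- w + wv$amp * sin(kk * u + wv$phiU) * cos(kk * v + wv$phiV)
    }
  w
}

.leaf_w_grad <- function(patch, u, v) {
  wu <- -2 * patch$droop * pmax((u - patch$a) / patch$a, 0) / patch$a
  wv_ <- rep(0, length(u))
  if (!is.null(patch$waves))
    for (k in seq_len(nrow(patch$waves))) {
      wv <- patch$waves[k, ]
      kk <- 2 * pi / wv$len
      wu <- wu + wv$amp * kk * cos(kk * u + wv$phiU) * cos(kk * v + wv$phiV)
      wv_ <- wv_ - wv$amp * kk * sin(kk * u + wv$phiU) * sin(kk * v + wv$phiV)
    }
  cbind(wu, wv_)
}

# evaluate a patch at parameter values (vectorized)
.leaf_eval <- function(patch, r, theta) {
  u <- patch$a * (r * cos(theta) + 1)
  v <- patch$b * r * sin(theta)
  sweep(cbind(u, v, .leaf_w(patch, u, v)) %*% t(patch$M), 2, patch$attach,
        `+`)
}

#' Analytic leaf area by quadrature
#'
#' Integrates the patch's area element |S_r x S_theta| with Gauss-Legendre
#' nodes in r and a midpoint rule in theta (spectrally accurate for the
#' periodic direction).  A flat patch (droop 0) integrates to pi a b
#' exactly to quadrature precision.
#'
#' @param patch a [leafPatch()].
#' @param nR,nTheta quadrature resolution.
#' @return Area in m^2.
#' @export
leafArea <- function(patch, nR = 64L, nTheta = 256L) {
  gl <- pracma::gaussLegendre(nR, 0, 1)
  th <- (seq_len(nTheta) - 0.5) * 2 * pi / nTheta
  a <- patch$a; b <- patch$b
  tot <- 0
  for (i in seq_len(nR)) {
    r <- gl$x[i]
    u <- a * (r * cos(th) + 1)
    v <- b * r * sin(th)
    g <- .leaf_w_grad(patch, u, v)
    # graph area element sqrt(1 + wu^2 + wv^2), Jacobian a b r
    nrm <- a * b * r * sqrt(1 + g[, 1]^2 + g[, 2]^2)
    tot <- tot + gl$w[i] * sum(nrm) * (2 * pi / nTheta)
  }
  tot
}

# apex (maximum-z point) of a patch: analytic along theta = 0 for smooth
# patches, dense-grid search when ruffling waves are present
.leaf_apex <- function(patch) {
  if (is.null(patch$waves)) {
    a <- patch$a; d <- patch$droop; tau <- patch$tilt
    rstar <- if (d > 1e-12) min(1, a * tan(tau) / (2 * d)) else 1
    return(.leaf_eval(patch, rstar, 0))
  }
  gr <- expand.grid(r = sqrt(seq(0.0005, 0.9995, length.out = 300)),
                    t = seq(0, 2 * pi, length.out = 361)[-361])
  p <- .leaf_eval(patch, gr$r, gr$t)
  p[which.max(p[, 3]), , drop = FALSE]
}

# lowest point of a patch (the inner tip, r = 1, theta = pi)
.leaf_base <- function(patch) .leaf_eval(patch, 1, pi)

#' Uniform surface samples of a leaf patch
#'
#' Rejection sampling uniform over the (u, v) ellipse; the patch's apex
#' (maximum z) and inner-tip points are appended so the analytic plant
#' top and stem base are always represented in the cloud.
#'
#' @param patch a [leafPatch()].
#' @param spacing target sample spacing (m); the sample count is
#'   area / spacing^2.
#' @param seed RNG seed.
#' @return n x 3 matrix of surface points.
#' @export
leafPoints <- function(patch, spacing = 0.0008, seed = NULL) {
  .with_seed(seed, {
    n <- max(16L, ceiling(leafArea(patch, 16L, 64L) / spacing^2))
    got <- 0L
    out <- matrix(0, 0, 3)
    while (got < n) {
      m <- ceiling((n - got) * 4 / pi * 1.1)
      u <- runif(m, 0, 2 * patch$a)
      v <- runif(m, -patch$b, patch$b)
      r2 <- ((u - patch$a) / patch$a)^2 + (v / patch$b)^2
      keep <- r2 <= 1
      if (any(keep)) {
        loc <- cbind(u[keep], v[keep], .leaf_w(patch, u[keep], v[keep]))
        out <- rbind(out, sweep(loc %*% t(patch$M), 2, patch$attach, `+`))
        got <- nrow(out)
      }
    }
    rbind(out[seq_len(n), , drop = FALSE], .leaf_apex(patch),
          .leaf_base(patch))
  })
}

#' Projected canopy area by rasterization (oracle)
#'
#' Each leaf's vertical projection is the region enclosed by its projected
#' rim (the patches are graphs over their projection for the slopes used
#' here); the union is rasterized by exact point-in-polygon tests at pixel
#' centers.  Independent of the grid-counting measurement code.
#'
#' @param patches list of [leafPatch()].
#' @param pixel rasterization pixel (m), default 0.00025.
#' @param nRim rim polygon resolution.
#' @return Projected area in m^2.
#' @export
canopyProjectedArea <- function(patches, pixel = 0.00025, nRim = 360L) {
  th <- seq(0, 2 * pi, length.out = nRim + 1L)[-(nRim + 1L)]
  rims <- lapply(patches, function(p) .leaf_eval(p, 1, th)[, 1:2])
  allxy <- do.call(rbind, rims)
  x0 <- min(allxy[, 1]) - pixel; x1 <- max(allxy[, 1]) + pixel
  y0 <- min(allxy[, 2]) - pixel; y1 <- max(allxy[, 2]) + pixel
  nx <- ceiling((x1 - x0) / pixel); ny <- ceiling((y1 - y0) / pixel)
  xs <- x0 + (seq_len(nx) - 0.5) * pixel
  ys <- y0 + (seq_len(ny) - 0.5) * pixel
  covered <- matrix(FALSE, nx, ny)
  for (rim in rims) {
    ix <- which(xs >= min(rim[, 1]) - pixel & xs <= max(rim[, 1]) + pixel)
    iy <- which(ys >= min(rim[, 2]) - pixel & ys <= max(rim[, 2]) + pixel)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    inside <- rep(FALSE, length(px))
    m <- nrow(rim)
    xj <- rim[m, 1]; yj <- rim[m, 2]
    for (e in seq_len(m)) {
      xi <- rim[e, 1]; yi <- rim[e, 2]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      xj <- xi; yj <- yi
    }
    covered[ix, iy] <- covered[ix, iy] | matrix(inside, length(ix),
                                                length(iy))
  }
  sum(covered) * pixel^2
}

#' Canopy volume of the thickened leaf surfaces (oracle)
#'
#' Dense-grid occupancy: voxel centers within `thickness / 2` of any dense
#' surface sample count as canopy.  A coarse but measurement-independent
#' reference for the tetrahedra-union volume.
#'
#' @param patches list of [leafPatch()].
#' @param thickness slab thickness around each surface (m), default 0.004.
#' @param voxel occupancy grid spacing (m), default 0.0015.
#' @return Volume in m^3.
#' @export
canopyVolumeTruth <- function(patches, thickness = 0.004, voxel = 0.0015) {
  dense <- do.call(rbind, lapply(patches, function(p) {
    nr <- ceiling(4 * p$a / 0.001)
    nt <- ceiling(2 * pi * p$a / 0.001)
    gr <- expand.grid(r = sqrt(seq(0.5 / nr, 1 - 0.5 / nr, length.out = nr)),
                      t = (seq_len(nt) - 0.5) * 2 * pi / nt)
    .leaf_eval(p, gr$r, gr$t)
  }))
  rad <- thickness / 2
  lo <- apply(dense, 2, min) - rad - voxel
  hi <- apply(dense, 2, max) + rad + voxel
  ns <- pmax(1, ceiling((hi - lo) / voxel))
  total <- 0
  # chunk the grid by z slabs to bound memory
  zc <- lo[3] + (seq_len(ns[3]) - 0.5) * voxel
  xc <- lo[1] + (seq_len(ns[1]) - 0.5) * voxel
  yc <- lo[2] + (seq_len(ns[2]) - 0.5) * voxel
  xy <- cbind(rep(xc, times = ns[2]), rep(yc, each = ns[1]))
  for (z in zc) {
    q <- cbind(xy, z)
    total <- total + sum(cpp_any_within(dense, q, rad))
  }
  total * voxel^3
}

#' Generate a leaf canopy with analytic ground truth
#'
#' `nLeaves` curved leaf patches radiate from the stem axis at evenly
#' spread azimuths, climbing a vertical ladder of `ladderStep` per leaf so
#' neighboring leaves never touch while their projections overlap near the
#' center.  Per-leaf size and azimuth receive seeded jitter.  Colors
#' satisfy the plant acceptance region, with an optional ambiguous
#' fraction between the two decision surfaces.
#'
#' @param nLeaves number of leaves, >= 1.
#' @param leafScale nominal semi-major axis a (m); b = 0.6 a.
#' @param stemBaseZ z of the lowest leaf attachment (m).
#' @param seed RNG seed.
#' @param tiltDeg leaf pitch (degrees), default 35.
#' @param scaleJitter relative jitter of a, default 0.05.
#' @param azimuthJitterDeg azimuth jitter, default 6.
#' @param ladderStep vertical spacing of successive attachments (m); the
#'   default 0.015 keeps neighboring leaf sheets farther apart than the
#'   canonical MLS smoothing radius so denoising cannot merge them.
#' @param sampleSpacing surface sample spacing (m), default 0.0008.
#' @param ambiguousFrac fraction of points given ambiguous colors.
#' @param wavyAmps,wavyLens amplitudes and wavelengths (m) of sinusoidal
#'   leaf ruffling (empty = smooth leaves); per-leaf phases are drawn from
#'   the seeded RNG.
#' @return List with `cloud` ([ColoredPointCloud-class]), `truth`
#'   ([SceneTruth-class] with canopy fields filled), and `patches`.
#' @export
genCanopy <- function(nLeaves, leafScale, stemBaseZ = 0.16, seed = NULL,
                      tiltDeg = 35, scaleJitter = 0.05,
                      azimuthJitterDeg = 6, ladderStep = 0.015,
                      sampleSpacing = 0.0008, ambiguousFrac = 0,
                      wavyAmps = numeric(0), wavyLens = numeric(0)) {
  stopifnot(nLeaves >= 1, length(wavyAmps) == length(wavyLens))
  .with_seed(seed, {
    patches <- vector("list", nLeaves)
    for (i in seq_len(nLeaves)) {
      a <- leafScale * (1 + runif(1, -scaleJitter, scaleJitter))
      b <- 0.6 * a
      tau <- tiltDeg * pi / 180
      droop <- a * (tan(tau) / 2 + runif(1, 0.1, 0.16))
      az <- (i - 1) * 360 / nLeaves + runif(1, -azimuthJitterDeg,
                                            azimuthJitterDeg)
      attach <- c(0, 0, stemBaseZ + (i - 1) * ladderStep)
      waves <- if (length(wavyAmps))
        data.frame(amp = wavyAmps, len = wavyLens,
                   phiU = runif(length(wavyAmps), 0, 2 * pi),
                   phiV = runif(length(wavyAmps), 0, 2 * pi)) else NULL
      patches[[i]] <- leafPatch(a, b, droop, tiltDeg, az, attach, waves)
    }
    pts <- do.call(rbind, lapply(patches, leafPoints,
                                 spacing = sampleSpacing))
    n <- nrow(pts)
    nAmb <- round(ambiguousFrac * n)
    cols <- .sample_colors(n - nAmb, "plant")
    if (nAmb > 0) {
      cols <- rbind(cols, .sample_colors(nAmb, "ambiguous"))
      cols <- cols[sample.int(n), , drop = FALSE]  # scatter ambiguous points
    }
    truth <- new("SceneTruth",
                 plantTopZ = max(vapply(patches,
                                        function(p) .leaf_apex(p)[3],
                                        numeric(1))),
                 stemBaseZ = min(vapply(patches,
                                        function(p) .leaf_base(p)[3],
                                        numeric(1))),
                 leafAreaTotal = sum(vapply(patches, leafArea, numeric(1))),
                 leafAreaProjected = canopyProjectedArea(patches),
                 canopyVolume = NA_real_)
    list(cloud = pointCloud(pts, cols), truth = truth, patches = patches)
  })
}

#' Generate a full potted-plant scene
#'
#' Pot wall + soil disk + canopy, merged in the turntable frame, with a
#' [SceneTruth-class] combining all ground-truth quantities.  The presets
#' emulate three growth stages: `small` (4 leaves, a = 3 cm), `medium`
#' (6 leaves, a = 4 cm), `large` (8 leaves, a = 5 cm).
#'
#' @param preset `"small"`, `"medium"` or `"large"`.
#' @param seed RNG seed.
#' @param soilRoughnessSd soil z roughness (m), default 5e-4.
#' @param ambiguousFrac fraction of ambiguous-colored canopy points.
#' @param computeVolumeTruth also fill the (slow) canopy volume oracle.
#' @param nLeaves,leafScale,ladderStep,sampleSpacing canopy overrides
#'   forwarded to [genCanopy()] (defaults come from the preset).
#' @param potRings sample the pot wall inside the two section slabs as
#'   exact circular rings at z1 and z2 instead of tapered bands; isolates
#'   the cone-apex extrapolation from the (real, but tiny) taper bias of
#'   fitting one circle to a conical band.
#' @return List with `cloud`, `truth`, `patches`, and the component clouds
#'   `pot`, `soil`, `canopy`.
#' @export
genScene <- function(preset = c("medium", "small", "large"), seed = NULL,
                     soilRoughnessSd = 5e-4, ambiguousFrac = 0,
                     computeVolumeTruth = FALSE, potRings = FALSE,
                     nLeaves = NULL, leafScale = NULL, ladderStep = 0.015,
                     sampleSpacing = 0.0008) {
  preset <- match.arg(preset)
  par <- switch(preset,
                small = list(nLeaves = 4L, scale = 0.03),
                medium = list(nLeaves = 6L, scale = 0.04),
                large = list(nLeaves = 8L, scale = 0.05))
  if (!is.null(nLeaves)) par$nLeaves <- nLeaves
  if (!is.null(leafScale)) par$scale <- leafScale
  .with_seed(seed, {
    apex <- c(0, 0, -0.085)
    halfAngle <- atan2(1, 3) * 180 / pi  # radius 0.04 at z = 0.035
    pot <- if (potRings) {
      ring <- function(z, n) {
        th <- runif(n, 0, 2 * pi)
        r <- tan(halfAngle * pi / 180) * (z - apex[3])
        pointCloud(cbind(r * cos(th), r * sin(th), z),
                   .sample_colors(n, "nonplant-pot"))
      }
      mergeClouds(list(genPot(apex, halfAngle, c(0.002, 0.029), 1200),
                       ring(0.035, 800),
                       genPot(apex, halfAngle, c(0.041, 0.089), 2000),
                       ring(0.095, 800),
                       genPot(apex, halfAngle, c(0.101, 0.168), 2000)))
    } else genPot(apex, halfAngle, c(0.002, 0.168), 6000)
    soilZ <- 0.14
    soil <- genSoil(soilZ, 0.062, soilRoughnessSd, 3000)
    can <- genCanopy(par$nLeaves, par$scale, stemBaseZ = 0.16,
                     ladderStep = ladderStep, sampleSpacing = sampleSpacing,
                     ambiguousFrac = ambiguousFrac)
    truth <- can$truth
    truth@potApex <- apex
    truth@potHalfAngle <- halfAngle
    truth@soilHeight <- soilZ
    if (computeVolumeTruth)
      truth@canopyVolume <- canopyVolumeTruth(can$patches)
    cloud <- mergeClouds(list(pot, soil, can$cloud))
    list(cloud = cloud, truth = truth, patches = can$patches, pot = pot,
         soil = soil, canopy = can$cloud)
  })
}

#' Duplicate a scene into multi-view clouds with capture artifacts
#'
#' View k is the scene rotated by `-k * 360 / nViews` about z (the
#' turntable turning under a fixed camera).  In each view, a random half
#' of the `layerMask` points (the leaves) is displaced by `layerOffset`
#' along its local surface normal, emulating the layered duplicate
#' surfaces of time-of-flight multipath, and every point receives
#' isotropic Gaussian noise of sd `noiseSd`.  Four markers on the
#' turntable rim are transformed identically.
#'
#' @param cloud the scene [ColoredPointCloud-class] (turntable frame).
#' @param nViews number of views, >= 2 (18 in the reference setup, one
#'   every 20 degrees; other counts trigger a warning, not an error).
#' @param layerOffset layer displacement (m), default 0.
#' @param noiseSd Gaussian noise sd (m), default 0.
#' @param seed RNG seed.
#' @param layerMask logical vector marking points subject to layering
#'   (default: points whose color classifies as plant).
#' @param markerRadius turntable rim radius for the 4 markers (m).
#' @return List of `list(cloud=, markers=)` per view, with the applied
#'   [RigidTransform-class]s in `attr(, "transforms")`.
#' @export
genMultiview <- function(cloud, nViews = 18L, layerOffset = 0, noiseSd = 0,
                         seed = NULL, layerMask = NULL,
                         markerRadius = 0.25) {
  stopifnot(nViews >= 2L)
  if (360 %% nViews != 0)
    warning("nViews does not divide 360 evenly; nominal angles will not be ",
            "multiples of a whole degree step")
  .with_seed(seed, {
    if (is.null(layerMask))
      layerMask <- classifyHsi(rgbToHsi(cloud@colors)) == "plant"
    normals <- if (layerOffset != 0) estimateNormals(cloud, 0.004) else NULL
    base_markers <- cbind(markerRadius * cos(c(0, 0.5, 1, 1.5) * pi),
                          markerRadius * sin(c(0, 0.5, 1, 1.5) * pi), 0)
    views <- vector("list", nViews)
    tfs <- vector("list", nViews)
    idx_layer <- which(layerMask)
    for (k in seq_len(nViews) - 1L) {
      tf <- rotationZ(-k * 360 / nViews)
      pts <- cloud@points
      if (layerOffset != 0 && length(idx_layer)) {
        half <- sample(idx_layer, length(idx_layer) %/% 2L)
        nrm <- normals[half, , drop = FALSE]
        nrm[!is.finite(nrm)] <- 0
        pts[half, ] <- pts[half, ] + layerOffset * nrm
      }
      if (noiseSd > 0)
        pts <- pts + matrix(rnorm(length(pts), 0, noiseSd), nrow(pts), 3)
      vcloud <- pointCloud(applyTransform(tf, pts), cloud@colors,
                           frame = "view-local")
      mk <- markerSet(k, nViews, applyTransform(tf, base_markers))
      views[[k + 1L]] <- list(cloud = vcloud, markers = mk)
      tfs[[k + 1L]] <- tf
    }
    attr(views, "transforms") <- tfs
    views
  })
}

#' Synthetic plant mesh at reference processing settings
#'
#' Generates a ruffled canopy of the requested size and meshes it with the
#' canonical parameters (PointSpacing 0.002, TriEdgeLength 0.008); used by
#' the grid-precision studies.  The leaves carry medium- and fine-scale
#' ruffling (4 mm / 1 mm amplitude at 4 cm / 1.2 cm wavelength) so the
#' reconstructed surface, and hence the overlapped-tetrahedra union, has
#' the thickness of a real scan rather than that of an ideal thin sheet.
#'
#' @param size `"small"`, `"medium"` or `"large"`.
#' @param seed RNG seed.
#' @return List with `mesh`, `truth`, `patches`.
#' @export
syntheticPlantMesh <- function(size = c("small", "medium", "large"),
                               seed = NULL) {
  size <- match.arg(size)
  par <- switch(size,
                small = list(nLeaves = 4L, scale = 0.03),
                medium = list(nLeaves = 6L, scale = 0.04),
                large = list(nLeaves = 8L, scale = 0.05))
  can <- genCanopy(par$nLeaves, par$scale, stemBaseZ = 0.16, seed = seed,
                   ladderStep = 0.02,
                   wavyAmps = c(0.004, 0.001), wavyLens = c(0.04, 0.012))
  mesh <- meshPipeline(can$cloud, pipelineConfig())
  list(mesh = mesh, truth = can$truth, patches = can$patches)
}
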