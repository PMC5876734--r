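# Plant / non-plant segmentation in HSI color space.
#
# Plant:     S > 0.1  and  I > 0.05  and  I >= f(H, S)
# Non-plant: S <= 0.1  or  I <= g(H, S)
# Ambiguous: neither.  When both tests pass (possible at low I with S just
# above 0.1) the plant label wins: the plant test is the stricter
# conjunctive one and ambiguity is reserved for "neither".

#' Convert RGB to HSI
#'
#' Intensity is the channel mean I = (r + g + b) / 3; saturation
#' S = 1 - min(r, g, b) / I (0 when I = 0); hue is the standard angular
#' formula normalized to \[0, 1), with H = 0 for achromatic colors (S = 0).
#'
#' @param rgb length-3 vector or n x 3 matrix with components in \[0, 1\].
#' @return Numeric vector `c(H, S, I)` or an n x 3 matrix.
#' @examples
#' rgbToHsi(c(0, 1, 0))   # H = 1/3, S = 1, I = 1/3
#' @export
rgbToHsi <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, 1, 3)
  if (any(m < 0 | m > 1)) stop("RGB components must lie in [0, 1]")
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  I <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  S <- ifelse(I > 0, 1 - mn / I, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 1), -1), 1))
  H <- ifelse(b <= g, theta, 2 * pi - theta) / (2 * pi)
  H[S == 0] <- 0
  H[H >= 1] <- 0
  out <- cbind(H = H, S = S, I = I)
  if (is.matrix(rgb)) out else drop(out)
}

#' Convert HSI to RGB
#'
#' Inverse of [rgbToHsi()] by the standard sector formulas; used by the
#' synthetic scene generator to realize colors sampled in HSI space.
#'
#' @param hsi length-3 vector or n x 3 matrix (`H` in \[0, 1)`, `S`, `I` in
#'   \[0, 1\]).
#' @return RGB vector or matrix with components in \[0, 1\].
#' @export
hsiToRgb <- function(hsi) {
  m <- if (is.matrix(hsi)) hsi else matrix(hsi, 1, 3)
  H <- m[, 1] * 2 * pi; S <- m[, 2]; I <- m[, 3]
  r <- g <- b <- numeric(length(H))
  sec1 <- H < 2 * pi / 3
  sec2 <- H >= 2 * pi / 3 & H < 4 * pi / 3
  sec3 <- H >= 4 * pi / 3
  hh <- H
  hh[sec2] <- H[sec2] - 2 * pi / 3
  hh[sec3] <- H[sec3] - 4 * pi / 3
  x <- I * (1 - S)
  y <- I * (1 + S * cos(hh) / cos(pi / 3 - hh))
  z <- 3 * I - x - y
  b[sec1] <- x[sec1]; r[sec1] <- y[sec1]; g[sec1] <- z[sec1]
  r[sec2] <- x[sec2]; g[sec2] <- y[sec2]; b[sec2] <- z[sec2]
  g[sec3] <- x[sec3]; b[sec3] <- y[sec3]; r[sec3] <- z[sec3]
  out <- cbind(r = pmin(pmax(r, 0), 1), g = pmin(pmax(g, 0), 1),
               b = pmin(pmax(b, 0), 1))
  if (is.matrix(hsi)) out else drop(out)
}

#' Evaluate a quadric decision surface
#'
#' `c0 + c1 H + c2 S + c3 H^2 + c4 H S + c5 S^2`.
#'
#' @param coeffs numeric(6) in the order constant, H, S, H^2, H*S, S^2.
#' @param H,S hue and saturation (vectorized).
#' @return Numeric value(s) of the quadric.
#' @examples
#' evalQuadric(quadricSegModel()@plantCoeffs, 0, 0)   # 1.114
#' @export
evalQuadric <- function(coeffs, H, S) {
  stopifnot(length(coeffs) == 6L)
  coeffs[1] + coeffs[2] * H + coeffs[3] * S + coeffs[4] * H^2 +
    coeffs[5] * H * S + coeffs[6] * S^2
}

#' Classify HSI colors as plant / non-plant / ambiguous
#'
#' @param hsi length-3 vector or n x 3 matrix of HSI values.
#' @param model a [QuadricSegModel-class]; default [quadricSegModel()].
#' @return Character vector of labels `"plant"`, `"nonplant"`,
#'   `"ambiguous"`.
#' @examples
#' classifyHsi(c(0.35, 0.6, 0.4))    # "plant"
#' @export
classifyHsi <- function(hsi, model = quadricSegModel()) {
  m <- if (is.matrix(hsi)) hsi else matrix(hsi, 1, 3)
  H <- m[, 1]; S <- m[, 2]; I <- m[, 3]
  f <- evalQuadric(model@plantCoeffs, H, S)
  g <- evalQuadric(model@nonplantCoeffs, H, S)
  is_plant <- S > model@sMinPlant & I > model@iMinPlant & I >= f
  is_nonplant <- !is_plant & (S <= model@sMaxNonplant | I <= g)
  out <- rep("ambiguous", length(H))
  out[is_plant] <- "plant"
  out[is_nonplant] <- "nonplant"
  out
}

#' Smoothed reference colors
#'
#' Gaussian distance-weighted (sigma = radius / 2) average color over each
#' point's radius neighborhood.  The returned reference colors are used for
#' classification only; the cloud's own colors are never altered, so color
#' detail is preserved for other uses.
#'
#' @param cloud a [ColoredPointCloud-class].
#' @param radius smoothing radius (m), default 0.005.
#' @return n x 3 matrix of reference RGB colors.
#' @export
smoothColors <- function(cloud, radius = 0.005) {
  stopifnot(radius > 0)
  if (nPoints(cloud) == 0L) return(cloud@colors)
  cpp_weighted_neighbor_mean(cloud@points, cloud@colors, radius, radius / 2)
}

#' Segment a cloud into plant, non-plant and ambiguous parts
#'
#' Classification runs on smoothed reference colors (mitigating the
#' inconsistent color mapping across views) while the output clouds keep
#' their original colors.  The three outputs partition the input exactly.
#'
#' @param cloud a non-empty [ColoredPointCloud-class].
#' @param model a [QuadricSegModel-class].
#' @param smoothRadius color smoothing radius (m); 0 disables smoothing.
#' @return List with `plant`, `nonplant`, `ambiguous` clouds and `labels`.
#' @export
segmentCloud <- function(cloud, model = quadricSegModel(),
                         smoothRadius = 0.005) {
  if (nPoints(cloud) == 0L) stop("cannot segment an empty cloud")
  ref <- if (smoothRadius > 0) smoothColors(cloud, smoothRadius) else
    cloud@colors
  labels <- classifyHsi(rgbToHsi(ref), model)
  list(plant = cloud[labels == "plant"],
       nonplant = cloud[labels == "nonplant"],
       ambiguous = cloud[labels == "ambiguous"],
       labels = labels)
}

#' Fit a quadric boundary surface to HSI samples
#'
#' Least-squares fit of I ~ quadric(H, S) to manually selected points
#' around a class boundary; this is the fitting utility behind the shipped
#' segmentation coefficients.
#'
#' @param boundarySamples k x 3 matrix of (H, S, I) samples, k >= 6, with
#'   H and S spanning a full-rank quadric design.
#' @return numeric(6) quadric coefficients.
#' @export
fitQuadricBoundary <- function(boundarySamples) {
  m <- as.matrix(boundarySamples)
  if (nrow(m) < 6L) stop("at least 6 boundary samples are required")
  H <- m[, 1]; S <- m[, 2]; I <- m[, 3]
  X <- cbind(1, H, S, H^2, H * S, S^2)
  if (qr(X)$rank < 6L) stop("rank-deficient design: samples must span H and S")
  unname(qr.solve(X, I))
}

#' Segmentation scores (true-positive / true-negative rates)
#'
#' Point-count TPR and TNR of a predicted labeling against a reference
#' labeling, for a given positive class.
#'
#' @param predicted,truth character vectors of labels.
#' @param positive the positive class, e.g. `"plant"`.
#' @return List with `TPR` and `TNR` in percent.
#' @export
segmentationScores <- function(predicted, truth, positive = "plant") {
  stopifnot(length(predicted) == length(truth))
  pos <- truth == positive
  list(TPR = 100 * sum(predicted[pos] == positive) / max(sum(pos), 1L),
       TNR = 100 * sum(predicted[!pos] != positive) / max(sum(!pos), 1L))
}
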