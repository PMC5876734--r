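# Rigid-transform utilities.

#' Rotation about the z axis
#' @param angleDeg angle in degrees (counter-clockwise seen from +z).
#' @return A [RigidTransform-class].
#' @export
rotationZ <- function(angleDeg) {
  a <- angleDeg * pi / 180
  rigidTransform(matrix(c(cos(a), sin(a), 0,
                          -sin(a), cos(a), 0,
                          0, 0, 1), 3, 3))
}

#' Apply a rigid transform
#' @param transform a [RigidTransform-class].
#' @param x an n x 3 matrix, a [ColoredPointCloud-class] or a
#'   [MarkerSet-class].
#' @return The transformed object (same type as `x`).
#' @export
setGeneric("applyTransform",
           function(transform, x) standardGeneric("applyTransform"))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "matrix"),
  function(transform, x) {
    t(transform@rotation %*% t(x)) +
      matrix(transform@translation, nrow(x), 3, byrow = TRUE)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "ColoredPointCloud"),
  function(transform, x) {
    pointCloud(applyTransform(transform, x@points), x@colors, frame = x@frame)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "MarkerSet"),
  function(transform, x) {
    markerSet(x@viewIndex, x@nViews, applyTransform(transform, x@markers))
  })

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [RigidTransform-class] objects.
#' @return The composite transform `x -> a(b(x))`.
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.vector(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return The inverse transform.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, as.vector(-Rt %*% transform@translation))
}

# Least-squares rigid transform mapping rows of A onto rows of B (Kabsch).
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigidTransform(R, cb - as.vector(R %*% ca))
}
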