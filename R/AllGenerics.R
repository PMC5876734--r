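# Accessors and show methods.

#' Number of points in a cloud
#' @param x a [ColoredPointCloud-class].
#' @return integer point count.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "ColoredPointCloud", function(x) nrow(x@points))

#' Point coordinates of a cloud
#' @param x a [ColoredPointCloud-class].
#' @return n x 3 numeric matrix (m).
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))

#' @rdname cloudPoints
#' @export
setMethod("cloudPoints", "ColoredPointCloud", function(x) x@points)

#' Point colors of a cloud
#' @param x a [ColoredPointCloud-class].
#' @return n x 3 numeric matrix of RGB in \[0, 1\].
#' @export
setGeneric("cloudColors", function(x) standardGeneric("cloudColors"))

#' @rdname cloudColors
#' @export
setMethod("cloudColors", "ColoredPointCloud", function(x) x@colors)

#' Coordinate frame tag of a cloud
#' @param x a [ColoredPointCloud-class].
#' @return `"view-local"` or `"turntable"`.
#' @export
setGeneric("frameTag", function(x) standardGeneric("frameTag"))

#' @rdname frameTag
#' @export
setMethod("frameTag", "ColoredPointCloud", function(x) x@frame)

#' Subset a point cloud by point index
#' @param x a [ColoredPointCloud-class].
#' @param i index vector (integer or logical).
#' @param j,...,drop ignored.
#' @return The subset [ColoredPointCloud-class].
#' @export
setMethod("[", "ColoredPointCloud", function(x, i, j, ..., drop = FALSE) {
  pointCloud(x@points[i, , drop = FALSE], x@colors[i, , drop = FALSE],
             frame = x@frame)
})

setMethod("show", "ColoredPointCloud", function(object) {
  cat(sprintf("ColoredPointCloud: %d points [%s frame]\n",
              nrow(object@points), object@frame))
  if (nrow(object@points)) {
    rng <- apply(object@points, 2, range)
    cat(sprintf("  x: [%.4f, %.4f]  y: [%.4f, %.4f]  z: [%.4f, %.4f] m\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3],
                rng[2, 3]))
  }
  invisible(object)
})

#' Vertices of a mesh
#' @param x a [TriangleMesh-class].
#' @return n x 3 numeric matrix (m).
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname meshVertices
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' Triangles of a mesh
#' @param x a [TriangleMesh-class].
#' @return m x 3 integer matrix of 1-based vertex indices.
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))

#' @rdname meshTriangles
#' @export
setMethod("meshTriangles", "TriangleMesh", function(x) x@triangles)

#' Number of triangles in a mesh
#' @param x a [TriangleMesh-class].
#' @return integer triangle count.
#' @export
setGeneric("nTriangles", function(x) standardGeneric("nTriangles"))

#' @rdname nTriangles
#' @export
setMethod("nTriangles", "TriangleMesh", function(x) nrow(x@triangles))

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d triangles\n",
              nrow(object@vertices), nrow(object@triangles)))
  invisible(object)
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(signif(object@translation, 6), collapse = " "),
      "\n")
  invisible(object)
})

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet: view %d/%d (%.1f deg), %d markers\n",
              object@viewIndex, object@nViews, object@nominalAngle,
              nrow(object@markers)))
  invisible(object)
})

setMethod("show", "PotConeModel", function(object) {
  cat(sprintf(
    "PotConeModel: r1 = %.4f m, r2 = %.4f m, apex z = %.4f m, ra = %.4f m\n",
    object@r1, object@r2, object@apex[3], object@ra))
  invisible(object)
})

setMethod("show", "GrowthReport", function(object) {
  cat("GrowthReport\n")
  cat(sprintf("  relative height        h_R  = %8.2f cm\n", object@hR))
  if (is.finite(object@hAS))
    cat(sprintf("  absolute height (soil) h_AS = %8.2f cm (%d soil points)\n",
                object@hAS, object@soilPointsUsed))
  else
    cat(sprintf("  absolute height (soil) h_AS =       NA (%d soil points)\n",
                object@soilPointsUsed))
  cat(sprintf("  absolute height (base) h_AP = %8.2f cm\n", object@hAP))
  cat(sprintf("  total leaf area             = %8.2f cm^2\n",
              object@totalLeafArea))
  cat(sprintf("  projected leaf area    S_PA = %8.2f cm^2\n",
              object@projectedLeafArea))
  cat(sprintf("  volume                 V    = %8.2f cm^3\n", object@volume))
  if (length(object@calibrated)) {
    cat("  calibrated estimates:\n")
    for (nm in names(object@calibrated))
      cat(sprintf("    %-24s %10.3f\n", nm, object@calibrated[[nm]]))
  }
  invisible(object)
})
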