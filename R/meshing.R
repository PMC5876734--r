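# Surface meshing of the denoised plant cloud: centroid down-sampling,
# empty-ball triangulation bounded by a maximum edge length, defect
# filters (duplicates, suspended and non-manifold triangles, triangles
# nearly perpendicular to the surface), small-component removal,
# three-edge hole filling, and boundary smoothing.

#' Centroid down-sampling to a minimum point spacing
#'
#' Repeatedly merges neighboring points (each output point is the centroid
#' of the inputs merged into it) until every pairwise distance is at least
#' `pointSpacing`.  Points are processed in index order and merge into the
#' earliest kept point, so the result is deterministic.
#'
#' @param cloud a [ColoredPointCloud-class].
#' @param pointSpacing minimum output spacing (m), default 0.002.
#' @return The down-sampled [ColoredPointCloud-class] (colors averaged).
#' @export
downsampleCloud <- function(cloud, pointSpacing = 0.002) {
  stopifnot(pointSpacing > 0)
  if (nPoints(cloud) == 0L) return(cloud)
  res <- cpp_downsample(cloud@points, cloud@colors, pointSpacing)
  pointCloud(res$points, pmin(pmax(res$colors, 0), 1), frame = cloud@frame)
}

#' Empty-ball triangulation
#'
#' Emits every triangle (from k-nearest-neighbor candidates) whose minimum
#' enclosing ball contains no other point strictly inside (points exactly
#' on the ball are tolerated) and whose edges are all shorter than
#' `triEdgeLength`, so discontinuous surfaces are not connected.
#'
#' @param cloud a [ColoredPointCloud-class] (ideally down-sampled); at
#'   least 3 points for a non-empty result.
#' @param triEdgeLength maximum triangle edge (m), default 0.008.
#' @param k neighborhood size for candidate generation, default 16.
#' @return A [TriangleMesh-class] (possibly empty).
#' @export
triangulateCloud <- function(cloud, triEdgeLength = 0.008, k = 16L) {
  stopifnot(triEdgeLength > 0)
  if (nPoints(cloud) < 3L)
    return(triangleMesh(cloud@points, matrix(integer(0), 0, 3)))
  tri <- cpp_triangulate(cloud@points, triEdgeLength, as.integer(k))
  triangleMesh(cloud@points, tri)
}

# per-triangle areas (m^2)
.tri_areas <- function(vertices, triangles) {
  if (nrow(triangles) == 0L) return(numeric(0))
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# unit face normals
.tri_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  cr / pmax(sqrt(rowSums(cr^2)), 1e-300)
}

# edge table: one row per triangle edge with a canonical numeric key
.edge_table <- function(triangles, nv) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)],
             triangles[, c(3, 1)])
  tri_id <- rep(seq_len(nrow(triangles)), 3L)
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- (lo - 1) * as.numeric(nv) + hi  # exact for nv < 2^26
  list(key = key, tri = tri_id, lo = lo, hi = hi)
}

#' Filter abnormal triangles
#'
#' Four defect filters applied in order: (i) redundant paired triangles
#' (duplicate unordered vertex triples) reduced to one copy; (ii)
#' suspended triangles (sharing no edge with any other) removed; (iii) for
#' non-manifold edges shared by three or more triangles, the two with the
#' most consistent dihedral (most nearly parallel planes) are kept and the
#' rest removed; (iv) triangles whose face normal deviates more than
#' `perpAngleDeg` from the mean normal of their vertices removed.
#'
#' @param mesh a [TriangleMesh-class].
#' @param normals per-vertex unit normals (n x 3); rows may be NaN.
#' @param perpAngleDeg perpendicularity threshold in degrees, default 70.
#' @return The filtered [TriangleMesh-class] (vertices unchanged).
#' @export
filterTriangles <- function(mesh, normals, perpAngleDeg = 70) {
  tr <- mesh@triangles
  v <- mesh@vertices
  if (nrow(tr) == 0L) return(mesh)
  nv <- nrow(v)
  # (i) duplicates
  sorted <- t(apply(tr, 1, sort))
  key <- (as.numeric(sorted[, 1]) * nv + sorted[, 2]) * nv + sorted[, 3]
  tr <- tr[!duplicated(key), , drop = FALSE]
  # (ii) suspended triangles
  et <- .edge_table(tr, nv)
  cnt <- table(et$key)
  shared <- as.numeric(names(cnt)[cnt >= 2L])
  has_shared <- tapply(et$key %in% shared, et$tri, any)
  tr <- tr[as.logical(has_shared), , drop = FALSE]
  # (iii) non-manifold edges: keep the two most coplanar triangles
  if (nrow(tr)) {
    et <- .edge_table(tr, nv)
    fn <- .tri_normals(v, tr)
    cnt <- table(et$key)
    bad_keys <- as.numeric(names(cnt)[cnt >= 3L])
    drop <- logical(nrow(tr))
    for (bk in bad_keys) {
      tris <- et$tri[et$key == bk]
      tris <- tris[!drop[tris]]
      if (length(tris) <= 2L) next
      best <- c(NA, NA); bestd <- -Inf
      for (a in seq_len(length(tris) - 1L))
        for (b in seq(a + 1L, length(tris))) {
          d <- abs(sum(fn[tris[a], ] * fn[tris[b], ]))
          if (d > bestd) { bestd <- d; best <- c(tris[a], tris[b]) }
        }
      drop[setdiff(tris, best)] <- TRUE
    }
    tr <- tr[!drop, , drop = FALSE]
  }
  # (iv) triangles nearly perpendicular to the local surface
  if (nrow(tr)) {
    fn <- .tri_normals(v, tr)
    vn <- normals
    vn[!is.finite(vn)] <- 0
    # sign-align vertex normals within each triangle before averaging
    n1 <- vn[tr[, 1], , drop = FALSE]
    n2 <- vn[tr[, 2], , drop = FALSE]
    n3 <- vn[tr[, 3], , drop = FALSE]
    s2 <- sign(rowSums(n1 * n2)); s2[s2 == 0] <- 1
    s3 <- sign(rowSums(n1 * n3)); s3[s3 == 0] <- 1
    mn <- n1 + n2 * s2 + n3 * s3
    L <- sqrt(rowSums(mn^2))
    ok <- L > 1e-9
    cosang <- abs(rowSums(fn * mn) / pmax(L, 1e-300))
    keep <- !ok | cosang >= cos(perpAngleDeg * pi / 180)
    tr <- tr[keep, , drop = FALSE]
  }
  triangleMesh(v, tr)
}

# connected components over edge adjacency; returns component id per triangle
.tri_components <- function(triangles, nv) {
  nt <- nrow(triangles)
  if (nt == 0L) return(integer(0))
  et <- .edge_table(triangles, nv)
  ord <- order(et$key)
  key <- et$key[ord]; tri <- et$tri[ord]
  parent <- seq_len(nt)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$lengths >= 2L)) {
    ids <- tri[starts[r]:ends[r]]
    root <- find(ids[1])
    for (t in ids[-1]) {
      rt <- find(t)
      if (rt != root) parent[rt] <- root
    }
  }
  vapply(seq_len(nt), find, integer(1))
}

#' Remove small mesh components
#'
#' Drops connected components (edge adjacency) whose summed triangle area
#' is below `minArea`.
#'
#' @param mesh a [TriangleMesh-class].
#' @param minArea minimum component area (m^2), default 1e-4 (1 cm^2).
#' @return The filtered [TriangleMesh-class].
#' @export
removeSmallComponents <- function(mesh, minArea = 1e-4) {
  stopifnot(minArea >= 0)
  tr <- mesh@triangles
  if (nrow(tr) == 0L || minArea == 0) return(mesh)
  comp <- .tri_components(tr, nrow(mesh@vertices))
  areas <- .tri_areas(mesh@vertices, tr)
  comp_area <- tapply(areas, comp, sum)
  keep_comp <- as.numeric(names(comp_area)[comp_area >= minArea])
  triangleMesh(mesh@vertices, tr[comp %in% keep_comp, , drop = FALSE])
}

#' Fill three-edge holes
#'
#' Closes every boundary loop of exactly three edges with one triangle;
#' larger holes are left untouched.
#'
#' @param mesh a [TriangleMesh-class].
#' @return The [TriangleMesh-class] with three-edge holes closed.
#' @export
fillTriHoles <- function(mesh) {
  tr <- mesh@triangles
  if (nrow(tr) == 0L) return(mesh)
  nv <- nrow(mesh@vertices)
  et <- .edge_table(tr, nv)
  cnt <- table(et$key)
  bkeys <- as.numeric(names(cnt)[cnt == 1L])
  if (!length(bkeys)) return(mesh)
  sel <- match(bkeys, et$key)
  blo <- et$lo[sel]; bhi <- et$hi[sel]
  # adjacency among boundary vertices via boundary edges
  bset <- paste(blo, bhi)
  existing <- {
    s <- t(apply(tr, 1, sort))
    paste(s[, 1], s[, 2], s[, 3])
  }
  adj <- split(c(bhi, blo), c(blo, bhi))
  new_tris <- list()
  seen <- character(0)
  for (e in seq_along(blo)) {
    a <- blo[e]; b <- bhi[e]
    cands <- intersect(adj[[as.character(a)]], adj[[as.character(b)]])
    for (cc in cands) {
      tripl <- sort(c(a, b, cc))
      keyc <- paste(tripl[1], tripl[2], tripl[3])
      if (keyc %in% seen || keyc %in% existing) next
      seen <- c(seen, keyc)
      new_tris[[length(new_tris) + 1L]] <- tripl
    }
  }
  if (!length(new_tris)) return(mesh)
  triangleMesh(mesh@vertices, rbind(tr, do.call(rbind, new_tris)))
}

#' Smooth jagged mesh boundaries
#'
#' Boundary vertices (on edges used by exactly one triangle) are moved to
#' the Gaussian-weighted average (sigma = radius / 2) of the boundary
#' vertices within arc-length `radius` along their boundary loop, which
#' flattens the jagged edges left by boundary noise while leaving straight
#' boundaries in place.  Interior vertices within `radius` of a moved
#' boundary vertex follow with the distance-weighted average of the nearby
#' boundary displacements; all other vertices and the connectivity are
#' unchanged.
#'
#' @param mesh a [TriangleMesh-class].
#' @param radius smoothing range (m), default 0.015.
#' @return The smoothed [TriangleMesh-class].
#' @export
smoothBoundary <- function(mesh, radius = 0.015) {
  stopifnot(radius > 0)
  tr <- mesh@triangles
  v <- mesh@vertices
  if (nrow(tr) == 0L) return(mesh)
  nv <- nrow(v)
  et <- .edge_table(tr, nv)
  cnt <- table(et$key)
  bkeys <- as.numeric(names(cnt)[cnt == 1L])
  if (!length(bkeys)) return(mesh)  # closed mesh
  sel <- match(bkeys, et$key)
  blo <- et$lo[sel]; bhi <- et$hi[sel]
  bverts <- sort(unique(c(blo, bhi)))
  nbr <- split(c(bhi, blo), c(blo, bhi))
  deg <- lengths(nbr)[as.character(bverts)]
  # walk boundary loops (only through degree-2 vertices)
  visited <- setNames(rep(FALSE, length(bverts)), bverts)
  newv <- v
  sigma <- radius / 2
  for (start in bverts[deg == 2L]) {
    if (visited[as.character(start)]) next
    loop <- c(start)
    visited[as.character(start)] <- TRUE
    prev <- start
    cur <- nbr[[as.character(start)]][1]
    closed <- TRUE
    while (cur != start) {
      if (length(nbr[[as.character(cur)]]) != 2L) { closed <- FALSE; break }
      loop <- c(loop, cur)
      visited[as.character(cur)] <- TRUE
      nxt <- setdiff(nbr[[as.character(cur)]], prev)[1]
      prev <- cur
      cur <- nxt
      if (is.na(cur)) { closed <- FALSE; break }
    }
    if (!closed || length(loop) < 3L) next
    m <- length(loop)
    pos <- v[loop, , drop = FALSE]
    seg <- sqrt(rowSums((pos - pos[c(2:m, 1), , drop = FALSE])^2))
    # arc-length positions around the loop
    arc <- cumsum(c(0, seg[-m]))
    total <- sum(seg)
    for (i in seq_len(m)) {
      darc <- abs(arc - arc[i])
      darc <- pmin(darc, total - darc)  # around the loop both ways
      w <- exp(-darc^2 / (2 * sigma^2))
      w[darc > radius] <- 0
      newv[loop[i], ] <- colSums(pos * w) / sum(w)
    }
  }
  # interior vertices near the boundary follow the boundary displacement
  disp <- newv - v
  moved <- which(rowSums(abs(disp)) > 0)
  if (length(moved)) {
    interior <- setdiff(seq_len(nv), bverts)
    if (length(interior)) {
      nb <- cpp_radius_neighbors(v[moved, , drop = FALSE],
                                 v[interior, , drop = FALSE], radius)
      for (ii in seq_along(interior)) {
        idx <- nb[[ii]]
        if (!length(idx)) next
        d <- sqrt(colSums((t(v[moved[idx], , drop = FALSE]) -
                             v[interior[ii], ])^2))
        w <- exp(-d^2 / (2 * sigma^2))
        newv[interior[ii], ] <- v[interior[ii], ] +
          colSums(disp[moved[idx], , drop = FALSE] * w) / sum(w)
      }
    }
  }
  triangleMesh(newv, tr)
}

#' Full meshing pipeline
#'
#' Down-sampling, empty-ball triangulation, the four defect filters, small
#' component removal, three-edge hole filling and boundary smoothing, in
#' that order.
#'
#' @param cloud the denoised plant [ColoredPointCloud-class].
#' @param config a [PipelineConfig-class].
#' @return A [TriangleMesh-class] of the visible leaf surfaces.
#' @export
meshPipeline <- function(cloud, config = pipelineConfig()) {
  ds <- downsampleCloud(cloud, config@pointSpacing)
  mesh <- triangulateCloud(ds, config@triEdgeLength)
  normals <- estimateNormals(ds, max(3 * config@pointSpacing,
                                     config@normalRadius))
  mesh <- filterTriangles(mesh, normals, config@perpAngleDeg)
  mesh <- removeSmallComponents(mesh, config@minComponentArea)
  mesh <- fillTriHoles(mesh)
  smoothBoundary(mesh, config@boundarySmoothR)
}
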