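# Independent oracles used across the suite.  These deliberately avoid the
# compiled code paths they are checking.

# brute-force radius neighbors: indices within radius of `query`,
# ascending distance, ties by index
bruteNeighbors <- function(points, query, radius) {
  d <- sqrt(colSums((t(points) - query)^2))
  idx <- which(d <= radius)
  idx[order(d[idx], idx)]
}

# brute-force neighbor counts (excluding self)
bruteNeighborCounts <- function(points, radius) {
  n <- nrow(points)
  vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(points) - points[i, ])^2))
    sum(d <= radius) - 1L
  }, integer(1))
}

# x-interval of a 2D triangle cut by the horizontal line y = y0
.triXInterval <- function(tri, y0) {
  xs <- c()
  for (e in 1:3) {
    p <- tri[e, ]; q <- tri[e %% 3 + 1, ]
    if ((p[2] - y0) * (q[2] - y0) <= 0 && p[2] != q[2]) {
      t <- (y0 - p[2]) / (q[2] - p[2])
      xs <- c(xs, p[1] + t * (q[1] - p[1]))
    }
  }
  if (length(xs) < 2) return(NULL)
  range(xs)
}

# exact area of the union of 2D triangles by strip decomposition:
# between consecutive event ordinates (vertices and edge crossings) the
# union's x-extent varies linearly, so the mid-strip extent is exact
polyUnionArea <- function(tris) {
  ys <- c()
  for (t in seq_along(tris)) ys <- c(ys, tris[[t]][, 2])
  # pairwise edge intersections contribute event ordinates
  edges <- do.call(rbind, lapply(tris, function(tr) {
    cbind(tr, tr[c(2, 3, 1), ])
  }))
  ne <- nrow(edges)
  for (i in seq_len(ne - 1)) for (j in seq(i + 1, ne)) {
    p1 <- edges[i, 1:2]; p2 <- edges[i, 3:4]
    q1 <- edges[j, 1:2]; q2 <- edges[j, 3:4]
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-15) next
    t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    if (t >= 0 && t <= 1 && u >= 0 && u <= 1)
      ys <- c(ys, p1[2] + t * d1[2])
  }
  ys <- sort(unique(ys))
  total <- 0
  for (s in seq_len(length(ys) - 1)) {
    y0 <- ys[s]; y1 <- ys[s + 1]
    if (y1 - y0 < 1e-14) next
    ym <- (y0 + y1) / 2
    ints <- list()
    for (tr in tris) {
      iv <- .triXInterval(tr, ym)
      if (!is.null(iv)) ints[[length(ints) + 1]] <- iv
    }
    if (!length(ints)) next
    m <- do.call(rbind, ints)
    m <- m[order(m[, 1]), , drop = FALSE]
    len <- 0; curL <- m[1, 1]; curR <- m[1, 2]
    if (nrow(m) > 1) for (k in 2:nrow(m)) {
      if (m[k, 1] <= curR) curR <- max(curR, m[k, 2])
      else { len <- len + curR - curL; curL <- m[k, 1]; curR <- m[k, 2] }
    }
    len <- len + curR - curL
    total <- total + len * (y1 - y0)
  }
  total
}

# Monte-Carlo volume of a union of tetrahedra
mcUnionVolume <- function(verts, tets, nSamples = 1e6, seed = 1) {
  set.seed(seed)
  lo <- apply(verts, 2, min); hi <- apply(verts, 2, max)
  S <- cbind(runif(nSamples, lo[1], hi[1]), runif(nSamples, lo[2], hi[2]),
             runif(nSamples, lo[3], hi[3]))
  inside <- rep(FALSE, nSamples)
  for (t in seq_len(nrow(tets))) {
    A <- verts[tets[t, 1], ]; B <- verts[tets[t, 2], ]
    C <- verts[tets[t, 3], ]; D <- verts[tets[t, 4], ]
    M <- cbind(B - A, C - A, D - A)
    bc <- t(solve(M, t(S) - A))
    hit <- bc[, 1] >= -1e-12 & bc[, 2] >= -1e-12 & bc[, 3] >= -1e-12 &
      rowSums(bc) <= 1 + 1e-12
    inside <- inside | hit
  }
  p <- mean(inside)
  vbox <- prod(hi - lo)
  list(volume = p * vbox, sd = vbox * sqrt(p * (1 - p) / nSamples))
}

# planar strip mesh: 3 rows of vertices, triangulated; returns TriangleMesh
stripMesh <- function(nx = 26, dx = 0.004, zigzag = 0) {
  xs <- seq(0, by = dx, length.out = nx)
  rows <- list(cbind(xs, 0, 0), cbind(xs, dx, 0), cbind(xs, 2 * dx, 0))
  v <- do.call(rbind, rows)
  if (zigzag > 0)   # jagged bottom boundary
    v[seq_len(nx), 2] <- v[seq_len(nx), 2] + zigzag * rep_len(c(-1, 1), nx)
  tris <- list()
  for (r in 0:1) for (i in seq_len(nx - 1)) {
    a <- r * nx + i; b <- a + 1; c <- a + nx; d <- a + nx + 1
    tris[[length(tris) + 1]] <- c(a, b, d)
    tris[[length(tris) + 1]] <- c(a, d, c)
  }
  triangleMesh(v, do.call(rbind, tris))
}
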