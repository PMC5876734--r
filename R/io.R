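# Point-cloud and mesh file I/O.  PLY is the canonical format (ASCII and
# binary-little-endian, properties x y z [red green blue]); PCD v0.7 ASCII
# is supported read-only.  Colors are stored as uchar 0..255 in files and
# mapped to [0, 1] in memory.

.read_lines_until <- function(con, sentinel, max = 1000L) {
  out <- character(0)
  for (i in seq_len(max)) {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unexpected end of header")
    out <- c(out, ln)
    if (grepl(sentinel, ln)) return(out)
  }
  stop("header sentinel '", sentinel, "' not found")
}

#' Read a colored point cloud from PLY or PCD
#'
#' Supports ASCII and binary-little-endian PLY with vertex properties
#' `x y z` and optional `red green blue` (uchar), and PCD v0.7 ASCII with
#' `x y z` and optional packed-float `rgb`.  Colors default to black when
#' the file carries none; the point count is preserved exactly.
#'
#' @param path file path; format is chosen by extension (`.ply` / `.pcd`).
#' @param frame frame tag to assign, default `"turntable"`.
#' @return A [ColoredPointCloud-class].
#' @export
readPointCloud <- function(path, frame = "turntable") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pcd") return(.read_pcd(path, frame))
  .read_ply_cloud(path, frame)
}

.read_ply_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) stop("malformed PLY: missing 'ply' magic line")
  hdr <- .read_lines_until(con, "^end_header")
  fmt_ln <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt_ln)) stop("malformed PLY: no 'format' line")
  fmt <- strsplit(fmt_ln[1], "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  elements <- list()
  cur <- NULL
  for (ln in hdr) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(0), types = character(0),
                  list_prop = logical(0))
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props <- c(cur$props, tok[5])
        cur$types <- c(cur$types, paste(tok[3], tok[4]))
        cur$list_prop <- c(cur$list_prop, TRUE)
      } else {
        cur$props <- c(cur$props, tok[3])
        cur$types <- c(cur$types, tok[2])
        cur$list_prop <- c(cur$list_prop, FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(format = fmt, elements = elements)
}

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.read_ply_cloud <- function(path, frame) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .read_ply_header(con)
  vert <- hdr$elements[["vertex"]]
  if (is.null(vert)) stop("malformed PLY: no 'vertex' element")
  if (any(vert$list_prop)) stop("list properties on vertex are unsupported")
  need <- c("x", "y", "z")
  if (!all(need %in% vert$props))
    stop("malformed PLY: vertex element lacks x/y/z properties")
  n <- vert$count
  np <- length(vert$props)
  if (hdr$format == "ascii") {
    if (n == 0L) {
      vals <- matrix(numeric(0), 0, np)
    } else {
      txt <- readLines(con, n = n)
      if (length(txt) < n) stop("malformed PLY: fewer vertex rows than declared")
      vals <- matrix(scan(text = txt, quiet = TRUE), nrow = n, ncol = np,
                     byrow = TRUE)
    }
  } else {
    vals <- matrix(0, n, np)
    sizes <- .ply_type_size[vert$types]
    if (anyNA(sizes)) stop("unknown PLY property type on vertex element")
    if (n > 0L) {
      raw <- readBin(con, "raw", n = n * sum(sizes))
      if (length(raw) < n * sum(sizes))
        stop("malformed PLY: truncated binary vertex data")
      offs <- cumsum(c(0L, sizes))[seq_len(np)]
      row_sz <- sum(sizes)
      for (p in seq_len(np)) {
        ty <- vert$types[p]
        idx <- as.vector(outer(seq_len(sizes[p]),
                               (seq_len(n) - 1L) * row_sz + offs[p], `+`))
        bytes <- raw[idx]
        vals[, p] <- switch(ty,
          float = , float32 = readBin(bytes, "double", n = n, size = 4L,
                                      endian = "little"),
          double = , float64 = readBin(bytes, "double", n = n, size = 8L,
                                       endian = "little"),
          uchar = , uint8 = as.numeric(readBin(bytes, "integer", n = n,
                                               size = 1L, signed = FALSE)),
          char = , int8 = as.numeric(readBin(bytes, "integer", n = n,
                                             size = 1L, signed = TRUE)),
          ushort = , uint16 = as.numeric(readBin(bytes, "integer", n = n,
                                                 size = 2L, signed = FALSE,
                                                 endian = "little")),
          short = , int16 = as.numeric(readBin(bytes, "integer", n = n,
                                               size = 2L, signed = TRUE,
                                               endian = "little")),
          int = , int32 = , uint = , uint32 =
            as.numeric(readBin(bytes, "integer", n = n, size = 4L,
                               endian = "little")),
          stop("unknown PLY property type: ", ty))
      }
    }
  }
  colnames(vals) <- vert$props
  pts <- vals[, need, drop = FALSE]
  if (all(c("red", "green", "blue") %in% vert$props)) {
    cols <- vals[, c("red", "green", "blue"), drop = FALSE]
    ctypes <- vert$types[match(c("red", "green", "blue"), vert$props)]
    if (any(ctypes %in% c("uchar", "uint8", "char", "int8")))
      cols <- cols / 255
  } else {
    cols <- matrix(0, n, 3)
  }
  pointCloud(pts, pmin(pmax(cols, 0), 1), frame = frame)
}

.read_pcd <- function(path, frame) {
  lines <- readLines(path, warn = FALSE)
  hend <- grep("^DATA\\b", lines)
  if (!length(hend)) stop("malformed PCD: no DATA line")
  hend <- hend[1]
  hdr <- lines[seq_len(hend)]
  get <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    strsplit(trimws(ln[1]), "\\s+")[[1]][-1]
  }
  if (!identical(get("DATA"), "ascii"))
    stop("only ASCII PCD files are supported")
  fields <- get("FIELDS")
  if (is.null(fields) || !all(c("x", "y", "z") %in% fields))
    stop("malformed PCD: FIELDS must include x y z")
  n <- as.integer(get("POINTS")[1])
  body <- lines[-seq_len(hend)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) stop("malformed PCD: fewer data rows than POINTS")
  vals <- matrix(scan(text = body[seq_len(max(n, 0L))], quiet = TRUE),
                 nrow = max(n, 0L), ncol = length(fields), byrow = TRUE)
  colnames(vals) <- fields
  pts <- vals[, c("x", "y", "z"), drop = FALSE]
  if ("rgb" %in% fields && n > 0L) {
    # PCL packs RGB as a float whose bit pattern is 0x00RRGGBB
    packed <- vals[, "rgb"]
    ints <- readBin(writeBin(as.numeric(packed), raw(), size = 4L,
                             endian = "little"),
                    "integer", n = n, size = 4L, endian = "little")
    cols <- cbind(bitwAnd(bitwShiftR(ints, 16L), 255L),
                  bitwAnd(bitwShiftR(ints, 8L), 255L),
                  bitwAnd(ints, 255L)) / 255
  } else {
    cols <- matrix(0, max(n, 0L), 3)
  }
  pointCloud(pts, cols, frame = frame)
}

#' Write a colored point cloud to PLY
#'
#' @param cloud a [ColoredPointCloud-class]; colors must already lie in
#'   \[0, 1\] (enforced by the class validity).
#' @param path output path.
#' @param binary write binary-little-endian PLY (default ASCII, which
#'   round-trips bit-exactly through [readPointCloud()] for the coordinate
#'   precision written).
#' @return `path`, invisibly.
#' @export
writePointCloud <- function(cloud, path, binary = FALSE) {
  stopifnot(is(cloud, "ColoredPointCloud"))
  validObject(cloud)
  n <- nPoints(cloud)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  ctype <- if (binary) "float" else "double"  # ascii keeps full precision
  hdr <- c("ply", paste("format", fmt, "1.0"),
           paste("element vertex", n),
           paste("property", ctype, c("x", "y", "z")),
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  cols <- round(cloud@colors * 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n == 0L) return(invisible(path))
  if (binary) {
    row_raw <- lapply(seq_len(n), function(i) {
      c(writeBin(as.numeric(cloud@points[i, ]), raw(), size = 4L,
                 endian = "little"),
        writeBin(as.integer(cols[i, ]), raw(), size = 1L))
    })
    writeBin(do.call(c, row_raw), con)
  } else {
    txt <- sprintf("%.17g %.17g %.17g %d %d %d",
                   cloud@points[, 1], cloud@points[, 2], cloud@points[, 3],
                   cols[, 1], cols[, 2], cols[, 3])
    writeLines(txt, con)
  }
  invisible(path)
}

#' Write a triangle mesh to PLY or OBJ
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path) {
  stopifnot(is(mesh, "TriangleMesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh@vertices; tr <- mesh@triangles
  if (ext == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]))
    writeLines(lines, path)
  } else {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property float x", "property float y", "property float z",
             paste("element face", nrow(tr)),
             "property list uchar int vertex_indices", "end_header")
    lines <- c(hdr, sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                       tr[, 3] - 1L))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a triangle mesh from ASCII PLY
#' @param path file path.
#' @return A [TriangleMesh-class].
#' @export
readMesh <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .read_ply_header(con)
  if (hdr$format != "ascii") stop("only ASCII PLY meshes are supported")
  vert <- hdr$elements[["vertex"]]
  face <- hdr$elements[["face"]]
  if (is.null(vert) || is.null(face)) stop("malformed PLY mesh")
  vtxt <- readLines(con, n = vert$count)
  v <- matrix(scan(text = vtxt, quiet = TRUE), nrow = vert$count,
              byrow = TRUE)[, 1:3, drop = FALSE]
  ftxt <- readLines(con, n = face$count)
  f <- matrix(scan(text = ftxt, quiet = TRUE), nrow = face$count,
              byrow = TRUE)
  if (nrow(f) && any(f[, 1] != 3)) stop("only triangular faces are supported")
  triangleMesh(v, f[, 2:4, drop = FALSE] + 1L)
}

#' Read a plain-text markers file
#'
#' One row per marker: `view_index angle_deg x y z`.
#'
#' @param path file path.
#' @param nViews number of views; defaults to `max(view_index) + 1`.
#' @return List of [MarkerSet-class], ordered by view index.
#' @export
readMarkers <- function(path, nViews = NULL) {
  if (!file.exists(path)) stop("markers file not found: ", path)
  m <- as.matrix(read.table(path, col.names = c("view", "angle", "x", "y",
                                                "z")))
  if (is.null(nViews)) nViews <- max(m[, 1]) + 1L
  lapply(sort(unique(m[, 1])), function(v) {
    rows <- m[m[, 1] == v, , drop = FALSE]
    markerSet(as.integer(v), as.integer(nViews), rows[, 3:5, drop = FALSE])
  })
}

#' Write marker sets to a plain-text file
#' @param markerSets list of [MarkerSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMarkers <- function(markerSets, path) {
  rows <- do.call(rbind, lapply(markerSets, function(ms) {
    cbind(ms@viewIndex, ms@nominalAngle, ms@markers)
  }))
  write.table(rows, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Radius neighbor query
#'
#' Exact indices of all cloud points within `radius` of a query point, in
#' deterministic ascending-distance order (ties broken by index).
#'
#' @param cloud a [ColoredPointCloud-class].
#' @param query length-3 numeric point, or an m x 3 matrix of query points.
#' @param radius search radius (m), > 0.
#' @return Integer vector of indices (single query) or a list of them.
#' @examples
#' pc <- pointCloud(matrix(runif(300), 100, 3))
#' nearestNeighbors(pc, c(0.5, 0.5, 0.5), 0.2)
#' @export
nearestNeighbors <- function(cloud, query, radius) {
  stopifnot(radius > 0)
  q <- if (is.matrix(query)) query else matrix(query, 1, 3)
  storage.mode(q) <- "double"
  res <- cpp_radius_neighbors(cloud@points, q, radius)
  if (!is.matrix(query)) res[[1]] else res
}

#' @importFrom utils read.table write.table
NULL
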