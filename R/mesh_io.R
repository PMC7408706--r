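#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Supports binary and ASCII STL, ASCII PLY (x, y, z as the first three vertex
#' properties), and OBJ geometry (materials, normals and textures ignored;
#' polygonal faces are fan-triangulated). Coordinates are taken to be in mm.
#' The result is validated: duplicate vertices merged, degenerate faces
#' dropped (with a warning), indices checked.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`, or `NULL` to infer from the
#'   file extension.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read mesh: file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "ply", "obj"))
  m <- switch(format,
              stl = read_stl(path),
              ply = read_ply(path),
              obj = read_obj(path))
  triangle_mesh(m$vertices, m$faces,
                name = tools::file_path_sans_ext(basename(path)))
}

stl_is_binary <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  # a well-formed binary STL has size exactly 84 + 50 * ntriangles
  !is.na(n) && n >= 0 && sz == 84 + 50 * as.double(n)
}

read_stl <- function(path) {
  if (stl_is_binary(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    body <- readBin(con, "raw", 50 * n)
    # each record: 12 float32 (normal + 3 vertices) + uint16 attribute
    off <- rep((0:(n - 1)) * 50, each = 48) + rep(0:47, times = n)
    fl <- readBin(body[off + 1], "double", n = 12 * n, size = 4,
                  endian = "little")
    rec <- matrix(fl, ncol = 12, byrow = TRUE)
    v <- rbind(rec[, 4:6, drop = FALSE], rec[, 7:9, drop = FALSE],
               rec[, 10:12, drop = FALSE])
    # interleave back to per-face order
    v <- v[as.vector(t(matrix(seq_len(3 * n), ncol = 3))), , drop = FALSE]
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("cannot parse ASCII STL: ", path)
    nums <- scan(text = sub("^\\s*vertex\\s+", "", vl), quiet = TRUE)
    v <- matrix(nums, ncol = 3, byrow = TRUE)
  }
  nf <- nrow(v) / 3
  list(vertices = v,
       faces = matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY header not terminated: ", path)
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex\\s", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face\\s", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY header missing elements: ", path)
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vl <- body[seq_len(nv)]
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[1:3])))
  fl <- body[nv + seq_len(nf)]
  faces <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    k <- as.integer(x[1])
    idx <- as.integer(x[2:(1 + k)]) + 1L  # PLY is 0-based
    if (k == 3) matrix(idx, 1) else
      cbind(idx[1], idx[2:(k - 1)], idx[3:k])  # fan triangulation
  })
  list(vertices = v, faces = do.call(rbind, faces))
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0) stop("cannot parse OBJ: ", path)
  v <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vl), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- lapply(strsplit(sub("^f\\s+", "", fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*$", "", x))  # drop texture/normal refs
    idx[idx < 0] <- nrow(v) + 1L + idx[idx < 0]
    k <- length(idx)
    if (k == 3) matrix(idx, 1) else
      cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  })
  list(vertices = v, faces = do.call(rbind, faces))
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' Binary STL stores float32 coordinates; ASCII formats are written with 10
#' significant digits. A file written here is re-readable by [read_mesh()]
#' with vertex coordinates preserved to 1e-6 mm (for coordinates within
#' +/- 32 mm in the float32 case).
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @param format `"stl"` (binary), `"stl_ascii"`, `"ply"`, or `"obj"`;
#'   `NULL` infers binary STL / PLY / OBJ from the extension.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  if (nrow(mesh$faces) == 0) stop("refusing to write an empty mesh")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "stl_ascii", "ply", "obj"))
  switch(format,
         stl = write_stl_binary(mesh, path),
         stl_ascii = write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path))
  invisible(path)
}

stl_records <- function(mesh) {
  fn <- face_normals(mesh)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cbind(fn, a, b, cc)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  rec <- stl_records(mesh)
  for (i in seq_len(nrow(rec))) {
    writeBin(as.numeric(rec[i, ]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

write_stl_ascii <- function(mesh, path) {
  rec <- stl_records(mesh)
  fmt <- paste0(
    "facet normal %.10g %.10g %.10g\n outer loop\n",
    "  vertex %.10g %.10g %.10g\n  vertex %.10g %.10g %.10g\n",
    "  vertex %.10g %.10g %.10g\n endloop\nendfacet")
  body <- sprintf(fmt, rec[, 1], rec[, 2], rec[, 3], rec[, 4], rec[, 5],
                  rec[, 6], rec[, 7], rec[, 8], rec[, 9], rec[, 10],
                  rec[, 11], rec[, 12])
  writeLines(c(paste("solid", mesh$name), body,
               paste("endsolid", mesh$name)), path)
}

write_ply <- function(mesh, path, scalar = NULL, scalar_name = "quality") {
  nv <- nrow(mesh$vertices)
  props <- c("property float x", "property float y", "property float z")
  if (!is.null(scalar)) props <- c(props, paste("property float", scalar_name))
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nv), props,
              paste("element face", nrow(mesh$faces)),
              "property list uchar int vertex_indices", "end_header")
  vm <- mesh$vertices
  if (!is.null(scalar)) vm <- cbind(vm, scalar)
  vlines <- apply(vm, 1, function(x) paste(sprintf("%.10g", x), collapse = " "))
  flines <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                    mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
  writeLines(c(header, vlines, flines), path)
}

write_obj <- function(mesh, path) {
  vlines <- sprintf("v %.10g %.10g %.10g", mesh$vertices[, 1],
                    mesh$vertices[, 2], mesh$vertices[, 3])
  flines <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                    mesh$faces[, 3])
  writeLines(c(paste("o", mesh$name), vlines, flines), path)
}

#' Trim region
#'
#' An axis-aligned box or an axis-aligned cylinder in reference coordinates,
#' used to cut scan meshes to a uniform extent (the digital counterpart of
#' trimming scans with a fixed template). The predicate is evaluated on face
#' centroids; faces are kept or removed whole, with no re-triangulation.
#'
#' @param type `"box"` or `"cylinder"`.
#' @param lo,hi box corners (mm), for `type = "box"`.
#' @param center,axis,radius,range cylinder centre point, axis direction,
#'   radius (mm) and extent along the axis (mm, length 2), for
#'   `type = "cylinder"`.
#' @param mode `"keep_inside"` or `"keep_outside"`.
#' @export
trim_region <- function(type = c("box", "cylinder"), lo = NULL, hi = NULL,
                        center = NULL, axis = c(0, 0, 1), radius = NULL,
                        range = c(-Inf, Inf),
                        mode = c("keep_inside", "keep_outside")) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  if (type == "box") {
    if (is.null(lo) || is.null(hi)) stop("box region needs lo and hi")
    if (any(hi <= lo)) stop("trim region must have positive volume")
  } else {
    if (is.null(center) || is.null(radius)) stop("cylinder region needs center and radius")
    if (radius <= 0 || diff(range) <= 0) stop("trim region must have positive volume")
  }
  structure(list(type = type, lo = lo, hi = hi, center = center,
                 axis = axis / sqrt(sum(axis^2)), radius = radius,
                 range = range, mode = mode),
            class = "trim_region")
}

region_contains <- function(region, points) {
  if (region$type == "box") {
    inside <- points[, 1] >= region$lo[1] & points[, 1] <= region$hi[1] &
      points[, 2] >= region$lo[2] & points[, 2] <= region$hi[2] &
      points[, 3] >= region$lo[3] & points[, 3] <= region$hi[3]
  } else {
    d <- sweep(points, 2, region$center)
    h <- as.numeric(d %*% region$axis)
    rad <- sqrt(rowSums((d - outer(h, region$axis))^2))
    inside <- rad <= region$radius & h >= region$range[1] & h <= region$range[2]
  }
  if (region$mode == "keep_inside") inside else !inside
}

#' Trim a mesh with a region predicate
#'
#' Keeps the faces whose centroids satisfy the region predicate and drops
#' unused vertices. Trimming is idempotent.
#'
#' @param mesh a [triangle_mesh()].
#' @param region a [trim_region()].
#' @return a trimmed [triangle_mesh()].
#' @export
trim_mesh <- function(mesh, region) {
  if (!inherits(region, "trim_region")) stop("region must be a trim_region")
  keep <- region_contains(region, face_centroids(mesh))
  if (!any(keep)) stop("empty mesh: trim region removed all faces")
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[f], ncol = 3), name = mesh$name)
}
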