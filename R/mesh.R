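#' Triangle mesh container
#'
#' An indexed triangle surface with coordinates in millimetres. This is the
#' carrier both for library files (the manufacturer's exact CAD reference) and
#' for scan meshes. Construction validates the mesh: duplicate vertices are
#' merged (STL stores no vertex sharing, and consistent connectivity is needed
#' for outward normals), degenerate faces are dropped, and face indices are
#' checked.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param name free-text label.
#' @param merge_tol vertices closer than this (mm) are merged. Default 1e-9.
#' @param area_tol faces with area (mm^2) at or below this are dropped.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh",
                          merge_tol = 1e-9, area_tol = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")

  # merge duplicate vertices by coordinate key at merge_tol resolution
  if (nrow(vertices) > 0) {
    key <- paste(round(vertices[, 1] / merge_tol),
                 round(vertices[, 2] / merge_tol),
                 round(vertices[, 3] / merge_tol))
    first <- !duplicated(key)
    remap <- match(key, key[first])
    vertices <- vertices[first, , drop = FALSE]
    if (nrow(faces) > 0) {
      faces <- matrix(remap[faces], ncol = 3L)
      storage.mode(faces) <- "integer"
    }
  }

  if (nrow(faces) > 0) {
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    cc <- vertices[faces[, 3], , drop = FALSE]
    n <- row_cross(b - a, cc - a)
    area <- 0.5 * sqrt(rowSums(n * n))
    bad <- area <= area_tol |
      faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(bad)) {
      warning(sum(bad), " degenerate face(s) dropped")
      faces <- faces[!bad, , drop = FALSE]
    }
  }
  if (nrow(faces) == 0L) stop("empty mesh: no valid faces")

  structure(list(vertices = vertices, faces = faces, name = name),
            class = "triangle_mesh")
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' @exportS3Method base::print
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Per-face unit outward normals, areas and centroids
#'
#' @param mesh a `triangle_mesh`.
#' @return `face_normals`: m x 3 matrix of unit normals (right-hand rule on
#'   the face winding); `face_areas`: length-m vector (mm^2); `face_centroids`:
#'   m x 3 matrix (mm).
#' @export
face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  n <- row_cross(b - a, cc - a)
  n / sqrt(rowSums(n * n))
}

#' @rdname face_normals
#' @export
face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  n <- row_cross(b - a, cc - a)
  0.5 * sqrt(rowSums(n * n))
}

#' @rdname face_normals
#' @export
face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

#' Area-weighted per-vertex unit normals
#'
#' Each vertex normal is the area-weighted average of the normals of its
#' incident faces, renormalised to unit length. Used to displace simulated
#' scan surfaces along the local surface direction.
#'
#' @param mesh a `triangle_mesh`.
#' @return n x 3 matrix of unit vectors.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  ar <- face_areas(mesh)
  w <- fn * ar
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(w[, k], mesh$faces[, j], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      n[idx, k] <- n[idx, k] + acc
    }
  }
  len <- sqrt(rowSums(n * n))
  len[len == 0] <- 1
  n / len
}

#' Closedness and orientation checks
#'
#' A mesh is closed (watertight) when every undirected edge is shared by
#' exactly two faces. `mesh_volume` returns the signed enclosed volume
#' (positive when face windings point outward).
#'
#' @param mesh a `triangle_mesh`.
#' @return `mesh_is_closed`: logical; `mesh_volume`: signed volume in mm^3.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' @rdname mesh_is_closed
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(rowSums(a * row_cross(b, cc))) / 6
}

#' Area-weighted random sampling of surface points
#'
#' Draws points uniformly over the surface: faces are selected with
#' probability proportional to area and points placed by uniform barycentric
#' sampling (square-root trick). Seeded and reproducible; sampling density is
#' therefore independent of tessellation density.
#'
#' @param mesh a `triangle_mesh`.
#' @param n number of points.
#' @param seed integer seed.
#' @return list with `points` (n x 3, mm) and `face` (face index per point).
#' @export
sample_surface <- function(mesh, n, seed = 1L) {
  with_seed(seed, {
    ar <- face_areas(mesh)
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = ar)
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
    u <- 1 - r1
    v <- r1 * (1 - r2)
    w <- r1 * r2
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    list(points = a * u + b * v + cc * w, face = fi)
  })
}
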