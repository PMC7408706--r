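# Small fixture meshes, built in code.

make_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f, name = "tetrahedron")
}

# unit cube surface [0,1]^3, 12 triangles, outward oriented
make_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(
    quad(1, 3, 4, 2),  # z = 0 (down)
    quad(5, 6, 8, 7),  # z = 1 (up)
    quad(1, 2, 6, 5),  # y = 0
    quad(3, 7, 8, 4),  # y = 1
    quad(1, 5, 7, 3),  # x = 0
    quad(2, 4, 8, 6))  # x = 1
  m <- triangle_mesh(v, f, name = "cube")
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# random triangle soup (not closed) for I/O round trips
random_soup <- function(seed, n_faces = 10, scale = 20) {
  set.seed(seed)
  v <- matrix(runif(9 * n_faces, -scale, scale), ncol = 3)
  f <- matrix(seq_len(3 * n_faces), ncol = 3, byrow = TRUE)
  triangle_mesh(v, f, name = paste0("soup", seed))
}

# ASCII STL text for a list of triangles (rows of 9 coords)
stl_text <- function(tris, name = "fixture") {
  body <- apply(tris, 1, function(r) {
    paste0("facet normal 0 0 0\n outer loop\n",
           sprintf("  vertex %g %g %g\n", r[1], r[2], r[3]),
           sprintf("  vertex %g %g %g\n", r[4], r[5], r[6]),
           sprintf("  vertex %g %g %g\n", r[7], r[8], r[9]),
           " endloop\nendfacet")
  })
  paste(c(paste("solid", name), body, paste("endsolid", name)),
        collapse = "\n")
}

max_vertex_gap <- function(a, b) {
  # largest per-coordinate discrepancy after pairing vertices by nearest
  # neighbour (formats may reorder or re-merge vertices)
  one_way <- function(x, y) {
    max(vapply(seq_len(nrow(x)), function(i) {
      j <- which.min(colSums((t(y) - x[i, ])^2))
      max(abs(y[j, ] - x[i, ]))
    }, 1.0))
  }
  max(one_way(a$vertices, b$vertices), one_way(b$vertices, a$vertices))
}

transform_gap <- function(a, b) {
  # rotation angle (deg) and translation distance (um) between two transforms
  d <- compose_transform(invert_transform(a), b)
  c(rot_deg = rotation_angle_deg(d$rotation),
    trans_um = sqrt(sum(d$translation^2)) * 1000)
}
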