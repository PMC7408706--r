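#' Scanbody geometry specification
#'
#' Parametric description of a flat-faced cylindrical implant scanbody: a
#' shaft of circular cross-section with one or more planar scanning faces
#' (chords of the circle), a chamfered top, and a total height of 13 mm by
#' default. The exact commercial geometry is proprietary; only the relative
#' geometry (flat reference faces vs cylindrical back) matters for congruence
#' analysis, so all dimensions are parameters.
#'
#' @param height total height (mm).
#' @param shaft_radius cylinder radius (mm).
#' @param flat_face_count number of planar faces, >= 1 (a scanbody needs a
#'   flat reference face).
#' @param flat_face_width chord width of each flat face (mm); must be smaller
#'   than the shaft diameter.
#' @param top_chamfer height of the chamfered top band (mm).
#' @param mesh_edge_length target triangle edge length (mm).
#' @return an object of class `scanbody_spec`.
#' @export
scanbody_spec <- function(height = 13, shaft_radius = 2.5,
                          flat_face_count = 1, flat_face_width = 3.5,
                          top_chamfer = 0.5, mesh_edge_length = 0.3) {
  if (height <= 0) stop("height must be positive")
  if (flat_face_count < 1) stop("a scanbody needs at least one flat reference face")
  if (flat_face_width >= 2 * shaft_radius)
    stop("flat_face_width must be smaller than the shaft diameter")
  if (flat_face_width <= 0) stop("flat_face_width must be positive")
  if (top_chamfer < 0 || top_chamfer >= height)
    stop("top_chamfer must be in [0, height)")
  if (mesh_edge_length <= 0) stop("mesh_edge_length must be positive")
  structure(list(height = height, shaft_radius = shaft_radius,
                 flat_face_count = as.integer(flat_face_count),
                 flat_face_width = flat_face_width,
                 top_chamfer = top_chamfer,
                 mesh_edge_length = mesh_edge_length),
            class = "scanbody_spec")
}

# azimuths of the outward directions of the flat faces
flat_azimuths <- function(spec) {
  2 * pi * (seq_len(spec$flat_face_count) - 1) / spec$flat_face_count
}

# Cross-section polygon (counter-clockwise viewed from +z): circle of radius r
# with each flat face replaced by its chord. Chords are subdivided into 3k
# equal columns so that the central-third band boundary of each flat face
# falls exactly on vertex columns (keeps region labelling exact).
scanbody_cross_section <- function(spec) {
  r <- spec$shaft_radius
  w <- spec$flat_face_width
  edge <- spec$mesh_edge_length
  alpha <- asin((w / 2) / r)
  th0 <- flat_azimuths(spec)
  k <- spec$flat_face_count
  pts <- NULL
  for (i in seq_len(k)) {
    a0 <- th0[i] - alpha
    a1 <- th0[i] + alpha
    # chord: 3m equal segments, endpoints on the circle
    m <- max(1L, ceiling(w / (3 * edge)))
    p0 <- r * c(cos(a0), sin(a0))
    p1 <- r * c(cos(a1), sin(a1))
    tt <- seq(0, 1, length.out = 3L * m + 1L)
    chord <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                   p0[2] + tt * (p1[2] - p0[2]))
    # arc to the next flat (or wrap-around)
    b0 <- a1
    b1 <- (if (i < k) th0[i + 1] else th0[1] + 2 * pi) - alpha
    narc <- max(2L, ceiling((b1 - b0) * r / edge))
    ang <- seq(b0, b1, length.out = narc + 1L)
    arc <- cbind(r * cos(ang), r * sin(ang))
    # drop each segment's final point: it starts the next segment
    pts <- rbind(pts, chord[-nrow(chord), , drop = FALSE],
                 arc[-nrow(arc), , drop = FALSE])
  }
  pts
}

#' Build the reference (library) scanbody mesh
#'
#' Generates a closed, outward-oriented triangle mesh of the scanbody: the
#' cross-section polygon extruded from z = 0 to z = height - top_chamfer, a
#' chamfer band tapering to a scaled top polygon at z = height, and planar
#' caps. The bounding-box height equals `spec$height` exactly. This plays the
#' role of the manufacturer's geometrically perfect CAD library file.
#'
#' @param spec a [scanbody_spec()].
#' @return a [triangle_mesh()], closed and outward-oriented.
#' @export
build_library_mesh <- function(spec) {
  if (!inherits(spec, "scanbody_spec")) stop("spec must be a scanbody_spec")
  poly <- scanbody_cross_section(spec)
  np <- nrow(poly)
  h <- spec$height
  ch <- spec$top_chamfer
  edge <- spec$mesh_edge_length
  nz <- max(1L, ceiling((h - ch) / edge))
  zs <- seq(0, h - ch, length.out = nz + 1L)

  rings <- lapply(zs, function(z) cbind(poly, z))
  if (ch > 0) {
    s <- (spec$shaft_radius - ch) / spec$shaft_radius
    rings <- c(rings, list(cbind(poly * s, h)))
  }
  nr <- length(rings)
  V <- do.call(rbind, rings)
  ib <- nrow(V) + 1L           # bottom cap centre
  it <- nrow(V) + 2L           # top cap centre
  V <- rbind(V, c(0, 0, 0), c(0, 0, h))

  idx <- function(ring, i) (ring - 1L) * np + ((i - 1L) %% np) + 1L
  i1 <- seq_len(np)
  i2 <- c(2:np, 1L)
  side <- vector("list", nr - 1L)
  for (j in seq_len(nr - 1L)) {
    a <- idx(j, i1); b <- idx(j, i2)
    cc <- idx(j + 1L, i2); d <- idx(j + 1L, i1)
    side[[j]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  bottom <- cbind(ib, idx(1L, i2), idx(1L, i1))
  top <- cbind(it, idx(nr, i1), idx(nr, i2))
  faces <- do.call(rbind, c(side, list(bottom, top)))

  m <- triangle_mesh(V, faces, name = "scanbody_library")
  if (mesh_volume(m) < 0)  # defensive: flip to outward orientation
    m$faces <- m$faces[, c(1, 3, 2)]
  m
}
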