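#' Arch layout of the six scanbody positions
#'
#' Six labelled poses S1-S6 on a fully edentulous maxillary arch, mirroring
#' the standard positions (right first molar, right first premolar, right
#' central incisor, left central incisor, left first premolar, left first
#' molar). Positions are specular and the axes near-parallel (tilts of a few
#' degrees at most), as scanbodies are mounted on fairly parallel implants.
#'
#' @param positions 6 x 2 matrix of (x, y) implant positions (mm).
#' @param tilt_deg length-6 axis tilts (degrees, small).
#' @return an object of class `arch_layout`: list of 6 named rigid poses.
#' @export
arch_layout <- function(positions = NULL, tilt_deg = c(3, -2, 4, -4, 2, -3)) {
  if (is.null(positions))
    positions <- rbind(c(25, 5), c(18, 18), c(5, 28),
                       c(-5, 28), c(-18, 18), c(-25, 5))
  positions <- as.matrix(positions)
  if (nrow(positions) != 6L || ncol(positions) != 2L)
    stop("exactly six (x, y) positions are required")
  if (anyDuplicated(paste(positions[, 1], positions[, 2])))
    stop("scanbody positions must be pairwise distinct")
  if (length(tilt_deg) != 6L) stop("tilt_deg must have length 6")
  poses <- lapply(seq_len(6L), function(k) {
    # tilt about the local tangential direction, position in the arch plane
    axis <- c(-positions[k, 2], positions[k, 1], 0)
    if (all(axis == 0)) axis <- c(1, 0, 0)
    rigid_transform(rotation_about_axis(axis, tilt_deg[k]),
                    c(positions[k, ], 0))
  })
  names(poses) <- paste0("S", 1:6)
  structure(list(poses = poses, positions = positions, tilt_deg = tilt_deg),
            class = "arch_layout")
}

#' Generate a full synthetic scan study
#'
#' Builds the reference library mesh and, for every (scanner profile, model
#' replicate, scanbody position), a simulated scan mesh placed at its arch
#' pose. Per-scan random streams are split deterministically from the master
#' seed, so adding replicates never perturbs earlier ones; the six physical
#' parts are shared across scanners, so their manufacturing offsets are drawn
#' once (scaled to each profile's stated tolerance).
#'
#' @param spec a [scanbody_spec()].
#' @param layout an [arch_layout()].
#' @param scanner_profiles named list of [error_model()] profiles.
#' @param n_models replicate scans per scanner (>= 1).
#' @param seed master seed.
#' @param dir optional output directory; when given, meshes are written as
#'   binary STL in one folder per scanner (`<scanner>/model_<m>/sb_<k>.stl`)
#'   plus a `manifest.csv`, and file paths are returned instead of meshes.
#' @return list with `library` (the reference mesh), `manifest` (data frame:
#'   scanner, model, sb, seed, true_offset_um, path), and `meshes` (named
#'   list, `NULL` when `dir` is used).
#' @export
generate_study <- function(spec = scanbody_spec(), layout = arch_layout(),
                           scanner_profiles = default_scanner_profiles(),
                           n_models = 10L, seed = 1L, dir = NULL) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (length(scanner_profiles) < 1) stop("at least one scanner profile required")
  if (is.null(names(scanner_profiles)))
    stop("scanner_profiles must be a named list")
  library_mesh <- build_library_mesh(spec)
  vlabs <- vertex_region_labels(library_mesh, spec)
  part_draw <- with_seed(seed, runif(6L, -1, 1))  # shared physical parts

  rows <- list()
  meshes <- if (is.null(dir)) list() else NULL
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(scanner_profiles)) {
    scanner <- names(scanner_profiles)[s]
    prof <- scanner_profiles[[s]]
    for (m in seq_len(n_models)) {
      for (k in 1:6) {
        sb <- paste0("S", k)
        sc_seed <- derive_seed(seed, s, m, k)
        prof_k <- prof
        prof_k$manufacturing_offset_um <-
          part_draw[k] * prof$manufacturing_tolerance_um
        scan <- simulate_scan(library_mesh, prof_k, seed = sc_seed,
                              region_labels = vlabs)
        pose <- layout$poses[[sb]]
        placed <- scan
        placed$vertices <- apply_transform(pose, scan$vertices)
        placed$name <- sprintf("%s_model%d_%s", scanner, m, sb)
        # total pose = arch pose o rigid jitter
        attr(placed, "applied_transform") <-
          compose_transform(pose, attr(scan, "applied_transform"))
        attr(placed, "true_offset_um") <- attr(scan, "true_offset_um")
        attr(placed, "manufacturing_offset_um") <-
          attr(scan, "manufacturing_offset_um")
        path <- NA_character_
        if (!is.null(dir)) {
          d <- file.path(dir, scanner, sprintf("model_%02d", m))
          dir.create(d, recursive = TRUE, showWarnings = FALSE)
          path <- file.path(d, sprintf("sb_%d.stl", k))
          write_mesh(placed, path, "stl")
        } else {
          meshes[[placed$name]] <- placed
        }
        rows[[length(rows) + 1L]] <-
          data.frame(scanner = scanner, model = m, sb = sb, seed = sc_seed,
                     true_offset_um = attr(scan, "true_offset_um"),
                     path = path, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write_mesh(library_mesh, file.path(dir, "library.stl"), "stl")
  }
  list(library = library_mesh, manifest = manifest, meshes = meshes)
}
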