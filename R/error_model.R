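#' Scanner error model
#'
#' Generative model for the errors a scanner (plus the physical part) imprints
#' on a scanbody surface reconstruction, applied in a fixed, documented order:
#' manufacturing scale offset along vertex normals, region-dependent mean
#' normal offset, Laplacian smoothing, per-vertex Gaussian normal noise, and a
#' random rigid transform (the arbitrary pose of the scan). Signed offsets are
#' in micrometres: positive = outward growth (scan mesh envelops the
#' reference), negative = inward shrinkage (scan mesh inside the reference).
#'
#' @param normal_offset_mean mean signed offset along the surface normal (um).
#' @param normal_offset_by_region optional named vector of per-region signed
#'   offsets (um), names in `flat_central`, `flat_lateral`, `back`; added to
#'   `normal_offset_mean` where supplied.
#' @param surface_noise_sd per-vertex Gaussian noise SD along normals (um).
#' @param smoothing_iterations Laplacian smoothing passes (>= 0).
#' @param rigid_jitter_rotation_sd SD of the random pose rotation (degrees).
#' @param rigid_jitter_translation_sd SD of the random pose translation (um).
#' @param manufacturing_tolerance_um half-width of the uniform manufacturing
#'   scale offset (um); each simulated part draws its offset in
#'   `[-tol, +tol]`, the stated production tolerance.
#' @param manufacturing_offset_um optional fixed manufacturing offset (um),
#'   e.g. when the same physical part is rescanned; must be within tolerance.
#' @param seed default seed used when [simulate_scan()] is called without one.
#' @return an object of class `error_model`.
#' @export
error_model <- function(normal_offset_mean = 0,
                        normal_offset_by_region = NULL,
                        surface_noise_sd = 0,
                        smoothing_iterations = 0L,
                        rigid_jitter_rotation_sd = 0,
                        rigid_jitter_translation_sd = 0,
                        manufacturing_tolerance_um = 20,
                        manufacturing_offset_um = NULL,
                        seed = 1L) {
  if (surface_noise_sd < 0) stop("surface_noise_sd must be >= 0")
  if (smoothing_iterations < 0) stop("smoothing_iterations must be >= 0")
  if (manufacturing_tolerance_um < 0)
    stop("manufacturing_tolerance_um must be >= 0")
  if (!is.null(manufacturing_offset_um) &&
      abs(manufacturing_offset_um) > manufacturing_tolerance_um)
    stop("fixed manufacturing offset exceeds the stated tolerance")
  structure(list(normal_offset_mean = normal_offset_mean,
                 normal_offset_by_region = normal_offset_by_region,
                 surface_noise_sd = surface_noise_sd,
                 smoothing_iterations = as.integer(smoothing_iterations),
                 rigid_jitter_rotation_sd = rigid_jitter_rotation_sd,
                 rigid_jitter_translation_sd = rigid_jitter_translation_sd,
                 manufacturing_tolerance_um = manufacturing_tolerance_um,
                 manufacturing_offset_um = manufacturing_offset_um,
                 seed = as.integer(seed)),
            class = "error_model")
}

# One pass: v <- v + lambda * (neighbour mean - v). Plain umbrella operator;
# mildly shrinks convex surfaces, which is exactly the inward bias that
# scanner post-processing is suspected to introduce.
laplacian_smooth <- function(vertices, faces, iterations, lambda = 0.5) {
  if (iterations == 0L) return(vertices)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- unique(rbind(e, e[, c(2, 1)]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = rep(nrow(vertices), 2))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  v <- vertices
  for (i in seq_len(iterations))
    v <- v + lambda * (as.matrix(A %*% v) / deg - v)
  v
}

#' Simulate a scanbody scan mesh
#'
#' Applies an [error_model()] to a reference library mesh and returns the
#' simulated scan, deterministically for a given `(model, seed)`. The applied
#' rigid pose, the drawn manufacturing offset, and the total true mean offset
#' are attached as attributes (`applied_transform`, `manufacturing_offset_um`,
#' `true_offset_um`) so that downstream recovery can be checked against
#' ground truth.
#'
#' @param library a closed, outward-oriented [triangle_mesh()].
#' @param model an [error_model()].
#' @param seed integer seed; defaults to `model$seed`.
#' @param region_labels optional per-vertex region labels (character), needed
#'   only when `model$normal_offset_by_region` is used.
#' @return a [triangle_mesh()] with ground-truth attributes.
#' @export
simulate_scan <- function(library, model, seed = model$seed,
                          region_labels = NULL) {
  if (!inherits(library, "triangle_mesh")) stop("library must be a triangle_mesh")
  if (!inherits(model, "error_model")) stop("model must be an error_model")
  if (!mesh_is_closed(library))
    stop("library mesh must be closed (watertight) and oriented")
  vn <- vertex_normals(library)
  nvert <- nrow(library$vertices)

  with_seed(seed, {
    u <- if (!is.null(model$manufacturing_offset_um)) {
      runif(1)  # keep the stream layout identical either way
      model$manufacturing_offset_um
    } else {
      runif(1, -model$manufacturing_tolerance_um,
            model$manufacturing_tolerance_um)
    }
    off <- rep(u + model$normal_offset_mean, nvert)
    if (!is.null(model$normal_offset_by_region)) {
      if (is.null(region_labels))
        stop("region_labels required for per-region offsets")
      extra <- model$normal_offset_by_region[region_labels]
      extra[is.na(extra)] <- 0
      off <- off + as.numeric(extra)
    }
    v <- library$vertices + (off * 1e-3) * vn
    v <- laplacian_smooth(v, library$faces, model$smoothing_iterations)
    if (model$surface_noise_sd > 0)
      v <- v + (rnorm(nvert, 0, model$surface_noise_sd) * 1e-3) * vn

    tf <- rigid_transform()
    if (model$rigid_jitter_rotation_sd > 0 ||
        model$rigid_jitter_translation_sd > 0) {
      ax <- rnorm(3)
      ang <- rnorm(1, 0, model$rigid_jitter_rotation_sd)
      tr <- rnorm(3, 0, model$rigid_jitter_translation_sd) * 1e-3
      tf <- rigid_transform(rotation_about_axis(ax, ang), tr)
      v <- apply_transform(tf, v)
    }

    out <- triangle_mesh(v, library$faces,
                         name = paste0(library$name, "_scan"))
    attr(out, "applied_transform") <- tf
    attr(out, "manufacturing_offset_um") <- u
    attr(out, "true_offset_um") <- u + model$normal_offset_mean
    attr(out, "error_model") <- model
    out
  })
}

#' Shipped scanner error profiles
#'
#' Five named [error_model()] profiles spanning the deviation signatures seen
#' across commercial intraoral scanners: outward-dominant growth
#' (`cs3700_like`), inward-dominant shrinkage at three severities
#' (`primescan_like`, `itero_like`, `emerald_like`) and a mixed, zero-mean
#' interpolating signature (`medit_like`) whose regions deviate with opposite
#' signs (scan and reference interpenetrate with no overall direction). Mean
#' offsets and noise levels are chosen so per-superimposition mean absolute
#' deviations land in the 20-50 um range typical of scanbody congruence
#' studies.
#'
#' @param manufacturing_tolerance_um production tolerance shared by all
#'   profiles (the same physical parts are scanned by every scanner).
#' @return named list of [error_model()] objects.
#' @export
default_scanner_profiles <- function(manufacturing_tolerance_um = 20) {
  jit <- list(rot = 1.5, tra = 300)  # arbitrary scan pose, deg / um
  mk <- function(offset, noise, by_region = NULL)
    error_model(normal_offset_mean = offset, surface_noise_sd = noise,
                normal_offset_by_region = by_region,
                rigid_jitter_rotation_sd = jit$rot,
                rigid_jitter_translation_sd = jit$tra,
                manufacturing_tolerance_um = manufacturing_tolerance_um)
  list(primescan_like = mk(-24, 8),
       cs3700_like = mk(+26, 8),
       medit_like = mk(0, 40, by_region = c(flat_central = 18,
                                            flat_lateral = -18, back = 0)),
       itero_like = mk(-32, 10),
       emerald_like = mk(-36, 10))
}
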