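#' Least-squares rigid landmark alignment
#'
#' Closed-form orthogonal Procrustes (SVD with determinant correction,
#' i.e. the Kabsch solution): the rigid transform (no scaling) minimising
#' `sum ||R s_i + t - d_i||^2` over proper rotations. This is the coarse
#' "three points on each scanbody" alignment that precedes the best-fit
#' refinement.
#'
#' @param source_points n x 3 matrix (n >= 3), mm.
#' @param target_points n x 3 matrix, same row count, mm.
#' @return a [rigid_transform()] mapping source into target coordinates.
#' @export
landmark_align <- function(source_points, target_points) {
  s <- as.matrix(source_points)
  d <- as.matrix(target_points)
  if (nrow(s) != nrow(d)) stop("point counts differ")
  if (nrow(s) < 3) stop("at least three landmark pairs are required")
  cs <- colMeans(s)
  cd <- colMeans(d)
  s0 <- sweep(s, 2, cs)
  d0 <- sweep(d, 2, cd)
  # degenerate (collinear) configurations leave a rotation axis unconstrained
  if (svd(s0)$d[2] < 1e-9)
    stop("degenerate landmarks: source points are collinear")
  H <- crossprod(s0, d0)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  rigid_transform(R, as.numeric(cd - R %*% cs))
}

#' Closest point on a triangle
#'
#' Exact Euclidean closest point of `p` in the closed triangle; the returned
#' point lies on the triangle (vertex, edge, or interior).
#'
#' @param p length-3 point (mm).
#' @param tri 3 x 3 matrix, one vertex per row (mm).
#' @return list with `point` and `distance` (mm).
#' @export
closest_point_on_triangle <- function(p, tri) {
  tri <- as.matrix(tri)
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  if (sqrt(sum(n^2)) <= 2e-12) stop("degenerate triangle")
  q <- cp_point_triangle(as.numeric(p), tri)
  list(point = q, distance = sqrt(sum((p - q)^2)))
}

#' Spatial index over a triangle mesh
#'
#' Uniform-grid acceleration structure for exact nearest-surface queries.
#' Queries return the true nearest point over all triangles (the expanding
#' shell search terminates only once no unvisited cell can contain a closer
#' triangle), so accelerated results equal brute force.
#'
#' @param mesh a [triangle_mesh()].
#' @return an object of class `mesh_index`.
#' @export
mesh_index <- function(mesh) {
  structure(list(ptr = cp_build_index(mesh$vertices, mesh$faces),
                 mesh = mesh, normals = face_normals(mesh)),
            class = "mesh_index")
}

#' Exact nearest point on a mesh surface
#'
#' For each query point, the closest point on the mesh, the signed distance
#' (positive on the outward-normal side of the nearest face), and the nearest
#' face. Accepts a prebuilt [mesh_index()] to amortise the grid construction.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param target a [triangle_mesh()] or [mesh_index()].
#' @return data frame: `distance` (mm, unsigned), `signed_distance` (mm),
#'   `face`, and foot-point columns `fx, fy, fz` plus nearest-face normal
#'   columns `nx, ny, nz`.
#' @export
closest_surface_point <- function(points, target) {
  idx <- if (inherits(target, "mesh_index")) target else mesh_index(target)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  res <- cp_query(idx$ptr, as.matrix(points))
  nn <- idx$normals[res$face, , drop = FALSE]
  data.frame(distance = res$distance, signed_distance = res$signed_distance,
             face = res$face, fx = res$point[, 1], fy = res$point[, 2],
             fz = res$point[, 3], nx = nn[, 1], ny = nn[, 2], nz = nn[, 3])
}

#' Robust correspondence weights
#'
#' Maps residuals to weights in `[0, 1]`, non-increasing in `|residual|`.
#' The default scheme is the Tukey biweight with the residual scale estimated
#' as `1.4826 * MAD` (a robust sigma) each time it is evaluated; residuals
#' beyond `tuning * scale` get weight 0. When every residual is zero the
#' weights are all 1.
#'
#' @param residuals numeric vector of signed residuals.
#' @param scheme `"tukey"`, `"huber"`, or `"none"`.
#' @param scale `"auto"` (1.4826 * MAD) or a positive number.
#' @param tuning tuning constant (default 4.685, the standard 95%-efficiency
#'   value for the Tukey biweight; 1.345 is conventional for Huber).
#' @return numeric weights in `[0, 1]`.
#' @export
robust_weights <- function(residuals, scheme = c("tukey", "huber", "none"),
                           scale = "auto", tuning = 4.685) {
  scheme <- match.arg(scheme)
  if (length(residuals) < 1) stop("at least one residual required")
  if (scheme == "none") return(rep(1, length(residuals)))
  # 1.4826 * median absolute deviation about zero: the residual's target is
  # the surface itself, so a uniform surface offset must not be mistaken for
  # an outlier cloud (a median-centred scale collapses in that case). The
  # floor keeps exactly-converged data (residuals at machine precision) from
  # degenerating into an all-outlier classification.
  s <- if (identical(scale, "auto")) 1.4826 * median(abs(residuals))
       else as.numeric(scale)
  if (!is.finite(s)) return(rep(1, length(residuals)))
  s <- max(s, 1e-9)  # clamp, so zero residuals weigh 1 yet outliers still 0
  u <- residuals / (tuning * s)
  if (scheme == "tukey") {
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
  } else {
    w <- pmin(1, 1 / pmax(abs(u), 1e-300))
  }
  w
}

#' ICP configuration
#'
#' @param min_iterations minimum iteration count (default 100, the standard
#'   floor used when registrations must be comparable across cases).
#' @param max_iterations iteration cap (>= min_iterations).
#' @param convergence_tol_um stop (after the minimum) once the RMS residual
#'   changes by less than this (um).
#' @param sample_count correspondence budget per iteration: face centroids,
#'   subsampled (area-weighted, seeded) when the mesh has more faces.
#' @param robust_scheme robust weighting scheme, see [robust_weights()].
#' @param tuning robust tuning constant.
#' @param seed seed for the source sampling.
#' @export
icp_config <- function(min_iterations = 100L, max_iterations = 500L,
                       convergence_tol_um = 1e-4, sample_count = 20000L,
                       robust_scheme = "tukey", tuning = 4.685, seed = 1L) {
  if (min_iterations < 1) stop("min_iterations must be >= 1")
  if (max_iterations < min_iterations)
    stop("max_iterations must be >= min_iterations")
  structure(list(min_iterations = as.integer(min_iterations),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol_um = convergence_tol_um,
                 sample_count = as.integer(sample_count),
                 robust_scheme = robust_scheme, tuning = tuning,
                 seed = as.integer(seed)),
            class = "icp_config")
}

#' Robust point-to-plane ICP registration
#'
#' Refines an initial rigid transform of the moving (scan) mesh onto the
#' reference surface. Each iteration: exact nearest-surface correspondences
#' for an area-weighted sample of the source (face centroids carrying their
#' areas as weights; a seeded random area-weighted face subset when the
#' tessellation exceeds `sample_count`); robust reweighting of the
#' signed point-to-plane residuals; weighted least-squares minimisation of
#' `sum w_i (n_i . (R s_i + t - q_i))^2` via the small-angle linearisation
#' (6 x 6 normal equations) followed by re-orthonormalisation of the rotation.
#' Runs at least `min_iterations` and is deterministic given the seed.
#'
#' @param source the moving [triangle_mesh()] (the scan).
#' @param target the reference [triangle_mesh()] or a [mesh_index()] over it.
#' @param init initial [rigid_transform()] (e.g. from [landmark_align()]).
#' @param config an [icp_config()].
#' @return list: `transform` (source -> target), `trace` (data frame with
#'   per-iteration RMS residual in um and mean weight), `iterations`,
#'   `converged`.
#' @export
icp_point_to_plane <- function(source, target, init = rigid_transform(),
                               config = icp_config()) {
  idx <- if (inherits(target, "mesh_index")) target else mesh_index(target)
  # correspondences are face centroids carrying their face areas as weights:
  # for a closed source this zeroes the first surface moments exactly, so a
  # normal-symmetric offset cannot masquerade as a rigid motion. Larger
  # meshes use a seeded uniform face subset that keeps the area weights
  # (area-biased sampling would oversample broken faces, whose areas are
  # inflated by exactly the vertex outliers robustness must reject).
  ar <- face_areas(source)
  if (nrow(source$faces) <= config$sample_count) {
    S <- face_centroids(source)
    w_area <- ar / mean(ar)
  } else {
    fi <- with_seed(config$seed,
                    sample.int(nrow(source$faces), config$sample_count))
    S <- face_centroids(source)[fi, , drop = FALSE]
    w_area <- ar[fi] / mean(ar[fi])
  }
  tf <- init
  trace_rms <- numeric(0)
  trace_w <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    P <- apply_transform(tf, S)
    cor <- cp_query(idx$ptr, P)
    nn <- idx$normals[cor$face, , drop = FALSE]
    Q <- cor$point
    r <- rowSums((P - Q) * nn)  # signed point-to-plane residual, mm
    w <- robust_weights(r, config$robust_scheme, tuning = config$tuning)
    if (all(w == 0)) w <- rep(1, length(r))
    w <- w * w_area
    A <- cbind(row_cross(P, nn), nn)
    Aw <- A * w
    M <- crossprod(Aw, A)
    rhs <- -crossprod(Aw, r)
    if (!is.finite(rcond(M)) || rcond(M) < 1e-12)
      stop("ill-conditioned registration: source geometry does not ",
           "constrain all six degrees of freedom")
    x <- solve(M, rhs)
    dR <- rotation_from_vector(x[1:3])
    tf <- rigid_transform(orthonormalize(dR %*% tf$rotation),
                          as.numeric(dR %*% tf$translation) + x[4:6])
    rms <- sqrt(sum(w * r^2) / sum(w)) * 1000  # um
    trace_rms <- c(trace_rms, rms)
    trace_w <- c(trace_w, mean(w))
    if (it >= config$min_iterations &&
        abs(prev_rms - rms) < config$convergence_tol_um) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
  }
  list(transform = tf,
       trace = data.frame(iteration = seq_len(it), rms_um = trace_rms,
                          mean_weight = trace_w),
       iterations = it, converged = converged)
}
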