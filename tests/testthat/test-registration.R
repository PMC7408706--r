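test_that("landmark alignment recovers exact transforms and beats random search", {
  pts <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0), c(1, 1, 2))
  expect_equal(landmark_align(pts, pts)$rotation, diag(3), tolerance = 1e-12)
  expect_equal(landmark_align(pts, pts)$translation, c(0, 0, 0),
               tolerance = 1e-12)

  tru <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(1, 2, 3))
  got <- landmark_align(pts, apply_transform(tru, pts))
  expect_lt(max(abs(got$rotation - tru$rotation)), 1e-9)
  expect_lt(max(abs(got$translation - tru$translation)), 1e-9)

  # noisy pairs: closed form must beat 1000 random rigid transforms
  set.seed(8)
  src <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 1))
  tgt <- apply_transform(tru, src) + matrix(rnorm(9, 0, 0.1), 3)
  fit <- landmark_align(src, tgt)
  res <- function(tf) sum((apply_transform(tf, src) - tgt)^2)
  rand <- replicate(1000, {
    tf <- rigid_transform(rotation_about_axis(rnorm(3), runif(1, 0, 360)),
                          tru$translation + rnorm(3, 0, 0.3))
    res(tf)
  })
  expect_lte(res(fit), min(rand))

  collinear <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(landmark_align(collinear, collinear), "collinear")
})

test_that("closest point on a triangle matches the candidate-enumeration oracle", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  centroid <- colMeans(tri)
  got <- closest_point_on_triangle(centroid + c(0, 0, 1), tri)
  expect_equal(got$distance, 1, tolerance = 1e-12)
  expect_equal(got$point, centroid, tolerance = 1e-12)

  # beyond an edge: analytic 2D foot
  p <- c(1, -3, 0)
  got <- closest_point_on_triangle(p, tri)
  expect_equal(got$point, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(got$distance, 3, tolerance = 1e-12)

  expect_equal(closest_point_on_triangle(tri[2, ], tri)$distance, 0)

  set.seed(21)
  for (i in 1:200) {
    tri <- matrix(rnorm(9, sd = 2), 3)
    p <- rnorm(3, sd = 3)
    got <- closest_point_on_triangle(p, tri)
    want <- oracle_point_triangle(p, tri)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
  }
  degenerate <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(closest_point_on_triangle(c(0, 1, 0), degenerate),
               "degenerate")
})

test_that("accelerated nearest-surface queries equal brute force exactly", {
  lib <- build_library_mesh(scanbody_spec(mesh_edge_length = 0.5))
  idx <- mesh_index(lib)
  set.seed(5)
  n <- 1000
  P <- cbind(runif(n, -5, 5), runif(n, -5, 5), runif(n, -3, 16))
  got <- closest_surface_point(P, idx)
  want <- vapply(seq_len(n), function(i) oracle_mesh_distance(P[i, ], lib),
                 1.0)
  expect_equal(got$distance, want, tolerance = 1e-9)
  expect_equal(abs(got$signed_distance), got$distance, tolerance = 1e-12)

  # on-surface and far-field queries
  s <- sample_surface(lib, 50, seed = 2)$points
  expect_lt(max(closest_surface_point(s, idx)$distance), 1e-9)
  far <- matrix(c(90, 90, 130), 1)  # ~10x the bounding radius
  expect_equal(closest_surface_point(far, idx)$distance,
               oracle_mesh_distance(far[1, ], lib), tolerance = 1e-9)
})

test_that("robust weights follow the biweight with MAD-about-zero scale", {
  expect_equal(robust_weights(rep(0.3, 10)), rep(robust_weights(0.3), 10))
  expect_equal(robust_weights(c(0, 0, 0)), c(1, 1, 1))
  expect_equal(robust_weights(rnorm(20), scheme = "none"), rep(1, 20))

  set.seed(9)
  r <- rnorm(100, 0, 0.01)
  s <- 1.4826 * median(abs(r))
  r_out <- c(r, 10 * s)
  w <- robust_weights(r_out, scheme = "tukey")
  expect_equal(w[101], 0)  # beyond c = 4.685 times the robust scale
  # non-increasing in |residual|
  o <- order(abs(r_out))
  expect_true(all(diff(w[o]) <= 1e-12))
  # fixed scale reproduces the closed-form biweight
  wf <- robust_weights(c(1, 2, 10), scale = 1, tuning = 4.685)
  u <- c(1, 2, 10) / 4.685
  expect_equal(wf, ifelse(abs(u) < 1, (1 - u^2)^2, 0))
})

test_that("point-to-plane ICP recovers a known rigid perturbation", {
  lib <- build_library_mesh(scanbody_spec(mesh_edge_length = 0.25))
  tru <- rigid_transform(rotation_about_axis(c(1, 2, 3), 2),
                         c(0.05, -0.03, 0.02) / sqrt(3))
  src <- lib
  src$vertices <- apply_transform(tru, lib$vertices)
  reg <- icp_point_to_plane(src, lib, rigid_transform(),
                            icp_config(sample_count = 4000, seed = 3))
  expect_gte(reg$iterations, 100)
  gap <- transform_gap(reg$transform, invert_transform(tru))
  expect_lt(gap["rot_deg"], 1e-3)
  expect_lt(gap["trans_um"], 0.1)
})

test_that("a normal-symmetric offset surface registers to the identity", {
  lib <- build_library_mesh(scanbody_spec(mesh_edge_length = 0.3))
  em <- error_model(normal_offset_mean = 30, manufacturing_tolerance_um = 0)
  src <- simulate_scan(lib, em, seed = 2)
  # sample budget above the face count: every centroid participates with its
  # area weight, so the closed surface's first moments cancel exactly
  reg <- icp_point_to_plane(src, lib, rigid_transform(),
                            icp_config(sample_count = 6000, seed = 4))
  expect_lt(sqrt(sum(reg$transform$translation^2)) * 1000, 1)   # < 1 um
  expect_lt(rotation_angle_deg(reg$transform$rotation), 0.01)
})

test_that("an exact initial transform is a fixed point", {
  lib <- build_library_mesh(scanbody_spec(mesh_edge_length = 0.3))
  reg <- icp_point_to_plane(lib, lib, rigid_transform(),
                            icp_config(min_iterations = 1,
                                       max_iterations = 1,
                                       sample_count = 2000, seed = 5))
  expect_lt(rotation_angle_deg(reg$transform$rotation) * pi / 180, 1e-9)
  expect_lt(sqrt(sum(reg$transform$translation^2)), 1e-9)
})

test_that("registration is transform-equivariant", {
  lib <- build_library_mesh(scanbody_spec(mesh_edge_length = 0.3))
  tru <- rigid_transform(rotation_about_axis(c(0, 1, 1), 1.5),
                         c(0.03, 0.01, -0.02))
  src <- lib
  src$vertices <- apply_transform(tru, lib$vertices)
  cfg <- icp_config(sample_count = 3000, seed = 6)
  base <- icp_point_to_plane(src, lib, rigid_transform(), cfg)

  extra <- rigid_transform(rotation_about_axis(c(1, 0, 0), 3), c(1, -2, 0.5))
  src2 <- src
  src2$vertices <- apply_transform(extra, src$vertices)
  init2 <- compose_transform(rigid_transform(), invert_transform(extra))
  moved <- icp_point_to_plane(src2, lib, init2, cfg)
  want <- compose_transform(base$transform, invert_transform(extra))
  gap <- transform_gap(moved$transform, want)
  expect_lt(gap["rot_deg"] * pi / 180, 1e-6)
  expect_lt(gap["trans_um"] / 1000, 1e-6)
})

test_that("gross outliers barely perturb the recovered transform", {
  lib <- build_library_mesh(scanbody_spec(mesh_edge_length = 0.3))
  tru <- rigid_transform(rotation_about_axis(c(2, 1, 0), 1), c(0.02, 0.04, -0.01))
  clean <- lib
  clean$vertices <- apply_transform(tru, lib$vertices)
  cfg <- icp_config(sample_count = 3000, seed = 7)
  base_gap <- transform_gap(
    icp_point_to_plane(clean, lib, rigid_transform(), cfg)$transform,
    invert_transform(tru))

  corrupted <- clean
  set.seed(13)
  hit <- sample(nrow(corrupted$vertices), round(0.1 * nrow(corrupted$vertices)))
  dirs <- matrix(rnorm(3 * length(hit)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  corrupted$vertices[hit, ] <- corrupted$vertices[hit, ] + dirs  # +1 mm
  out_gap <- transform_gap(
    icp_point_to_plane(corrupted, lib, rigid_transform(), cfg)$transform,
    invert_transform(tru))
  expect_lt(out_gap["rot_deg"], 2 * base_gap["rot_deg"] + 1e-3)
  expect_lt(out_gap["trans_um"], 2 * base_gap["trans_um"] + 0.5)
})

test_that("degenerate source geometry raises an ill-conditioned error", {
  # a flat plate constrains neither in-plane translation nor in-plane spin
  v <- as.matrix(expand.grid(x = 0:10, y = 0:10))
  v <- cbind(v, 0)
  f <- NULL
  for (i in 1:10) for (j in 1:10) {
    a <- (i - 1) * 11 + j
    f <- rbind(f, c(a, a + 1, a + 11), c(a + 1, a + 12, a + 11))
  }
  plate <- triangle_mesh(v, f, name = "plate")
  expect_error(
    icp_point_to_plane(plate, plate, rigid_transform(),
                       icp_config(min_iterations = 1, max_iterations = 1,
                                  sample_count = 500, seed = 1)),
    "ill-conditioned")
})
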