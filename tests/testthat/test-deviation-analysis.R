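field_from <- function(d, region = NA_character_) {
  out <- data.frame(x = 0, y = 0, z = 0, signed_um = d, region = region,
                    stringsAsFactors = FALSE)
  class(out) <- c("deviation_field", "data.frame")
  out
}

test_that("identical meshes give a zero deviation field", {
  lib <- build_library_mesh(scanbody_spec(mesh_edge_length = 0.4))
  f <- signed_deviation(lib, lib, sample_count = 2000, seed = 1)
  expect_lt(max(abs(f$signed_um)), 1e-6)
})

test_that("uniform offsets produce coherent signs and magnitudes", {
  spec <- scanbody_spec(mesh_edge_length = 0.15)
  lib <- build_library_mesh(spec)
  idx <- mesh_index(lib)
  for (off in c(10, -10)) {
    em <- error_model(normal_offset_mean = off, manufacturing_tolerance_um = 0)
    scan <- simulate_scan(lib, em, seed = 6)
    f <- signed_deviation(scan, idx, sample_count = 4000, seed = 3,
                          spec = spec)
    expect_gt(mean(sign(f$signed_um) == sign(off)), 0.995)
    expect_equal(mean(f$signed_um), off, tolerance = 0.05)
    # sign coherence: majorities swap with the offset direction
    lab <- direction_label(f)
    expect_equal(lab, if (off > 0) "outward deviation" else "inward deviation")
  }
})

test_that("congruence summaries compute the documented statistics", {
  s <- summarize_congruence(field_from(c(1, 2, 3)))
  expect_equal(s$mean_abs, 2)
  expect_equal(s$median, 2)
  expect_equal(s$q1_q3, c(1.5, 2.5))

  sym <- summarize_congruence(field_from(c(-17, 17, -17, 17)))
  expect_equal(sym$mean_abs, 17)
  expect_equal(sym$mean_signed, 0)
  expect_equal(sym$sd_abs, 0)
  expect_equal(format_congruence(sym), "17 ± 0 μm")

  set.seed(4)
  d <- rnorm(500, -5, 12)
  s2 <- summarize_congruence(field_from(d))
  expect_true(s2$q1_q3[1] <= s2$median && s2$median <= s2$q1_q3[2])
  expect_true(s2$range[1] <= s2$q1_q3[1] && s2$q1_q3[2] <= s2$range[2])
  expect_gte(s2$mean_abs, abs(s2$mean_signed))
  expect_equal(s2$ci95[2] - s2$mean_abs, 1.96 * s2$sd_abs / sqrt(500))

  expect_error(summarize_congruence(field_from(1)), "nsufficient")
})

test_that("colorimetric classification respects the green band and saturation", {
  bins <- color_bins(scale_max = 50, green_band = 1)
  f <- field_from(c(0, 5, -0.5, -5, 1, -1, 80, -80))
  cl <- classify_bins(f, bins)$class
  expect_equal(as.character(cl),
               c("none", "outward", "none", "inward", "none", "none",
                 "outward", "inward"))
  expect_equal(sum(classify_bins(f, bins)$overall), 1, tolerance = 1e-12)
  expect_error(color_bins(scale_max = 1, green_band = 1), "green_band")
})

test_that("direction labels follow chromatic predominance with ties to none", {
  expect_equal(direction_label(field_from(rep(5, 10))), "outward deviation")
  expect_equal(direction_label(field_from(c(rep(5, 5), rep(-5, 5)))),
               "no deviation")
  f <- field_from(c(5, 5, -5), region = c("back", "back", "flat_central"))
  expect_equal(direction_label(f, region = "back"), "outward deviation")
  expect_error(direction_label(f, region = "flat_lateral"), "empty region")
})

test_that("region labelling partitions the reference into the three areas", {
  spec <- scanbody_spec()
  lib <- build_library_mesh(spec)
  labs <- label_regions(lib, spec)
  expect_setequal(unique(labs), c("back", "flat_central", "flat_lateral"))
  expect_length(labs, nrow(lib$faces))

  # a face on the cylinder side opposite the flat is back
  ce <- face_centroids(lib)
  opposite <- which.min(ce[, 1])
  expect_equal(labs[opposite], "back")

  # the central band is the middle third of the flat width
  ar <- face_areas(lib)
  flat <- labs %in% c("flat_central", "flat_lateral")
  frac <- sum(ar[labs == "flat_central"]) / sum(ar[flat])
  expect_equal(frac, 1 / 3, tolerance = 0.02)

  # user labels override and are length-checked
  expect_error(label_regions(lib, spec, user_labels = "back"),
               "one label per face")
  vl <- vertex_region_labels(lib, spec)
  expect_length(vl, nrow(lib$vertices))
  expect_setequal(unique(vl), c("back", "flat_central", "flat_lateral"))
})

test_that("mean absolute deviation is invariant under a common rigid motion", {
  spec <- scanbody_spec(mesh_edge_length = 0.3)
  lib <- build_library_mesh(spec)
  em <- error_model(normal_offset_mean = -15, surface_noise_sd = 5,
                    manufacturing_tolerance_um = 0)
  scan <- simulate_scan(lib, em, seed = 9)
  f1 <- signed_deviation(scan, lib, sample_count = 2000, seed = 5)

  mov <- rigid_transform(rotation_about_axis(c(1, 1, 0), 25), c(4, -2, 7))
  lib2 <- lib
  lib2$vertices <- apply_transform(mov, lib$vertices)
  scan2 <- scan
  scan2$vertices <- apply_transform(mov, scan$vertices)
  f2 <- signed_deviation(scan2, lib2, sample_count = 2000, seed = 5)
  expect_equal(mean(abs(f2$signed_um)), mean(abs(f1$signed_um)),
               tolerance = 1e-9)
})

test_that("deviation fields export to CSV and PLY", {
  f <- field_from(c(2, -3, 0.5))
  f$x <- c(1, 2, 3); f$y <- f$x; f$z <- f$x
  csv <- withr::local_tempfile(fileext = ".csv")
  export_deviation_csv(f, csv)
  back <- read.csv(csv)
  expect_equal(back$signed_um, f$signed_um)
  expect_equal(back$class, c("outward", "inward", "none"))
  ply <- withr::local_tempfile(fileext = ".ply")
  export_deviation_ply(f, ply)
  expect_equal(trimws(readLines(ply, n = 1)), "ply")
})
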