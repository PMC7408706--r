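#' Colorimetric bin specification
#'
#' The deviation colour scale used for qualitative inspection: signed
#' deviations are rendered from -scale_max to +scale_max um, with a green
#' "no deviation" band between -green_band and +green_band um. Values beyond
#' the scale saturate in rendering but classification is unaffected.
#'
#' @param scale_max colour scale limit (um), default 50.
#' @param green_band half-width of the neutral band (um), default 1.
#' @export
color_bins <- function(scale_max = 50, green_band = 1) {
  if (!(green_band > 0 && green_band < scale_max))
    stop("require 0 < green_band < scale_max")
  structure(list(scale_max = scale_max, green_band = green_band),
            class = "color_bins")
}

#' Label reference faces by scanbody region
#'
#' Partitions the faces of a library mesh generated from a [scanbody_spec()]
#' into the three regions used for qualitative reporting: `flat_central` (the
#' middle third of each flat face's width), `flat_lateral` (the remainder of
#' the flat faces), and `back` (everything else: cylindrical shaft, chamfer,
#' caps). The partition is exhaustive and exclusive. For meshes not generated
#' from a spec, supply per-face labels yourself (`user_labels`).
#'
#' @param reference the library [triangle_mesh()].
#' @param spec the [scanbody_spec()] it was built from.
#' @param user_labels optional character vector of per-face labels overriding
#'   the geometric rule.
#' @return character vector of per-face labels.
#' @export
label_regions <- function(reference, spec, user_labels = NULL) {
  if (!is.null(user_labels)) {
    if (length(user_labels) != nrow(reference$faces))
      stop("user_labels must have one label per face")
    return(user_labels)
  }
  fn <- face_normals(reference)
  ce <- face_centroids(reference)
  lab <- rep("back", nrow(reference$faces))
  w <- spec$flat_face_width
  d_chord <- sqrt(spec$shaft_radius^2 - (w / 2)^2)
  for (th in flat_azimuths(spec)) {
    u <- c(cos(th), sin(th))            # outward direction of the flat
    tangent <- c(-sin(th), cos(th))     # in-face width direction
    is_flat <- abs(fn[, 1] * u[1] + fn[, 2] * u[2]) > 0.999 &
      abs(fn[, 3]) < 0.05 &
      (ce[, 1] * u[1] + ce[, 2] * u[2]) > d_chord - 0.05
    if (!any(is_flat)) next
    lat <- abs(ce[, 1] * tangent[1] + ce[, 2] * tangent[2])
    lab[is_flat & lat <= w / 6] <- "flat_central"
    lab[is_flat & lat > w / 6] <- "flat_lateral"
  }
  if (!any(lab == "flat_central") || !any(lab == "flat_lateral"))
    stop("labeling error: reference does not match the spec topology; ",
         "supply user_labels")
  lab
}

#' @rdname label_regions
#' @details `vertex_region_labels` maps the per-face partition onto vertices
#'   (boundary vertices resolve to the flat regions in preference to the
#'   back, and to `flat_central` over `flat_lateral`), as needed when error
#'   models displace vertices by region.
#' @export
vertex_region_labels <- function(reference, spec, user_labels = NULL) {
  fl <- label_regions(reference, spec, user_labels)
  vl <- rep("back", nrow(reference$vertices))
  for (lab in c("flat_lateral", "flat_central")) {
    idx <- unique(as.vector(reference$faces[fl == lab, ]))
    vl[idx] <- lab
  }
  vl
}

#' Signed deviation field between a registered scan and the reference
#'
#' Samples the scan surface (area-weighted, seeded), maps the samples into
#' the reference frame with `transform`, and computes for each the exact
#' distance to the nearest point of the reference surface, signed positive
#' when the sample lies on the outward-normal side of its nearest reference
#' face (outward deviation, "excess") and negative otherwise (inward,
#' "defect"). Distances are reported in micrometres. The reference library
#' file is the fixed frame, matching the convention that deviations describe
#' the scan relative to the CAD reference; set `direction =
#' "reference_to_scan"` to sample the reference against the scan surface
#' instead (sensitivity checks).
#'
#' @param scan the scan [triangle_mesh()].
#' @param reference the library [triangle_mesh()] or a [mesh_index()].
#' @param transform [rigid_transform()] mapping scan into reference frame.
#' @param sample_count number of surface samples.
#' @param seed sampling seed (reuse the ICP seed to sample identical points).
#' @param spec optional [scanbody_spec()]; when given, each sample is
#'   labelled with the region of its nearest reference face.
#' @param region_labels optional per-face labels for the reference (overrides
#'   `spec`).
#' @param direction which surface is sampled; the default samples the scan.
#' @return a `deviation_field`: data frame with columns `x, y, z` (mm, in the
#'   reference frame), `signed_um`, `region`.
#' @export
signed_deviation <- function(scan, reference, transform = rigid_transform(),
                             sample_count = 5000L, seed = 1L, spec = NULL,
                             region_labels = NULL,
                             direction = c("scan_to_reference",
                                           "reference_to_scan")) {
  direction <- match.arg(direction)
  idx <- if (inherits(reference, "mesh_index")) reference
         else mesh_index(reference)
  ref_mesh <- idx$mesh
  if (nrow(scan$faces) == 0 || nrow(ref_mesh$faces) == 0)
    stop("empty mesh")
  if (is.null(region_labels) && !is.null(spec))
    region_labels <- label_regions(ref_mesh, spec)

  if (direction == "scan_to_reference") {
    smp <- sample_surface(scan, sample_count, seed = seed)
    P <- apply_transform(transform, smp$points)
    res <- cp_query(idx$ptr, P)
    region <- if (is.null(region_labels)) rep(NA_character_, nrow(P))
              else region_labels[res$face]
    out <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3],
                      signed_um = res$signed_distance * 1000,
                      region = region, stringsAsFactors = FALSE)
  } else {
    # sample the reference, measure to the scan surface in the reference frame
    smp <- sample_surface(ref_mesh, sample_count, seed = seed)
    scan_in_ref <- scan
    scan_in_ref$vertices <- apply_transform(transform, scan$vertices)
    sidx <- mesh_index(scan_in_ref)
    res <- cp_query(sidx$ptr, smp$points)
    region <- if (is.null(region_labels)) rep(NA_character_, nrow(smp$points))
              else region_labels[smp$face]
    # sign relative to the reference's outward normal: a scan surface lying
    # outside the reference means the reference sample sees the scan on its
    # outward side, i.e. outward deviation is still positive
    rn <- face_normals(ref_mesh)[smp$face, , drop = FALSE]
    disp <- res$point - smp$points
    sgn <- ifelse(rowSums(disp * rn) >= 0, 1, -1)
    out <- data.frame(x = smp$points[, 1], y = smp$points[, 2],
                      z = smp$points[, 3],
                      signed_um = sgn * res$distance * 1000,
                      region = region, stringsAsFactors = FALSE)
  }
  attr(out, "reference") <- ref_mesh$name
  attr(out, "direction") <- direction
  class(out) <- c("deviation_field", "data.frame")
  out
}

#' Congruence summary of a deviation field
#'
#' The quantitative congruence statistics of one scan-reference
#' superimposition, computed on absolute deviations (the headline statistic)
#' with the signed mean retained for directionality: mean, SD (n-1
#' denominator), median, quartiles (linear interpolation), range, and a
#' normal-approximation 95% CI of the mean, all in um.
#'
#' @param field a `deviation_field` from [signed_deviation()].
#' @return an object of class `congruence_summary`.
#' @export
summarize_congruence <- function(field) {
  d <- field$signed_um
  n <- length(d)
  if (n < 2) stop("insufficient data: need at least 2 samples")
  a <- abs(d)
  q <- unname(quantile(a, c(0.25, 0.5, 0.75), type = 7))
  mean_abs <- mean(a)
  sd_abs <- sd(a)
  structure(list(mean_abs = mean_abs, sd_abs = sd_abs,
                 mean_signed = mean(d), median = q[2], q1_q3 = q[c(1, 3)],
                 range = range(a),
                 ci95 = mean_abs + c(-1, 1) * 1.96 * sd_abs / sqrt(n),
                 n_samples = n),
            class = "congruence_summary")
}

#' @exportS3Method base::print
print.congruence_summary <- function(x, ...) {
  cat(format_congruence(x), "\n")
  cat(sprintf("  median %.1f um; Q1-Q3 (%.1f-%.1f); range (%.1f-%.1f); 95%% CI (%.1f-%.1f); n = %d\n",
              x$median, x$q1_q3[1], x$q1_q3[2], x$range[1], x$range[2],
              x$ci95[1], x$ci95[2], x$n_samples))
  invisible(x)
}

#' @rdname summarize_congruence
#' @param x a `congruence_summary`.
#' @param digits decimals for the mean and SD.
#' @export
format_congruence <- function(x, digits = 0) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f μm"),
          x$mean_abs, x$sd_abs)
}

#' Colorimetric classification of a deviation field
#'
#' Classifies every sample into `outward` (beyond +green_band), `inward`
#' (below -green_band) or `none` (within the green band), and tabulates class
#' fractions overall and per region. Fractions sum to one.
#'
#' @param field a `deviation_field`.
#' @param bins a [color_bins()].
#' @return list: `class` (factor per sample), `overall` (named fractions),
#'   `by_region` (region x class fraction matrix, when regions are present).
#' @export
classify_bins <- function(field, bins = color_bins()) {
  cl <- ifelse(field$signed_um > bins$green_band, "outward",
               ifelse(field$signed_um < -bins$green_band, "inward", "none"))
  cl <- factor(cl, levels = c("inward", "none", "outward"))
  overall <- prop.table(table(cl))
  by_region <- NULL
  if (!all(is.na(field$region)))
    by_region <- prop.table(table(field$region, cl), margin = 1)
  list(class = cl, overall = overall, by_region = by_region)
}

#' Qualitative direction label
#'
#' The chromatic-predominance label of a field (or of one region): the class
#' with the largest sample fraction, with ties broken toward "no deviation".
#'
#' @param field a `deviation_field`.
#' @param bins a [color_bins()].
#' @param region optional region name; `NULL` uses all samples.
#' @return one of `"outward deviation"`, `"no deviation"`,
#'   `"inward deviation"`.
#' @export
direction_label <- function(field, bins = color_bins(), region = NULL) {
  d <- field
  if (!is.null(region)) {
    d <- field[!is.na(field$region) & field$region == region, , drop = FALSE]
    if (nrow(d) == 0) stop("empty region: ", region)
  }
  cl <- classify_bins(d, bins)$overall
  winners <- names(cl)[cl == max(cl)]
  lab <- if (length(winners) > 1) "none" else winners  # ties -> no deviation
  switch(lab, outward = "outward deviation", inward = "inward deviation",
         none = "no deviation")
}

#' Export a deviation field
#'
#' CSV export (x, y, z, signed_um, region, class) or ASCII PLY of the scan
#' samples with the signed deviation as a per-vertex scalar, for external
#' rendering of the colorimetric map.
#'
#' @param field a `deviation_field`.
#' @param path output file.
#' @param bins a [color_bins()] for the class column.
#' @export
export_deviation_csv <- function(field, path, bins = color_bins()) {
  df <- as.data.frame(field)
  df$class <- as.character(classify_bins(field, bins)$class)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_deviation_csv
#' @export
export_deviation_ply <- function(field, path) {
  v <- cbind(field$x, field$y, field$z)
  # point cloud: vertices with a scalar, no faces
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nrow(v)),
              "property float x", "property float y", "property float z",
              "property float quality",
              "element face 0",
              "property list uchar int vertex_indices", "end_header")
  lines <- sprintf("%.10g %.10g %.10g %.6g", v[, 1], v[, 2], v[, 3],
                   field$signed_um)
  writeLines(c(header, lines), path)
  invisible(path)
}
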