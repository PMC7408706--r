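#' Study configuration
#'
#' Bundles every knob of a simulate-register-deviate-summarise-stats study:
#' scanbody geometry, arch layout, scanner error profiles, replicate count,
#' ICP settings, colour bins and the master seed. Serialisable to YAML and
#' back without loss.
#'
#' @param spec a [scanbody_spec()].
#' @param layout an [arch_layout()].
#' @param profiles named list of [error_model()] scanner profiles.
#' @param n_models replicate scans per scanner.
#' @param icp an [icp_config()]; the default uses a reduced 1500-point sample
#'   per superimposition, which keeps a full five-scanner study tractable
#'   while leaving registration errors well below the deviations of interest.
#' @param bins a [color_bins()].
#' @param deviation_samples surface samples per deviation field.
#' @param landmark_noise_um SD of the simulated manual landmark picking
#'   error (um).
#' @param seed master seed.
#' @export
study_config <- function(spec = scanbody_spec(), layout = arch_layout(),
                         profiles = default_scanner_profiles(),
                         n_models = 10L,
                         icp = icp_config(sample_count = 1500L),
                         bins = color_bins(), deviation_samples = 4000L,
                         landmark_noise_um = 100, seed = 1L) {
  structure(list(spec = spec, layout = layout, profiles = profiles,
                 n_models = as.integer(n_models), icp = icp, bins = bins,
                 deviation_samples = as.integer(deviation_samples),
                 landmark_noise_um = landmark_noise_um,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  y <- strip(config)
  # poses are derived from positions + tilts; matrices serialise as row lists
  y$layout <- list(positions = lapply(seq_len(6), function(i)
    as.numeric(config$layout$positions[i, ])),
    tilt_deg = as.numeric(config$layout$tilt_deg))
  # named vectors must go out as maps, not bare sequences
  y$profiles <- lapply(y$profiles, function(p) {
    if (!is.null(p$normal_offset_by_region))
      p$normal_offset_by_region <- as.list(p$normal_offset_by_region)
    p
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- lapply(y$profiles, function(p) {
    if (!is.null(p$normal_offset_by_region))
      p$normal_offset_by_region <- unlist(p$normal_offset_by_region)
    do.call(error_model, p)
  })
  study_config(
    spec = do.call(scanbody_spec, y$spec),
    layout = arch_layout(positions = do.call(rbind, y$layout$positions),
                         tilt_deg = unlist(y$layout$tilt_deg)),
    profiles = profiles,
    n_models = y$n_models,
    icp = do.call(icp_config, y$icp),
    bins = do.call(color_bins, y$bins),
    deviation_samples = y$deviation_samples,
    landmark_noise_um = y$landmark_noise_um,
    seed = y$seed)
}

# Three well-separated, non-collinear reference landmarks on the library:
# middle of the flat face, top of the shaft on the back side, bottom edge.
library_landmarks <- function(library_mesh, spec) {
  r <- spec$shaft_radius
  h <- spec$height
  d <- sqrt(r^2 - (spec$flat_face_width / 2)^2)
  targets <- rbind(c(d, 0, h / 2), c(-r, 0, h - spec$top_chamfer - 0.5),
                   c(0, r, 0.5))
  idx <- apply(targets, 1, function(p) {
    which.min(colSums((t(library_mesh$vertices) - p)^2))
  })
  library_mesh$vertices[idx, , drop = FALSE]
}

#' Run a full synthetic congruence study
#'
#' For every (scanner profile, model replicate, scanbody position):
#' simulates the scan at its arch pose, performs the two-stage
#' superimposition (noisy three-point landmark alignment, then robust
#' point-to-plane ICP with the configured minimum iteration count), computes
#' the signed deviation field against the library reference, and records the
#' quantitative congruence summary plus the per-region qualitative direction
#' labels. Fully deterministic given the master seed.
#'
#' @param config a [study_config()].
#' @param progress print one line per scanner.
#' @return a `study_bundle`: `table` (the [deviation_table()]),
#'   `qualitative` (per superimposition and region direction labels), `log`
#'   (per superimposition iterations and final RMS), `stats` (descriptives,
#'   scanner estimates and contrasts, scanbody contrasts, Friedman tests,
#'   biclustering of cell means and SDs), and `config`.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  spec <- config$spec
  library_mesh <- build_library_mesh(spec)
  idx <- mesh_index(library_mesh)
  labs <- label_regions(library_mesh, spec)
  vlabs <- vertex_region_labels(library_mesh, spec)
  ref_lm <- library_landmarks(library_mesh, spec)
  part_draw <- with_seed(config$seed, runif(6L, -1, 1))
  regions <- c("flat_central", "flat_lateral", "back")

  rows <- list(); qual <- list(); logs <- list()
  for (s in seq_along(config$profiles)) {
    scanner <- names(config$profiles)[s]
    prof <- config$profiles[[s]]
    if (progress) message("scanner ", scanner)
    for (m in seq_len(config$n_models)) {
      for (k in 1:6) {
        sb <- paste0("S", k)
        sc_seed <- derive_seed(config$seed, s, m, k)
        aux_seed <- sc_seed %% 2147400000L + 7L
        prof_k <- prof
        prof_k$manufacturing_offset_um <-
          part_draw[k] * prof$manufacturing_tolerance_um
        scan <- simulate_scan(library_mesh, prof_k, seed = sc_seed,
                              region_labels = vlabs)
        pose <- config$layout$poses[[sb]]
        total <- compose_transform(pose, attr(scan, "applied_transform"))
        scan$vertices <- apply_transform(pose, scan$vertices)

        scan_lm <- apply_transform(total, ref_lm) +
          with_seed(aux_seed,
                    matrix(rnorm(9, 0, config$landmark_noise_um * 1e-3), 3))
        init <- landmark_align(scan_lm, ref_lm)
        icp_cfg <- config$icp
        icp_cfg$seed <- aux_seed + 1L
        reg <- tryCatch(
          icp_point_to_plane(scan, idx, init, icp_cfg),
          error = function(e) stop("registration failed for (", scanner,
                                   ", model ", m, ", ", sb, "): ",
                                   conditionMessage(e)))
        field <- signed_deviation(scan, idx, reg$transform,
                                  sample_count = config$deviation_samples,
                                  seed = aux_seed + 2L,
                                  region_labels = labs)
        summ <- summarize_congruence(field)
        rows[[length(rows) + 1L]] <-
          data.frame(scanner = scanner, sb = sb, model = m,
                     mean_abs_dev_um = summ$mean_abs,
                     mean_signed_um = summ$mean_signed,
                     stringsAsFactors = FALSE)
        for (rg in regions)
          qual[[length(qual) + 1L]] <-
            data.frame(scanner = scanner, sb = sb, model = m, region = rg,
                       label = direction_label(field, config$bins, rg),
                       stringsAsFactors = FALSE)
        logs[[length(logs) + 1L]] <-
          data.frame(scanner = scanner, sb = sb, model = m,
                     iterations = reg$iterations,
                     final_rms_um = reg$trace$rms_um[reg$iterations],
                     converged = reg$converged)
      }
    }
  }
  full <- do.call(rbind, rows)
  tab <- deviation_table(full[c("scanner", "sb", "model", "mean_abs_dev_um")])
  qual <- do.call(rbind, qual)
  logs <- do.call(rbind, logs)

  stats <- list(
    descriptives = describe_cells(tab),
    descriptives_formatted = describe_cells(tab, format = TRUE),
    scanner_estimates = scanner_estimates(tab),
    scanner_contrasts = if (length(config$profiles) >= 2)
      scanner_contrasts(tab) else NULL,
    sb_contrasts = sb_contrasts(tab),
    friedman = if (config$n_models >= 2) friedman_by_scanner(tab) else NULL,
    bicluster_means = if (length(config$profiles) >= 2)
      bicluster(cell_mean_matrix(tab)) else NULL,
    bicluster_sds = if (length(config$profiles) >= 2 && config$n_models >= 2)
      bicluster(cell_sd_matrix(tab)) else NULL)

  structure(list(table = tab, signed = full, qualitative = qual, log = logs,
                 stats = stats, config = config),
            class = "study_bundle")
}

cell_sd_matrix <- function(table) {
  agg <- stats::aggregate(mean_abs_dev_um ~ scanner + sb, data = table, sd)
  scanners <- unique(table$scanner)
  sbs <- sort(unique(table$sb))
  m <- matrix(NA_real_, length(scanners), length(sbs),
              dimnames = list(scanners, sbs))
  m[cbind(match(agg$scanner, scanners), match(agg$sb, sbs))] <-
    agg$mean_abs_dev_um
  m
}

# fraction -> predominance notation
predominance_symbol <- function(f) {
  ifelse(f >= 2 / 3, "+++", ifelse(f >= 1 / 3, "++", "+"))
}

#' Qualitative predominance table
#'
#' For each scanner and scanbody region, the fraction of superimpositions
#' whose chromatic predominance was outward / none / inward, expressed in the
#' conventional `+` / `++` / `+++` notation (thirds of the superimpositions).
#'
#' @param bundle a `study_bundle` from [run_study()].
#' @return data frame: scanner, deviation, flat_central, flat_lateral, back.
#' @export
predominance_table <- function(bundle) {
  q <- bundle$qualitative
  labels <- c("outward deviation", "no deviation", "inward deviation")
  regions <- c("flat_central", "flat_lateral", "back")
  out <- list()
  for (sc in unique(q$scanner)) {
    for (lb in labels) {
      row <- list(scanner = sc, deviation = lb)
      for (rg in regions) {
        d <- q[q$scanner == sc & q$region == rg, ]
        row[[rg]] <- predominance_symbol(mean(d$label == lb))
      }
      out[[length(out) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a human-readable study report
#'
#' Emits the study's tabular results as CSV files (descriptives, scanner
#' contrasts, scanbody contrast estimates and p-values, Friedman tests,
#' qualitative predominance, the raw deviation table and the registration
#' log) plus a markdown summary. A bundle with missing statistics still
#' produces the descriptive part, with a warning.
#'
#' @param bundle a `study_bundle` from [run_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
report_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  w(as.data.frame(bundle$table), "deviation_table.csv")
  w(bundle$log, "registration_log.csv")
  st <- bundle$stats
  md <- c("# Scanbody congruence study report", "")
  warned <- FALSE
  if (is.null(st)) {
    warning("bundle has no statistics; report limited to descriptives")
    warned <- TRUE
    st <- list(descriptives = describe_cells(bundle$table),
               descriptives_formatted = describe_cells(bundle$table,
                                                       format = TRUE))
  }
  w(st$descriptives, "cell_descriptives.csv")
  write.csv(st$descriptives_formatted,
            file.path(dir, "cell_descriptives_formatted.csv"))
  if (!is.null(st$scanner_estimates)) {
    w(st$scanner_estimates, "scanner_estimates.csv")
    w(st$sb_contrasts, "sb_contrasts.csv")
    if (!is.null(st$friedman)) w(st$friedman, "friedman_models.csv")
    est <- st$scanner_estimates
    md <- c(md, "## Scanner estimates (mean absolute deviation, um)", "",
            sprintf("- %s: %.1f [%.1f; %.1f]", est$scanner, est$estimate,
                    est$ci_lo, est$ci_hi), "")
    if (!is.null(st$scanner_contrasts)) {
      w(st$scanner_contrasts, "scanner_contrasts.csv")
      sig <- st$scanner_contrasts[st$scanner_contrasts$significant, ]
      md <- c(md, "## Significant scanner contrasts (alpha = 0.01)", "",
              if (nrow(sig)) sprintf("- %s: %.2f um (p = %.4g)", sig$pair,
                                     sig$estimate, sig$p_adjusted)
              else "- none", "")
    }
  } else if (!warned) {
    warning("bundle statistics incomplete; report limited to descriptives")
  }
  pt <- predominance_table(bundle)
  w(pt, "direction_predominance.csv")
  md <- c(md, "## Qualitative direction predominance", "",
          paste("scanner | deviation | flat_central | flat_lateral | back"),
          paste("--- | --- | --- | --- | ---"),
          sprintf("%s | %s | %s | %s | %s", pt$scanner, pt$deviation,
                  pt$flat_central, pt$flat_lateral, pt$back), "")
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
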