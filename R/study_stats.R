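#' Long-format study deviation table
#'
#' The input to the statistical battery: one row per superimposition, with
#' the scanner label, scanbody position (S1-S6), model replicate index and
#' the mean absolute deviation of that superimposition in um. Keys must be
#' unique and deviations positive.
#'
#' @param df data frame with columns `scanner`, `sb`, `model`,
#'   `mean_abs_dev_um`.
#' @return a validated `deviation_table` (data frame subclass).
#' @export
deviation_table <- function(df) {
  need <- c("scanner", "sb", "model", "mean_abs_dev_um")
  if (!all(need %in% names(df)))
    stop("deviation table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df[c("scanner", "sb", "model")]))
    stop("(scanner, sb, model) keys must be unique")
  if (any(!is.finite(df$mean_abs_dev_um) | df$mean_abs_dev_um < 0))
    stop("mean_abs_dev_um must be positive and finite")
  class(df) <- c("deviation_table", "data.frame")
  df
}

#' @rdname deviation_table
#' @param path CSV file with the four columns above.
#' @export
read_deviation_table <- function(path) {
  deviation_table(read.csv(path, stringsAsFactors = FALSE))
}

# per-(scanner, sb) cell means as a scanner x sb matrix
cell_mean_matrix <- function(table) {
  agg <- stats::aggregate(mean_abs_dev_um ~ scanner + sb, data = table, mean)
  scanners <- unique(table$scanner)
  sbs <- sort(unique(table$sb))
  m <- matrix(NA_real_, length(scanners), length(sbs),
              dimnames = list(scanners, sbs))
  m[cbind(match(agg$scanner, scanners), match(agg$sb, sbs))] <-
    agg$mean_abs_dev_um
  m
}

#' Descriptive statistics per scanner-scanbody cell
#'
#' Mean, SD, median and quartiles (linear interpolation) of the mean absolute
#' deviations in every (scanner, scanbody) cell; the table-shaped matrix of
#' formatted cells is available via `format = TRUE`, printing each cell as
#' `"mean (SD); median; (Q1-Q3)"`. Cells with fewer than 2 replicates are
#' reported as absent (NA), not imputed.
#'
#' @param table a [deviation_table()].
#' @param format if `TRUE`, return a scanner x sb character matrix of
#'   formatted cells instead of the long data frame.
#' @export
describe_cells <- function(table, format = FALSE) {
  sp <- split(table$mean_abs_dev_um, list(table$scanner, table$sb),
              drop = FALSE, sep = "\r")
  rows <- lapply(names(sp), function(k) {
    v <- sp[[k]]
    key <- strsplit(k, "\r", fixed = TRUE)[[1]]
    if (length(v) < 2)
      return(data.frame(scanner = key[1], sb = key[2], n = length(v),
                        mean = NA_real_, sd = NA_real_, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_))
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    data.frame(scanner = key[1], sb = key[2], n = length(v),
               mean = mean(v), sd = sd(v), median = q[2], q1 = q[1],
               q3 = q[3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$scanner, unique(table$scanner)), out$sb), ]
  rownames(out) <- NULL
  if (!format) return(out)
  scanners <- unique(out$scanner)
  sbs <- sort(unique(out$sb))
  m <- matrix(NA_character_, length(scanners), length(sbs),
              dimnames = list(scanners, sbs))
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    m[r$scanner, r$sb] <- if (is.na(r$mean)) NA_character_ else
      sprintf("%.1f (%.1f); %.1f; (%.1f–%.1f)",
              r$mean, r$sd, r$median, r$q1, r$q3)
  }
  m
}

#' Flag outlying observations
#'
#' Within-cell outlier flags, excluded from parametric estimation but kept in
#' descriptives and rank tests. The default rule is a leave-one-out z-score:
#' each observation is standardised against the mean and SD of the other
#' replicates in its cell (a plain z-score against the full cell can never
#' exceed `(n-1)/sqrt(n)` and would mask exactly the gross outliers the rule
#' exists for).
#'
#' @param table a [deviation_table()].
#' @param rule `"z"`, `"none"` or `"manual"`.
#' @param z_threshold flag when `|z| >` this (default 3).
#' @param manual data frame with columns `scanner`, `sb`, `model` listing the
#'   rows to flag (for `rule = "manual"`).
#' @return logical vector, one flag per row of `table`.
#' @export
flag_outliers <- function(table, rule = c("z", "none", "manual"),
                          z_threshold = 3, manual = NULL) {
  rule <- match.arg(rule)
  n <- nrow(table)
  if (rule == "none") return(rep(FALSE, n))
  if (rule == "manual") {
    if (is.null(manual)) stop("manual rule needs a manual list")
    key <- paste(table$scanner, table$sb, table$model)
    return(key %in% paste(manual$scanner, manual$sb, manual$model))
  }
  flags <- rep(FALSE, n)
  for (idx in split(seq_len(n), list(table$scanner, table$sb), drop = TRUE)) {
    v <- table$mean_abs_dev_um[idx]
    if (length(v) < 3) next
    for (j in seq_along(v)) {
      rest <- v[-j]
      s <- sd(rest)
      if (s > 0 && abs(v[j] - mean(rest)) / s > z_threshold)
        flags[idx[j]] <- TRUE
    }
  }
  flags
}

#' Balanced per-scanner estimates
#'
#' Scanner-level mean absolute deviation estimates under the balanced
#' hierarchical design: each scanner's estimate is the unweighted mean of its
#' scanbody cell means (for a balanced design this coincides with the
#' mixed-model point estimate), with a t-based 95% CI from the between-
#' scanbody variance of the cell means.
#'
#' @param table a [deviation_table()].
#' @param exclude optional logical flags (e.g. from [flag_outliers()]);
#'   flagged rows are dropped before estimation.
#' @return data frame: scanner, estimate, se, ci_lo, ci_hi, n_sb.
#' @export
scanner_estimates <- function(table, exclude = NULL) {
  if (!is.null(exclude)) table <- table[!exclude, , drop = FALSE]
  m <- cell_mean_matrix(table)
  if (any(rowSums(!is.na(m)) < 2))
    stop("estimation error: every scanner needs at least 2 scanbody cells")
  est <- rowMeans(m, na.rm = TRUE)
  nsb <- rowSums(!is.na(m))
  se <- apply(m, 1, sd, na.rm = TRUE) / sqrt(nsb)
  hw <- qt(0.975, nsb - 1) * se
  data.frame(scanner = rownames(m), estimate = est, se = se,
             ci_lo = est - hw, ci_hi = est + hw, n_sb = nsb,
             row.names = NULL)
}

#' Tukey-adjusted pairwise scanner contrasts
#'
#' All pairwise differences of the balanced scanner estimates, with p-values
#' and simultaneous confidence limits from the studentized-range distribution.
#' The error term is the between-scanbody variance of the cell means, pooled
#' across scanners (the unit of analysis for scanner comparisons in the
#' balanced two-level design). Decisions are flagged at alpha = 0.01.
#'
#' @param table a [deviation_table()].
#' @param exclude optional logical row flags, as in [scanner_estimates()].
#' @param conf_level confidence level of the simultaneous intervals.
#' @param alpha significance level for the `significant` flag.
#' @return data frame: pair, estimate, ci_lo, ci_hi, p_adjusted, significant.
#' @export
scanner_contrasts <- function(table, exclude = NULL, conf_level = 0.95,
                              alpha = 0.01) {
  if (!is.null(exclude)) table <- table[!exclude, , drop = FALSE]
  m <- cell_mean_matrix(table)
  k <- nrow(m)
  if (k < 2) stop("need at least 2 scanners")
  est <- rowMeans(m, na.rm = TRUE)
  nsb <- rowSums(!is.na(m))
  vars <- apply(m, 1, stats::var, na.rm = TRUE)
  df <- sum(nsb - 1)
  mse <- sum(vars * (nsb - 1)) / df     # pooled between-SB variance
  se_mean <- sqrt(mse / mean(nsb))
  pairs <- combn(rownames(m), 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- est[a] - est[b]
    p <- if (se_mean == 0) as.numeric(d != 0) * 0 + (d == 0) else
      ptukey(abs(d) / se_mean, nmeans = k, df = df, lower.tail = FALSE)
    hw <- if (se_mean == 0) 0 else
      qtukey(conf_level, nmeans = k, df = df) * se_mean
    data.frame(pair = paste(a, "-", b), estimate = unname(d),
               ci_lo = unname(d - hw), ci_hi = unname(d + hw),
               p_adjusted = unname(p), significant = unname(p < alpha))
  })
  do.call(rbind, out)
}

#' Within-scanner scanbody contrasts (two-way layout)
#'
#' For each scanner, all 15 pairwise differences between scanbody cell means,
#' Tukey-adjusted within the 15-pair family (6 means) using the within-cell
#' residual variance of the two-way scanner x scanbody layout with
#' interaction. With a single replicate per cell the point estimates are
#' still returned and p-values/CIs are NA.
#'
#' @param table a [deviation_table()].
#' @param exclude optional logical row flags.
#' @param conf_level confidence level.
#' @param alpha significance level for the `significant` flag.
#' @return data frame: scanner, pair, estimate, ci_lo, ci_hi, p_adjusted,
#'   significant.
#' @export
sb_contrasts <- function(table, exclude = NULL, conf_level = 0.95,
                         alpha = 0.01) {
  if (!is.null(exclude)) table <- table[!exclude, , drop = FALSE]
  m <- cell_mean_matrix(table)
  sbs <- colnames(m)
  # pooled within-cell variance across every cell (the ANOVA residual)
  sp <- split(table$mean_abs_dev_um, list(table$scanner, table$sb),
              drop = TRUE)
  ns <- vapply(sp, length, 1L)
  df <- sum(pmax(ns - 1L, 0L))
  mse <- if (df > 0)
    sum(vapply(sp, function(v) if (length(v) > 1) stats::var(v) * (length(v) - 1) else 0,
               1.0)) / df else NA_real_
  n_rep <- mean(ns)
  se_mean <- if (df > 0) sqrt(mse / n_rep) else NA_real_
  # S6-S5, S6-S4, ..., S2-S1 ordering: higher-numbered position first
  pairs <- combn(rev(sbs), 2)
  out <- list()
  for (sc in rownames(m)) {
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1, i]; b <- pairs[2, i]
      d <- m[sc, a] - m[sc, b]
      if (!is.na(se_mean) && se_mean > 0) {
        p <- ptukey(abs(d) / se_mean, nmeans = length(sbs), df = df,
                    lower.tail = FALSE)
        hw <- qtukey(conf_level, nmeans = length(sbs), df = df) * se_mean
      } else {
        p <- NA_real_; hw <- NA_real_
      }
      out[[length(out) + 1L]] <-
        data.frame(scanner = sc, pair = paste(a, "-", b), estimate = unname(d),
                   ci_lo = unname(d - hw), ci_hi = unname(d + hw),
                   p_adjusted = unname(p),
                   significant = unname(!is.na(p) & p < alpha))
    }
  }
  do.call(rbind, out)
}

#' Friedman rank tests across models, by scanner
#'
#' For each scanner, compares the model replicates with the scanbody position
#' as the blocking variable (complete blocks required), then Holm-adjusts the
#' p-values across the scanner family. Rank ties within blocks are handled by
#' average ranks.
#'
#' @param table a [deviation_table()].
#' @return data frame: scanner, statistic, df, p_raw, p_holm.
#' @export
friedman_by_scanner <- function(table) {
  scanners <- unique(table$scanner)
  if (length(unique(table$model)) < 2)
    stop("Friedman test needs at least 2 model replicates")
  res <- lapply(scanners, function(sc) {
    d <- table[table$scanner == sc, ]
    tab <- table(d$sb, d$model)
    if (any(tab != 1L)) {
      miss <- which(tab == 0L, arr.ind = TRUE)
      stop("incomplete blocks for scanner ", sc, ": missing ",
           paste(sprintf("(%s, model %s)", rownames(tab)[miss[, 1]],
                         colnames(tab)[miss[, 2]]), collapse = ", "))
    }
    ft <- friedman.test(d$mean_abs_dev_um, groups = factor(d$model),
                        blocks = factor(d$sb))
    stat <- unname(ft$statistic)
    p <- ft$p.value
    if (is.nan(stat)) {  # every block fully tied: no evidence at all
      stat <- 0
      p <- 1
    }
    data.frame(scanner = sc, statistic = stat,
               df = unname(ft$parameter), p_raw = p)
  })
  out <- do.call(rbind, res)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  out
}

#' Agglomerative hierarchical biclustering
#'
#' Independent agglomerative clustering of the rows and the columns of a
#' scanner x scanbody summary matrix (cell means or cell SDs). Euclidean
#' distance with average linkage by default; both are configurable.
#'
#' @param m numeric matrix with dimnames (e.g. from [cell_mean_matrix] via
#'   [describe_cells()]).
#' @param linkage linkage method passed to [stats::hclust()].
#' @param metric distance method passed to [stats::dist()].
#' @return a `bicluster_result`: `row_order` and `col_order` (label
#'   permutations) and the two `hclust` trees.
#' @export
bicluster <- function(m, linkage = "average", metric = "euclidean") {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("biclustering requires a complete finite matrix")
  rh <- hclust(dist(m, method = metric), method = linkage)
  ch <- hclust(dist(t(m), method = metric), method = linkage)
  structure(list(row_order = rownames(m)[rh$order],
                 col_order = colnames(m)[ch$order],
                 row_hclust = rh, col_hclust = ch),
            class = "bicluster_result")
}

#' Simulate a null study table
#'
#' Deviation tables under the null hypothesis of identical scanners: every
#' (scanner, scanbody) cell draws its level from the same distribution (a
#' cell-level effect standing for scanner-scanbody interaction variability,
#' plus replicate noise), so any detected scanner difference is a false
#' positive. Used to audit the Type-I error of the contrast machinery.
#'
#' @param n_scanners,n_models,n_sb design size.
#' @param mu grand mean (um).
#' @param cell_sd SD of the per-cell level (um).
#' @param resid_sd replicate SD within cells (um).
#' @param seed integer seed.
#' @return a [deviation_table()].
#' @export
simulate_null_table <- function(n_scanners = 3, n_models = 5, n_sb = 6,
                                mu = 30, cell_sd = 3, resid_sd = 3,
                                seed = 1L) {
  with_seed(seed, {
    g <- expand.grid(model = seq_len(n_models),
                     sb = paste0("S", seq_len(n_sb)),
                     scanner = paste0("scanner", seq_len(n_scanners)),
                     stringsAsFactors = FALSE)
    cell <- paste(g$scanner, g$sb)
    lev <- setNames(rnorm(length(unique(cell)), mu, cell_sd), unique(cell))
    g$mean_abs_dev_um <- pmax(0.1, lev[cell] + rnorm(nrow(g), 0, resid_sd))
    deviation_table(g)
  })
}

#' Empirical Type-I error of the Tukey scanner contrasts
#'
#' Runs [scanner_contrasts()] on `n_studies` null tables and returns the
#' fraction of pairwise contrasts declared significant at `alpha`.
#'
#' @param n_studies number of simulated null studies.
#' @param alpha significance level.
#' @param seed master seed.
#' @inheritParams simulate_null_table
#' @export
tukey_null_rate <- function(n_studies = 500, alpha = 0.01, n_scanners = 3,
                            n_models = 5, seed = 1L) {
  hits <- 0L
  total <- 0L
  for (i in seq_len(n_studies)) {
    tbl <- simulate_null_table(n_scanners = n_scanners, n_models = n_models,
                               seed = derive_seed(seed, 1L, i, 1L))
    ct <- scanner_contrasts(tbl, alpha = alpha)
    hits <- hits + sum(ct$p_adjusted < alpha)
    total <- total + nrow(ct)
  }
  hits / total
}

#' Bundled five-scanner benchmark cell statistics
#'
#' Per-(scanner, scanbody) descriptive statistics (mean, SD, median,
#' quartiles of the mean absolute deviations, in um) from a published in
#' vitro benchmark of five intraoral scanners on a six-implant edentulous
#' model, shipped as a plain-text table. Useful as a realistic input for the
#' balanced estimators and as the worked example of the statistics module.
#'
#' @return data frame: scanner, sb, mean, sd, median, q1, q3.
#' @export
ios_cell_stats <- function() {
  read.csv(system.file("extdata", "ios_cell_stats.csv", package = "scanbody",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

#' @rdname ios_cell_stats
#' @details `cell_stats_matrix` reshapes the `mean` or `sd` column into a
#'   scanner x sb matrix suitable for [scanner_estimates()] workflows and
#'   [bicluster()].
#' @param stats a data frame from [ios_cell_stats()].
#' @param value which statistic to spread.
#' @export
cell_stats_matrix <- function(stats = ios_cell_stats(),
                              value = c("mean", "sd")) {
  value <- match.arg(value)
  scanners <- unique(stats$scanner)
  sbs <- sort(unique(stats$sb))
  m <- matrix(NA_real_, length(scanners), length(sbs),
              dimnames = list(scanners, sbs))
  m[cbind(match(stats$scanner, scanners), match(stats$sb, sbs))] <-
    stats[[value]]
  m
}

#' @rdname ios_cell_stats
#' @details `table_from_cell_means` expands a scanner x sb matrix of cell
#'   means into a one-replicate-per-cell [deviation_table()]; under the
#'   balanced identity the scanner estimates and all contrast point estimates
#'   computed from it equal those of the full data.
#' @param m scanner x sb numeric matrix of cell means.
#' @export
table_from_cell_means <- function(m) {
  g <- expand.grid(scanner = rownames(m), sb = colnames(m),
                   stringsAsFactors = FALSE)
  g$model <- 1L
  g$mean_abs_dev_um <- m[cbind(g$scanner, g$sb)]
  deviation_table(g)
}
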