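table2_means <- function() cell_stats_matrix(ios_cell_stats(), "mean")

test_that("cell descriptives match hand-computed statistics and formatting", {
  vals <- 20:29
  tbl <- deviation_table(data.frame(scanner = "A", sb = "S1",
                                    model = 1:10, mean_abs_dev_um = vals))
  d <- describe_cells(tbl)
  expect_equal(d$mean, 24.5)
  expect_equal(d$median, unname(quantile(vals, 0.5)))
  expect_equal(d$sd, sd(vals))
  fm <- describe_cells(tbl, format = TRUE)
  expect_equal(fm["A", "S1"],
               sprintf("%.1f (%.1f); %.1f; (%.1f–%.1f)", mean(vals), sd(vals),
                       median(vals), quantile(vals, 0.25),
                       quantile(vals, 0.75)))
  # a single-replicate cell is reported absent, not imputed
  one <- deviation_table(data.frame(scanner = "A", sb = c("S1", "S2"),
                                    model = 1L, mean_abs_dev_um = c(25, 30)))
  expect_true(all(is.na(describe_cells(one)$mean)))
})

test_that("outlier flags follow the leave-one-out z rule, none, and manual", {
  set.seed(2)
  base <- data.frame(scanner = "A", sb = "S1", model = 1:10,
                     mean_abs_dev_um = c(30, 31, 32, 33, 31, 30, 32, 31, 33, 90))
  tbl <- deviation_table(base)
  fl <- flag_outliers(tbl, rule = "z")
  expect_equal(which(fl), 10L)
  expect_equal(sum(flag_outliers(tbl, rule = "none")), 0L)
  fl2 <- flag_outliers(tbl, rule = "manual",
                       manual = data.frame(scanner = "A", sb = "S1",
                                           model = 7))
  expect_equal(which(fl2), 7L)
})

test_that("balanced scanner estimates equal the mean of the cell means", {
  m <- table2_means()
  tbl <- table_from_cell_means(m)
  est <- scanner_estimates(tbl)
  expect_equal(est$estimate[est$scanner == "PRIMESCAN"], 25.5,
               tolerance = 1e-9)
  expect_equal(est$estimate[est$scanner == "Emerald S"], 38.3,
               tolerance = 1e-9)
  expect_equal(est$estimate, unname(rowMeans(m)), tolerance = 1e-12)

  # all cells equal: estimate is that constant with a zero-width CI
  flat <- table_from_cell_means(matrix(27, 2, 6,
                                       dimnames = list(c("a", "b"),
                                                       paste0("S", 1:6))))
  ef <- scanner_estimates(flat)
  expect_equal(ef$estimate, c(27, 27))
  expect_equal(ef$ci_lo, ef$ci_hi)
})

test_that("Tukey scanner contrasts reproduce the benchmark differences", {
  tbl <- table_from_cell_means(table2_means())
  ct <- scanner_contrasts(tbl)
  want <- c("PRIMESCAN - CS 3700" = -1.58,
            "PRIMESCAN - MEDIT i-500" = -4.37,
            "PRIMESCAN - Emerald S" = -12.80,
            "CS 3700 - MEDIT i-500" = -2.78,
            "CS 3700 - Emerald S" = -11.22,
            "MEDIT i-500 - Emerald S" = -8.43)
  for (pair in names(want))
    expect_equal(round(ct$estimate[ct$pair == pair], 2), unname(want[pair]))

  # antisymmetry under reversed pair orientation
  rev_tbl <- tbl[nrow(tbl):1, ]
  class(rev_tbl) <- class(tbl)
  ct2 <- scanner_contrasts(rev_tbl)
  a <- ct$estimate[ct$pair == "PRIMESCAN - Emerald S"]
  b <- ct2$estimate[ct2$pair == "Emerald S - PRIMESCAN"]
  expect_equal(a, -b)

  # two identical scanners: zero difference, p = 1
  same <- table_from_cell_means(matrix(rep(table2_means()[1, ], each = 2),
                                       2, 6,
                                       dimnames = list(c("x", "y"),
                                                       paste0("S", 1:6))))
  cs <- scanner_contrasts(same)
  expect_equal(cs$estimate, 0)
  expect_equal(cs$p_adjusted, 1)
})

test_that("Tukey-adjusted p-values never undercut unadjusted ones", {
  for (seed in 1:20) {
    tbl <- simulate_null_table(n_scanners = 4, n_models = 3, seed = seed)
    ct <- scanner_contrasts(tbl)
    m <- scanbody:::cell_mean_matrix(tbl)
    vars <- apply(m, 1, var)
    df <- sum(rep(ncol(m) - 1, nrow(m)))
    se_diff <- sqrt(2 * mean(vars) / ncol(m))
    for (i in seq_len(nrow(ct))) {
      pr <- strsplit(ct$pair[i], " - ")[[1]]
      d <- mean(m[pr[1], ]) - mean(m[pr[2], ])
      p_unadj <- 2 * pt(-abs(d) / se_diff, df)
      expect_gte(ct$p_adjusted[i] + 1e-12, p_unadj)
    }
  }
})

test_that("within-scanner scanbody contrasts equal cell-mean differences", {
  tbl <- table_from_cell_means(table2_means())
  sc <- sb_contrasts(tbl)
  expect_equal(round(sc$estimate[sc$scanner == "PRIMESCAN" &
                                   sc$pair == "S3 - S2"], 2), 8.40)
  expect_equal(round(sc$estimate[sc$scanner == "Emerald S" &
                                   sc$pair == "S4 - S2"], 2), 17.40)
  expect_equal(nrow(sc), 5 * 15)
  expect_true(all(is.na(sc$p_adjusted)))  # single replicate: no error term

  # with replicates the residual error term kicks in and p-values appear
  set.seed(3)
  g <- expand.grid(scanner = c("A", "B"), sb = paste0("S", 1:6), model = 1:4,
                   stringsAsFactors = FALSE)
  g$mean_abs_dev_um <- 30 + (g$sb == "S3") * 10 + rnorm(nrow(g), 0, 1)
  rep_tbl <- deviation_table(g)
  sc2 <- sb_contrasts(rep_tbl)
  expect_true(all(is.finite(sc2$p_adjusted)))
  s3_rows <- sc2[grepl("S3", sc2$pair), ]
  expect_true(all(s3_rows$significant))
})

test_that("Friedman battery matches the closed form and Holm arithmetic", {
  # forced ranks (1, 2, 3) in every one of 3 blocks: chi2 = 6, p ~ 0.0498
  g <- expand.grid(sb = paste0("S", 1:3), model = 1:3,
                   stringsAsFactors = FALSE)
  g$scanner <- "A"
  g$mean_abs_dev_um <- 10 + g$model + 0.1 * as.integer(factor(g$sb))
  fr <- friedman_by_scanner(deviation_table(g))
  expect_equal(fr$statistic, 6)
  expect_equal(fr$df, 2)
  expect_equal(fr$p_raw, 1 - pchisq(6, 2), tolerance = 1e-9)
  expect_equal(fr$p_raw, 0.0498, tolerance = 1e-3)

  # identical models within blocks: statistic 0, p = 1
  g0 <- g
  g0$mean_abs_dev_um <- 10 + 0.1 * as.integer(factor(g0$sb))
  fr0 <- friedman_by_scanner(deviation_table(g0))
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p_raw, 1)

  # invariance under strictly monotone transforms of the observations
  gm <- g
  gm$mean_abs_dev_um <- exp(g$mean_abs_dev_um / 5)
  expect_equal(friedman_by_scanner(deviation_table(gm))$statistic,
               fr$statistic)

  # Holm adjustment across the scanner family matches the oracle
  set.seed(11)
  many <- do.call(rbind, lapply(c("A", "B", "C"), function(sc) {
    gg <- expand.grid(sb = paste0("S", 1:6), model = 1:5,
                      stringsAsFactors = FALSE)
    gg$scanner <- sc
    gg$mean_abs_dev_um <- 30 + rnorm(nrow(gg), 0, 3)
    gg
  }))
  frm <- friedman_by_scanner(deviation_table(many))
  expect_equal(frm$p_holm, oracle_holm(frm$p_raw))
  expect_true(all(frm$p_holm >= frm$p_raw))

  # incomplete blocks are refused with the missing cell named
  incomplete <- many[-1, ]
  expect_error(friedman_by_scanner(deviation_table(incomplete)),
               "missing")
})

test_that("biclustering matches the independent UPGMA oracle", {
  # two identical rows merge at height zero
  m0 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  colnames(m0) <- paste0("S", 1:3)
  bc0 <- bicluster(m0)
  expect_equal(min(bc0$row_hclust$height), 0)

  # 2 x 2 with hand-computed merge heights
  m2 <- rbind(r1 = c(0, 0), r2 = c(3, 4))
  colnames(m2) <- c("c1", "c2")
  bc2 <- bicluster(m2)
  expect_equal(bc2$row_hclust$height, 5)
  expect_equal(bc2$col_hclust$height, 1)

  # benchmark cell means: the S3/S4 column pair is the last cluster joined
  m <- table2_means()
  bc <- bicluster(m)
  merges <- oracle_upgma(t(m))
  last <- merges[[length(merges)]]
  sides <- list(sort(last$left), sort(last$right))
  expect_true(any(vapply(sides, identical, TRUE, c("S3", "S4"))))
  # hclust heights equal the oracle heights
  expect_equal(sort(bc$col_hclust$height),
               sort(vapply(merges, `[[`, 1.0, "height")), tolerance = 1e-9)
  expect_setequal(bc$col_order, colnames(m))
  expect_setequal(bc$row_order, rownames(m))
  expect_true(all(diff(bc$col_hclust$height) >= -1e-12))

  expect_error(bicluster(rbind(c(1, NA), c(2, 3))), "finite")
})

test_that("null studies keep the Tukey false-positive rate near nominal", {
  rate <- tukey_null_rate(n_studies = 200, alpha = 0.01, seed = 99)
  expect_gte(rate, 0.001)
  expect_lte(rate, 0.05)
})
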