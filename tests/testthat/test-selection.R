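test_that("group p-values behave at their limits", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  expect_equal(group_pvalue(x, x, test = "wilcoxon"), 1)
  expect_gt(group_pvalue(x, x, test = "welch"), 0.99)
  set.seed(31)
  a <- rnorm(20); b <- rnorm(20, mean = 5)
  expect_lt(group_pvalue(a, b), 1e-6)
  # degenerate variance: finite p, no crash
  p <- group_pvalue(rep(1, 5), rnorm(5))
  expect_true(is.finite(p))
  expect_true(is.na(group_pvalue(c(1, NA, NA), rnorm(5))))
})

test_that("Bonferroni correction reproduces the worked examples", {
  expect_equal(bonferroni(0.0010, 19), 0.019)
  expect_equal(bonferroni(0.0264, 19), 0.5016)
  expect_equal(bonferroni(0.9, 19), 1)
  expect_equal(0.05 / 19, 0.00263, tolerance = 1e-3)
})

test_that("distribution ratios reproduce the reference worked examples", {
  tabs <- worked_example_tables()
  fc <- setNames(tabs$feature_counts$total, tabs$feature_counts$band_spec)
  expect_equal(sum(fc), 475)
  dr <- distribution_ratio(fc)
  expect_equal(round(dr$ratio[["theta/alpha"]], 3), 15.579)
  expect_equal(sum(dr$ratio), 100, tolerance = 1e-9)

  cc <- setNames(tabs$channel_counts$total, tabs$channel_counts$channel)
  expect_equal(sum(cc), 461)
  dc <- distribution_ratio(cc)
  expect_equal(round(dc$ratio[["P4"]], 3), 10.412)

  expect_equal(unname(distribution_ratio(c(x = 7))$ratio), 100)
  expect_error(distribution_ratio(c(0, 0)), "all counts are zero")
})

test_that("the cumulative-80% rule selects 11 features and 12 channels", {
  tabs <- worked_example_tables()
  fc <- setNames(tabs$feature_counts$total, tabs$feature_counts$band_spec)
  dr <- distribution_ratio(fc)
  ranked <- dr$ratio[dr$order]
  sel <- cumulative_select(ranked, 80)
  expect_length(sel, 11)
  expect_equal(unname(dr$cumulative[11]), 81.052, tolerance = 1e-2)
  expect_true(all(c("theta/alpha", "alpha/theta", "delta/theta") %in%
                    names(ranked)[sel]))

  cc <- setNames(tabs$channel_counts$total, tabs$channel_counts$channel)
  dc <- distribution_ratio(cc)
  selc <- cumulative_select(dc$ratio[dc$order], 80)
  expect_length(selc, 12)
  expect_equal(unname(dc$cumulative[12]), 81.343, tolerance = 1e-2)
  expect_setequal(names(cc)[dc$order][selc],
                  c("P4", "P3", "PZ", "T6", "T5", "C4", "T3", "C3", "CZ",
                    "T4", "O2", "O1"))
})

test_that("cumulative selection is monotone in the threshold", {
  set.seed(32)
  counts <- sort(rpois(15, 20), decreasing = TRUE) + 1
  ratios <- distribution_ratio(counts)$ratio[order(-counts)]
  prev <- integer(0)
  for (thr in c(20, 40, 60, 80, 95, 100)) {
    cur <- cumulative_select(ratios, thr)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_equal(cumulative_select(c(100), 80), 1L)
})

test_that("the screen controls its type-I error on null cohorts", {
  pool <- as.vector(outer(band_specs(), montage_1020(),
                          feature_id, method = "DPS"))
  n_sig <- 0L; n_tests <- 0L
  for (rep in 1:20) {
    tab <- make_feature_cohort(n_per_group = 20, n_features = 400,
                               seed = 100 + rep, ids = pool[1:400])
    rep_sel <- select_features(tab)
    n_sig <- n_sig + sum(rep_sel$pvalues$significant)
    n_tests <- n_tests + nrow(rep_sel$pvalues)
  }
  # 8000 null tests at alpha = 0.001: expect ~8 hits; binomial 99.9% band
  expect_gte(n_sig, 0)
  expect_lte(n_sig, 25)
})

test_that("selection finds planted effects where they were planted", {
  # build a table whose theta/alpha DPS features differ at several channels
  channels <- montage_1020()
  ids <- c(as.vector(outer(band_specs(), channels, feature_id,
                           method = "DPS")),
           as.vector(outer(band_specs(), channels, feature_id,
                           method = "LZC")))
  set.seed(33)
  n <- 40
  x <- matrix(rnorm(n * length(ids)), n, dimnames = list(NULL, ids))
  groups <- rep(c("NOLD", "AD"), each = 20)
  bump <- paste0("DPS_theta-alpha_", c("P3", "P4", "PZ", "T5", "T6"))
  x[groups == "AD", bump] <- x[groups == "AD", bump] + 4
  tab <- biomarker_table(x, groups)
  sel <- select_features(tab)
  expect_equal(sel$feature_ranking$id[1], "theta/alpha")
  expect_true("theta/alpha" %in% sel$selected_features)
  expect_true(all(c("P3", "P4") %in% sel$selected_channels))
  # Bonferroni columns use the per-family test count (19 channels)
  sig_rows <- sel$pvalues[sel$pvalues$significant, ]
  expect_equal(sig_rows$p_bonf, pmin(1, sig_rows$p * 19))
})

test_that("selection reports serialise to CSV", {
  tab <- make_feature_cohort(n_per_group = 10, n_features = 20,
                             informative = 1:2, d = 4, seed = 34)
  sel <- select_features(tab)
  dir <- withr::local_tempdir()
  paths <- write_selection_report(sel, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "feature_ranking.csv"))
  expect_equal(back$cumulative[nrow(back)], 100, tolerance = 1e-6)
})
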