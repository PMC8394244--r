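test_that("stratified splits are disjoint, exhaustive and deterministic", {
  tab <- make_feature_cohort(n_per_group = 12, n_features = 5, seed = 51)
  sp <- split_train_test(tab, train_frac = 0.6, seed = 3)
  expect_equal(nrow(sp$train$values) + nrow(sp$test$values), 24)
  expect_length(intersect(sp$train$subjects$id, sp$test$subjects$id), 0)
  expect_true(all(c("AD", "NOLD") %in% sp$train$subjects$group))
  expect_true(all(c("AD", "NOLD") %in% sp$test$subjects$group))

  sp2 <- split_train_test(tab, train_frac = 0.6, seed = 3)
  expect_identical(sp$train$subjects$id, sp2$train$subjects$id)
  sp3 <- split_train_test(tab, train_frac = 0.6, seed = 4)
  expect_false(identical(sp$train$subjects$id, sp3$train$subjects$id))

  expect_error(split_train_test(tab, train_frac = 1.0), "strictly between")
})

test_that("a 17/24 cohort splits with stratified rounding", {
  set.seed(52)
  x <- matrix(rnorm(41 * 4), 41,
              dimnames = list(NULL, paste0("TSEN_alpha_",
                                           montage_1020()[1:4])))
  tab <- biomarker_table(x, c(rep("AD", 17), rep("NOLD", 24)))
  sp <- split_train_test(tab, 0.6, seed = 9)
  n_train <- nrow(sp$train$values)
  expect_true(n_train %in% 24:25)  # round(0.6*17) + round(0.6*24) = 10 + 14
  expect_equal(sum(sp$train$subjects$group == "AD"), 10)
})

test_that("the SVM screen separates a separable panel and not noise", {
  tab <- make_feature_cohort(n_per_group = 15, n_features = 6,
                             informative = 1:2, d = 4, seed = 53)
  ids <- colnames(tab$values)
  good <- evaluate_panel_svm(tab, ids[1:2], folds = 10, seed = 1)
  expect_gte(good$metrics$sen, 90)
  expect_gte(good$metrics$spec, 90)

  # constant feature: chance-level, no crash
  tab$values[, 6] <- 1
  flat <- evaluate_panel_svm(tab, ids[6], folds = 5, seed = 1)
  expect_true(is.finite(flat$metrics$acc))
})

test_that("label permutation drives cross-validated accuracy to chance", {
  accs <- vapply(1:20, function(r) {
    tab <- make_feature_cohort(n_per_group = 10, n_features = 4,
                               informative = 1:2, d = 4, seed = 60 + r)
    perm <- tab
    set.seed(1000 + r)
    perm$subjects$group <- sample(perm$subjects$group)
    evaluate_panel_svm(perm, colnames(perm$values)[1:2], folds = 5,
                       seed = r)$metrics$acc
  }, 0)
  expect_gt(mean(accs), 40)
  expect_lt(mean(accs), 60)
})

test_that("panel filtering applies the >= 80/80 rule and ranks survivors", {
  res <- data.frame(panel_id = c("a", "b", "c", "d"),
                    n_locations = c(3, 1, 2, 1),
                    sen = c(100, 85, 100, 90), spec = c(83, 79, 100, 95))
  kept <- filter_panels(res)
  expect_setequal(kept$panel_id, c("a", "c", "d"))  # b fails spec
  expect_equal(kept$panel_id[1], "d")               # fewest locations first
  expect_equal(filter_panels(res[0, , drop = FALSE]), res[0, , drop = FALSE])
})

test_that("LDA fusion reaches perfect held-out accuracy on separable data", {
  tab <- make_feature_cohort(n_per_group = 20, n_features = 8,
                             informative = 1:3, d = 6, seed = 54)
  sp <- split_train_test(tab, 0.6, seed = 2)
  ids <- colnames(tab$values)
  model <- fuse_lda(list(ids[1:2], ids[2:3]), sp$train, sp$test)
  expect_equal(model$test_metrics$sen, 100)
  expect_equal(model$test_metrics$spec, 100)
  expect_setequal(model$features, ids[1:3])

  # single panel input reduces to plain LDA on that panel
  m1 <- fuse_lda(ids[1:2], sp$train, sp$test)
  expect_length(m1$features, 2)
  expect_gte(m1$test_metrics$acc, 90)
})

test_that("fusion beats the best single panel on mid-effect cohorts", {
  wins <- 0L
  for (r in 1:20) {
    tab <- make_feature_cohort(n_per_group = 40, n_features = 6,
                               informative = 1:3, d = 1.5, seed = 200 + r)
    sp <- split_train_test(tab, 0.6, seed = r)
    ids <- colnames(tab$values)
    panels <- list(ids[1], ids[2], ids[3])
    fused <- fuse_lda(panels, sp$train, sp$test)$test_metrics
    singles <- vapply(panels, function(p) {
      m <- fuse_lda(list(p), sp$train, sp$test)$test_metrics
      m$sen + m$spec
    }, 0)
    if (fused$sen + fused$spec >= max(singles)) wins <- wins + 1L
  }
  expect_gte(wins, 16)  # >= 80% of replicates
})

test_that("degenerate covariance falls back to the shrinkage discriminant", {
  set.seed(55)
  x <- matrix(rnorm(20 * 3), 20)
  x[, 3] <- x[, 1]  # exact collinearity
  colnames(x) <- paste0("TSEN_alpha_", c("C3", "C4", "P3"))
  x[11:20, 1:3] <- x[11:20, 1:3] + 4
  tab <- biomarker_table(x, rep(c("NOLD", "AD"), each = 10))
  expect_no_error(model <- fuse_lda(colnames(x), tab, tab))
  expect_gte(model$test_metrics$acc, 90)
})

test_that("validation never refits and demands the model's features", {
  tab <- make_feature_cohort(n_per_group = 12, n_features = 5,
                             informative = 1:2, d = 5, seed = 56)
  sp <- split_train_test(tab, 0.6, seed = 1)
  model <- fuse_lda(list(colnames(tab$values)[1:2]), sp$train, sp$test)
  # resubstitution bound: training metrics at least as good as held-out CV
  resub <- validate(model, sp$train)
  expect_gte(resub$acc, 90)
  # independent cohort from the same distribution generalises
  fresh <- make_feature_cohort(n_per_group = 12, n_features = 5,
                               informative = 1:2, d = 5, seed = 57)
  gen <- validate(model, fresh)
  expect_gte(gen$sen, resub$sen - 15)
  expect_gte(gen$spec, resub$spec - 15)
  # zero-effect cohort: chance performance
  null <- make_feature_cohort(n_per_group = 12, n_features = 5, seed = 58)
  m0 <- validate(model, null)
  expect_lt(m0$acc, 80)

  dropped <- null
  dropped$values <- dropped$values[, -1, drop = FALSE]
  expect_error(predict(model, dropped), "missing feature")
})

test_that("the minimal-subset search recovers planted feature pairs", {
  hits <- 0L
  for (r in 1:5) {
    set.seed(300 + r)
    n <- 40; k <- 20
    x <- matrix(rnorm(n * k), n)
    groups <- rep(c("NOLD", "AD"), each = n / 2)
    # jointly informative pair: the difference x1 - x2 separates groups
    z <- rnorm(n)
    d <- ifelse(groups == "AD", 2.5, -2.5)
    x[, 1] <- z + d / 2 + 0.3 * rnorm(n)
    x[, 2] <- z - d / 2 + 0.3 * rnorm(n)
    pool <- as.vector(outer(band_specs(), montage_1020(),
                            feature_id, method = "ZCI"))
    colnames(x) <- pool[seq_len(k)]
    tab <- biomarker_table(x, groups)
    res <- optimize_min_subset(tab, max_size = 3, folds = 5, seed = r)
    extras <- setdiff(res$panel, colnames(x)[1:2])
    if (res$compliant && length(res$panel) <= 3 && length(extras) <= 1)
      hits <- hits + 1L
  }
  expect_gte(hits, 4)
})

test_that("pure-noise candidates raise the non-compliant flag", {
  flags <- vapply(1:5, function(r) {
    tab <- make_feature_cohort(n_per_group = 10, n_features = 8,
                               seed = 400 + r)
    res <- optimize_min_subset(tab, max_size = 2, folds = 5, seed = r)
    !res$compliant
  }, TRUE)
  expect_gte(sum(flags), 4)  # >= 80% of replicates
})

test_that("max_size 1 returns the single best feature on separable data", {
  tab <- make_feature_cohort(n_per_group = 12, n_features = 5,
                             informative = 2, d = 6, seed = 59)
  res <- optimize_min_subset(tab, max_size = 1, folds = 5, seed = 1)
  expect_length(res$panel, 1)
  expect_identical(res$panel, colnames(tab$values)[2])
  expect_true(res$compliant)
})

test_that("models serialise to JSON and predict identically after reload", {
  tab <- make_feature_cohort(n_per_group = 12, n_features = 5,
                             informative = 1:2, d = 4, seed = 61)
  sp <- split_train_test(tab, 0.6, seed = 1)
  model <- fuse_lda(list(colnames(tab$values)[1:3]), sp$train, sp$test)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(model, path)
  back <- model_from_json(path)
  expect_identical(predict(back, sp$test), predict(model, sp$test))
})
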