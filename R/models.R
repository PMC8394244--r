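# Panel screening (cross-validated linear SVM), LDA fusion, and the
# minimal-subset optimisation.

#' Stratified train/test split of a biomarker table
#'
#' @param table a `biomarker_table` with both groups present.
#' @param train_frac fraction of each group assigned to training (0.6).
#' @param seed RNG seed making the split reproducible.
#' @return List with `train` and `test` biomarker tables.
#' @export
split_train_test <- function(table, train_frac = 0.6, seed = 1) {
  groups <- table$subjects$group
  if (any(table(groups) < 2)) stop("each group needs at least 2 subjects")
  if (train_frac <= 0 || train_frac >= 1)
    stop("'train_frac' must be strictly between 0 and 1 (both parts non-empty)")
  idx_train <- integer(0)
  with_seed(seed, {
    for (g in unique(groups)) {
      gi <- which(groups == g)
      n_tr <- max(1L, min(length(gi) - 1L, round(train_frac * length(gi))))
      idx_train <- c(idx_train, sort(sample(gi, n_tr)))
    }
  })
  idx_train <- sort(idx_train)
  take <- function(ix) new_biomarker_table(
    table$values[ix, , drop = FALSE], colnames(table$values),
    table$subjects[ix, , drop = FALSE], table$params)
  list(train = take(idx_train),
       test = take(setdiff(seq_along(groups), idx_train)))
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(code))
}

# stratified fold assignment; folds shrink when a class is small
stratified_folds <- function(groups, folds, seed) {
  n_min <- min(table(groups))
  if (folds > n_min) {
    warning("reducing folds from ", folds, " to ", n_min,
            " (smallest class size)")
    folds <- max(2L, n_min)
  }
  assign_f <- integer(length(groups))
  with_seed(seed, {
    for (g in unique(groups)) {
      gi <- sample(which(groups == g))
      assign_f[gi] <- rep_len(seq_len(folds), length(gi))
    }
  })
  assign_f
}

#' Cross-validated SVM evaluation of one biomarker panel
#'
#' Fits a linear support vector machine (unit cost) to the panel's
#' features with stratified k-fold cross-validation. Features are
#' standardised inside each training fold (constant features dropped for
#' that fold); the pooled out-of-fold confusion matrix yields the metrics.
#'
#' @param table a `biomarker_table` (the development set).
#' @param features character vector of feature ids forming the panel.
#' @param folds number of CV folds (default 10; reduced with a warning
#'   when a class is smaller).
#' @param seed RNG seed for fold assignment.
#' @param cost SVM regularisation constant (default 1).
#' @return List with `metrics` (see [metrics_from_confusion()]),
#'   `confusion`, and `folds` actually used.
#' @export
evaluate_panel_svm <- function(table, features, folds = 10, seed = 1,
                               cost = 1) {
  x <- table$values[, features, drop = FALSE]
  y <- factor(table$subjects$group, levels = c("NOLD", "AD"))
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]; y <- droplevels(y[keep])
  if (nlevels(y) < 2) stop("both groups required for panel evaluation")
  fold_of <- suppressWarnings(stratified_folds(as.character(y), folds, seed))
  nf <- max(fold_of)
  pred <- rep(NA_character_, length(y))
  for (f in seq_len(nf)) {
    tr <- fold_of != f; te <- !tr
    if (!any(te)) next
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd)
    usable <- sdv > 0
    if (!any(usable)) {
      # all-constant panel in this fold: majority-class prediction
      maj <- names(which.max(table(y[tr])))
      pred[te] <- maj
      next
    }
    xt <- scale(x[tr, usable, drop = FALSE], center = mu[usable],
                scale = sdv[usable])
    xe <- scale(x[te, usable, drop = FALSE], center = mu[usable],
                scale = sdv[usable])
    fit <- e1071::svm(xt, droplevels(y[tr]), kernel = "linear", cost = cost,
                      scale = FALSE)
    p <- predict(fit, xe)
    pred[te] <- as.character(p)
  }
  cm <- confusion_matrix(as.character(y), pred)
  list(metrics = metrics_from_confusion(cm), confusion = cm, folds = nf)
}

#' Filter panels on sensitivity and specificity thresholds
#'
#' Keeps panels with `sen >= sen_min` and `spec >= spec_min`, ranked by
#' fewest locations then by `sen + spec` descending.
#'
#' @param results data frame with columns `panel` (list or id), `n_locations`,
#'   `sen`, `spec` (as produced by the screening loop).
#' @param sen_min,spec_min thresholds in percent (default 80).
#' @return The surviving rows, re-ranked.
#' @export
filter_panels <- function(results, sen_min = 80, spec_min = 80) {
  if (nrow(results) == 0) return(results)
  keep <- !is.na(results$sen) & !is.na(results$spec) &
    results$sen >= sen_min & results$spec >= spec_min
  out <- results[keep, , drop = FALSE]
  if (nrow(out))
    out <- out[order(out$n_locations, -(out$sen + out$spec)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- LDA fusion ------------------------------------------------------------

# LDA with a shrinkage fallback when the within-class covariance is
# singular (tiny n, collinear features)
fit_lda_safe <- function(x, y) {
  fit <- tryCatch(MASS::lda(x, grouping = y),
                  error = function(e) NULL)
  if (!is.null(fit)) return(list(type = "lda", fit = fit))
  # shrunken Fisher discriminant: pooled covariance blended toward its
  # diagonal plus a ridge
  classes <- levels(y)
  mu <- lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  xc <- x
  for (cl in classes)
    xc[y == cl, ] <- sweep(x[y == cl, , drop = FALSE], 2, mu[[match(cl, classes)]])
  s <- crossprod(xc) / max(1, nrow(x) - length(classes))
  lambda <- 0.25
  s <- (1 - lambda) * s + lambda * diag(diag(s) + 1e-8, ncol(x))
  w <- solve(s, mu[[2]] - mu[[1]])
  thr <- as.numeric((mu[[1]] + mu[[2]]) %*% w) / 2
  list(type = "shrunken", w = w, threshold = thr, classes = classes)
}

predict_lda_safe <- function(model, x) {
  if (model$type == "lda") {
    as.character(predict(model$fit, x)$class)
  } else {
    sc <- as.numeric(x %*% model$w)
    ifelse(sc > model$threshold, model$classes[2], model$classes[1])
  }
}

#' Fuse surviving panels with linear discriminant analysis
#'
#' Concatenates the (unique) biomarkers of all surviving panels into one
#' feature vector, standardises on the training set, fits LDA (with a
#' shrinkage fallback when the within-class covariance is singular, which
#' is logged), and evaluates on the held-out table.
#'
#' @param panels list of character vectors of feature ids (one per panel),
#'   or a single character vector.
#' @param train,test `biomarker_table`s.
#' @return An `ad_model` (see [ad_fit()]) with `test_metrics`.
#' @export
fuse_lda <- function(panels, train, test = NULL) {
  if (is.character(panels)) panels <- list(panels)
  if (length(panels) == 0) stop("at least one surviving panel is required")
  features <- unique(unlist(panels))
  x <- train$values[, features, drop = FALSE]
  y <- factor(train$subjects$group, levels = c("NOLD", "AD"))
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]; y <- droplevels(y[keep])
  mu <- colMeans(x); sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x, center = mu, scale = sdv)
  lda_model <- fit_lda_safe(xs, y)
  if (lda_model$type != "lda")
    message("within-class covariance singular; shrinkage discriminant used")
  model <- structure(list(features = features, panels = panels,
                          center = mu, scale = sdv, lda = lda_model,
                          classes = levels(y)),
                     class = "ad_model")
  if (!is.null(test)) {
    model$test_metrics <- validate(model, test)
  }
  model
}

#' Predict diagnostic class for new subjects
#'
#' @param object an `ad_model`.
#' @param newdata a `biomarker_table` containing the model's features.
#' @param ... unused.
#' @return Character vector of `"AD"`/`"NOLD"` predictions.
#' @export
predict.ad_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata$values))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  x <- newdata$values[, object$features, drop = FALSE]
  x[!is.finite(x)] <- 0  # imputed at the training centre after scaling
  xs <- scale(x, center = object$center, scale = object$scale)
  xs[!is.finite(xs)] <- 0
  predict_lda_safe(object$lda, xs)
}

#' Evaluate a fitted diagnostic model on an unseen cohort
#'
#' Applies the model without refitting and returns the confusion-matrix
#' metrics.
#'
#' @param model an `ad_model`.
#' @param table a `biomarker_table` with group labels.
#' @return Metrics list from [metrics_from_confusion()].
#' @export
validate <- function(model, table) {
  pred <- predict(model, table)
  metrics_from_confusion(confusion_matrix(table$subjects$group, pred))
}

#' Minimal-subset optimisation over candidate biomarkers
#'
#' Evaluates every panel of size `1..max_size` drawn from the candidate
#' biomarkers by cross-validated SVM, smallest panels first, and returns
#' the smallest panel meeting the sensitivity/specificity criterion with
#' maximal `sen + spec` (ties broken by lexicographic feature ids). When
#' `stop_at_size = TRUE` (default) larger sizes are not enumerated once a
#' compliant panel exists at a smaller size — the goal is the fewest
#' biomarkers. If no panel complies, the best-scoring panel is returned
#' flagged `compliant = FALSE`.
#'
#' @param table the development `biomarker_table`.
#' @param biomarkers candidate feature ids (default: all columns).
#' @param max_size maximum panel size (default 4).
#' @param folds CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param sen_min,spec_min compliance thresholds in percent (default 80).
#' @param stop_at_size stop enumerating larger panels once a compliant
#'   panel is found at a smaller size.
#' @param eval_cap maximum number of panels rated (default `Inf`); panels
#'   are rated in the deterministic smallest-first order, so a cap keeps
#'   runs reproducible. `capped = TRUE` in the result marks truncation.
#' @return List with `panel` (feature ids), `metrics`, `compliant`,
#'   `n_evaluated`, `capped`, and `model` (an `ad_model` refit on all of
#'   `table`).
#' @export
optimize_min_subset <- function(table, biomarkers = colnames(table$values),
                                max_size = 4, folds = 10, seed = 1,
                                sen_min = 80, spec_min = 80,
                                stop_at_size = TRUE, eval_cap = Inf) {
  best <- NULL; best_score <- -Inf
  best_any <- NULL; best_any_score <- -Inf
  n_eval <- 0L; capped <- FALSE
  for (size in seq_len(min(max_size, length(biomarkers)))) {
    if (capped) break
    s <- combination_stream(biomarkers, size, size)
    while (!is.null(panel <- s$nextval())) {
      if (n_eval >= eval_cap) { capped <- TRUE; break }
      n_eval <- n_eval + 1L
      res <- evaluate_panel_svm(table, panel, folds = folds, seed = seed)
      sen <- res$metrics$sen; spec <- res$metrics$spec
      if (is.na(sen) || is.na(spec)) next
      score <- sen + spec
      if (score > best_any_score) {
        best_any <- list(panel = panel, metrics = res$metrics)
        best_any_score <- score
      }
      if (sen >= sen_min && spec >= spec_min && score > best_score) {
        best <- list(panel = panel, metrics = res$metrics)
        best_score <- score
      }
    }
    if (!is.null(best) && stop_at_size) break
  }
  out <- if (!is.null(best)) c(best, compliant = TRUE) else
    c(best_any, compliant = FALSE)
  if (is.null(out$panel)) stop("no panel could be evaluated")
  out$n_evaluated <- n_eval
  out$capped <- capped
  out$model <- fuse_lda(list(out$panel), table)
  out
}

# --- serialisation ---------------------------------------------------------

#' Serialise / restore a diagnostic model as JSON
#'
#' Stores the feature list, standardisation constants and discriminant
#' weights in a versioned JSON file; the reloaded model predicts
#' identically.
#'
#' @param model an `ad_model`.
#' @param path JSON path.
#' @return `path`, or the restored `ad_model` for `model_from_json()`.
#' @export
model_to_json <- function(model, path) {
  lda <- model$lda
  payload <- list(
    format = "adeeg-model", version = 1L,
    features = model$features, panels = model$panels,
    center = as.list(model$center), scale = as.list(model$scale),
    classes = model$classes)
  if (lda$type == "lda") {
    payload$lda <- list(type = "lda",
                        prior = as.list(lda$fit$prior),
                        means = as.data.frame(lda$fit$means),
                        scaling = as.data.frame(lda$fit$scaling),
                        lev = lda$fit$lev)
  } else {
    payload$lda <- list(type = "shrunken", w = as.list(lda$w),
                        threshold = lda$threshold, classes = lda$classes)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "adeeg-model"))
    stop("not an adeeg model file: ", path)
  lda <- if (identical(p$lda$type, "lda")) {
    fit <- structure(list(prior = unlist(p$lda$prior),
                          means = as.matrix(p$lda$means),
                          scaling = as.matrix(p$lda$scaling),
                          lev = p$lda$lev,
                          counts = setNames(rep(1L, length(p$lda$lev)), p$lda$lev),
                          N = 2L, svd = 1,
                          call = quote(lda())), class = "lda")
    list(type = "lda", fit = fit)
  } else {
    list(type = "shrunken", w = unlist(p$lda$w), threshold = p$lda$threshold,
         classes = p$lda$classes)
  }
  structure(list(features = p$features,
                 panels = if (is.list(p$panels)) p$panels else list(p$panels),
                 center = unlist(p$center), scale = unlist(p$scale),
                 lda = lda, classes = p$classes),
            class = "ad_model")
}
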