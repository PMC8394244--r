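# The modelling surface: ad_fit() runs selection -> Stage-1 panel
# screening -> threshold filtering -> LDA fusion and returns a classed
# model object.

#' Fit the panel-based EEG diagnostic model
#'
#' Runs the framework's screening and fusion stages on a biomarker table:
#'
#' 1. statistical screen ([select_features()]): band specs by cumulative
#'    distribution ratio, channels likewise, coherence pairs by
#'    significance;
#' 2. Stage-1 panels ([build_stage1_panels()]): each selected band spec
#'    crossed with combinations of the selected locations, homogeneous per
#'    method, smallest panels first;
#' 3. per-panel cross-validated linear SVM ([evaluate_panel_svm()]) on the
#'    training split;
#' 4. panels with sensitivity and specificity at or above the thresholds
#'    survive ([filter_panels()]);
#' 5. the surviving panels' biomarkers are fused with LDA ([fuse_lda()])
#'    and evaluated on the held-out split.
#'
#' `screen_cap` bounds the number of Stage-1 panels actually rated by the
#' SVM (panels are rated smallest-first in deterministic order, so a cap
#' keeps the screen reproducible); the full combinatorial audit is always
#' reported in `$panel_audit`.
#'
#' @param table a `biomarker_table` with both groups.
#' @param train_frac training fraction of the stratified split (0.6).
#' @param p_threshold raw p-value selection rule (0.001).
#' @param cum_threshold cumulative distribution-ratio threshold (80).
#' @param sen_min,spec_min panel survival thresholds in percent (80).
#' @param max_len maximum locations per Stage-1 panel (10).
#' @param folds CV folds for the SVM screen (10).
#' @param seed RNG seed (split + folds).
#' @param screen_cap maximum number of panels rated by the SVM.
#' @param test two-sample test for the screen.
#' @return An `ad_model` with the selection report, surviving panels,
#'   fused LDA and held-out metrics.
#' @export
ad_fit <- function(table, train_frac = 0.6, p_threshold = 0.001,
                   cum_threshold = 80, sen_min = 80, spec_min = 80,
                   max_len = 10, folds = 10, seed = 1, screen_cap = 5000,
                   test = c("welch", "wilcoxon")) {
  split <- split_train_test(table, train_frac, seed)
  sel <- select_features(table, p_threshold, cum_threshold, test)
  if (length(sel$selected_features) == 0)
    stop("no band-spec feature passed the statistical screen")

  audit <- stage1_panel_counts(
    length(sel$selected_features), length(sel$selected_channels),
    length(sel$selected_pairs), max_len,
    length(intersect(single_channel_methods(),
                     unique(table$features$method))))

  # rate panels smallest-first up to the cap
  results <- list()
  rate <- function(method, band_spec, locations) {
    if (length(results) >= screen_cap) return(FALSE)
    if (method == "COH") {
      ids <- feature_id("COH", band_spec, locations)
    } else {
      ids <- feature_id(method, band_spec, locations)
    }
    ids <- intersect(ids, colnames(table$values))
    if (length(ids) == 0) return(invisible(NULL))
    res <- tryCatch(
      evaluate_panel_svm(split$train, ids, folds = folds, seed = seed),
      error = function(e) NULL)
    if (is.null(res)) return(invisible(NULL))
    results[[length(results) + 1L]] <<- data.frame(
      panel_id = paste0(method, "_", gsub("/", "-", band_spec), "[",
                        paste(locations, collapse = ","), "]"),
      method = method, band_spec = band_spec,
      features = I(list(ids)), n_locations = length(locations),
      sen = res$metrics$sen, spec = res$metrics$spec,
      acc = res$metrics$acc)
    invisible(NULL)
  }
  methods_present <- intersect(single_channel_methods(),
                               unique(table$features$method))
  build_stage1_panels(sel$selected_features, sel$selected_channels,
                      sel$selected_pairs, max_len = max_len,
                      methods = methods_present, fun = rate)
  screened <- if (length(results)) do.call(rbind, results) else
    data.frame(panel_id = character(0), n_locations = integer(0),
               sen = numeric(0), spec = numeric(0))
  surviving <- filter_panels(screened, sen_min, spec_min)
  if (nrow(surviving) == 0)
    stop("no panel reached sen/spec >= ", sen_min, "/", spec_min,
         " in the SVM screen")

  model <- fuse_lda(surviving$features, split$train, split$test)
  model$selection <- sel
  model$panel_audit <- audit
  model$screened <- screened[, setdiff(names(screened), "features")]
  model$surviving <- surviving[, setdiff(names(surviving), "features")]
  model$surviving_features <- surviving$features
  model$config <- list(train_frac = train_frac, p_threshold = p_threshold,
                       cum_threshold = cum_threshold, sen_min = sen_min,
                       spec_min = spec_min, max_len = max_len, folds = folds,
                       seed = seed, screen_cap = screen_cap)
  model
}

#' @export
print.ad_model <- function(x, ...) {
  cat("<ad_model> panel-fused LDA diagnostic model\n")
  cat("  biomarkers:", length(x$features), "from",
      length(x$panels), "panel(s)\n")
  if (!is.null(x$test_metrics)) {
    fm <- format_metrics(x$test_metrics)
    cat(sprintf("  held-out: Sen %s%%  Spec %s%%  Acc %s%%  MCC %s\n",
                fm["sen"], fm["spec"], fm["acc"], fm["mcc"]))
  }
  invisible(x)
}

#' @export
summary.ad_model <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) {
    cat("  selected band specs:",
        paste(object$selection$selected_features, collapse = ", "), "\n")
    cat("  selected channels:",
        paste(object$selection$selected_channels, collapse = ", "), "\n")
  }
  if (!is.null(object$surviving)) {
    cat("  surviving panels (ranked):\n")
    df <- object$surviving
    df$sen <- round(df$sen, 2); df$spec <- round(df$spec, 2)
    print(utils::head(df[, c("panel_id", "n_locations", "sen", "spec")], 10),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.ad_model <- function(object, ...) {
  if (object$lda$type == "lda") {
    w <- object$lda$fit$scaling[, 1]
  } else {
    w <- object$lda$w
  }
  setNames(as.numeric(w), object$features)
}
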