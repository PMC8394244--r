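# Pipeline orchestration: reproducible end-to-end runs with a config and
# on-disk stage artefacts. Each stage can be re-run from its predecessor's
# files; the config (with every constant of the framework) is serialised
# into the output directory for provenance.

#' Default pipeline configuration
#'
#' All framework constants with their defaults: band edges, method
#' parameters, selection thresholds (p <= 0.001, cumulative 80%), panel
#' limits (Stage-1 length 10, Stage-2 size 4), screening thresholds
#' (Sen/Spec >= 80%), split fraction 0.6, 10 folds, and the synthetic
#' cohort specification used when no input data is given.
#'
#' @param ... overrides merged over the defaults (named, nested lists
#'   merged shallowly).
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    cohort = list(n_ad = 20, n_nold = 20, fs = 128, duration = 60,
                  slowing_effect = 0.3, complexity_effect = 0.15,
                  coherence_effect = 0.4, noise_sd = 1),
    methods = method_names(),
    feature_params = default_feature_params(),
    p_threshold = 0.001, cum_threshold = 80,
    max_len = 10, max_size = 4,
    sen_min = 80, spec_min = 80,
    train_frac = 0.6, folds = 10,
    screen_cap = 5000, optimize_cap = 5000, seed = 1, test = "welch")
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
    else cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

#' Run the ten-step framework end to end
#'
#' Simulates (or loads) a cohort, extracts the biomarker table, screens
#' features and channels, audits the panel combinatorics, rates Stage-1
#' panels with the cross-validated SVM, fuses survivors with LDA,
#' optionally optimises a minimal subset, and validates on an
#' independently generated cohort. Artefacts (CSV tables, JSON audits and
#' the config) are written to `out_dir` when given.
#'
#' @param config list from [default_config()].
#' @param records optional list of [eeg_record()]s; when `NULL` a synthetic
#'   cohort is generated from `config$cohort`.
#' @param out_dir optional output directory for stage artefacts.
#' @param optimize run the Stage-2 minimal-subset search (default TRUE).
#' @return List with `table`, `model` (an `ad_model`), `optimized` (when
#'   requested), and `validation` metrics on a fresh cohort (synthetic
#'   input only).
#' @export
run_pipeline <- function(config = default_config(), records = NULL,
                         out_dir = NULL, optimize = TRUE) {
  synthetic <- is.null(records)
  spec <- NULL
  if (synthetic) {
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
    records <- generate_cohort(spec)$records
  }
  table <- extract_features(records, methods = config$methods,
                            params = config$feature_params)
  model <- ad_fit(table, train_frac = config$train_frac,
                  p_threshold = config$p_threshold,
                  cum_threshold = config$cum_threshold,
                  sen_min = config$sen_min, spec_min = config$spec_min,
                  max_len = config$max_len, folds = config$folds,
                  seed = config$seed, screen_cap = config$screen_cap,
                  test = config$test)
  out <- list(table = table, model = model, config = config)

  if (optimize) {
    candidates <- unique(unlist(model$surviving_features))
    out$optimized <- optimize_min_subset(
      table, candidates, max_size = config$max_size, folds = config$folds,
      seed = config$seed, sen_min = config$sen_min,
      spec_min = config$spec_min, eval_cap = config$optimize_cap)
  }

  if (synthetic) {
    vspec <- do.call(cohort_spec,
                     c(config$cohort, list(seed = config$seed + 7919)))
    vrecords <- generate_cohort(vspec)$records
    vtable <- extract_features(vrecords, methods = config$methods,
                               params = config$feature_params)
    out$validation <- validate(model, vtable)
    if (optimize)
      out$validation_optimized <- validate(out$optimized$model, vtable)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config, file.path(out_dir, "config.yml"))
    write_biomarker_table(table, file.path(out_dir, "biomarkers.csv"))
    write_selection_report(model$selection, out_dir)
    write.csv(model$screened, file.path(out_dir, "panel_metrics.csv"),
              row.names = FALSE)
    jsonlite::write_json(model$panel_audit,
                         file.path(out_dir, "panel_audit.json"),
                         auto_unbox = TRUE, digits = NA)
    model_to_json(model, file.path(out_dir, "model.json"))
    if (optimize)
      model_to_json(out$optimized$model,
                    file.path(out_dir, "model_optimized.json"))
    summary_json <- list(
      held_out = model$test_metrics,
      validation = out$validation,
      optimized_panel = if (optimize) out$optimized$panel,
      optimized_compliant = if (optimize) out$optimized$compliant)
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
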