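#' Bundled worked-example tables for the selection arithmetic
#'
#' Small reference tables shipped with the package: per-band-spec and
#' per-channel significance-count matrices (with their reference totals),
#' the significant coherence-pair counts, and the per-channel p-values of
#' the theta/alpha Tsallis-entropy biomarker. They drive the worked
#' examples of [bonferroni()], [distribution_ratio()] and
#' [cumulative_select()] — e.g. the top band-spec ratio 74/475 = 15.579%,
#' the 11-feature and 12-channel cumulative-80% selections — and the
#' corresponding regression tests.
#'
#' Note that in a few rows the tabulated per-method cells do not add up to
#' the tabulated row total; both are kept (`total` column vs `rowSums` of
#' the cells), and ratio arithmetic uses the tabulated totals.
#'
#' @return Named list of data frames: `feature_counts`, `channel_counts`,
#'   `pair_counts`, `theta_alpha_pvalues`.
#' @export
#' @examples
#' tabs <- worked_example_tables()
#' distribution_ratio(setNames(tabs$feature_counts$total,
#'                             tabs$feature_counts$band_spec))$ratio[1]
worked_example_tables <- function() {
  f <- function(name) read.csv(system.file("extdata", name, package = "adeeg",
                                           mustWork = TRUE))
  list(feature_counts = f("worked_example_feature_counts.csv"),
       channel_counts = f("worked_example_channel_counts.csv"),
       pair_counts = f("worked_example_pair_counts.csv"),
       theta_alpha_pvalues = f("worked_example_theta_alpha_pvalues.csv"))
}
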