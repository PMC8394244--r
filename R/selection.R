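# Statistical screening: group-difference p-values, Bonferroni correction,
# probability distribution ratios, and the cumulative-80% selection rule.

#' Two-sample group-difference p-value
#'
#' Two-sided p-value comparing AD against Nold values of one biomarker.
#' Default is Welch's t-test (robust to unequal variances); Mann-Whitney U
#' is available as `test = "wilcoxon"`.
#'
#' @param values_ad,values_nold numeric vectors (>= 2 finite values each).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return The p-value, or `NA` when a group has fewer than two finite
#'   values.
#' @export
group_pvalue <- function(values_ad, values_nold,
                         test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  a <- values_ad[is.finite(values_ad)]
  b <- values_nold[is.finite(values_nold)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (test == "welch") {
    if (sd(a) == 0 && sd(b) == 0) {
      return(if (a[1] == b[1]) 1 else 0)
    }
    tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
  } else {
    suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
  }
}

#' Bonferroni correction
#'
#' `min(1, p * n_tests)`; the companion critical value for a familywise
#' error rate of 0.05 is `0.05 / n_tests` (0.00263 for the 19 channels of
#' one feature family).
#'
#' @param p raw p-value(s) in `[0, 1]`.
#' @param n_tests number of tests in the family (>= 1).
#' @return Corrected p-value(s).
#' @export
#' @examples
#' bonferroni(0.0010, 19)  # 0.019
#' bonferroni(0.0264, 19)  # 0.5016
bonferroni <- function(p, n_tests) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must lie in [0, 1]")
  if (any(n_tests < 1)) stop("'n_tests' must be >= 1")
  pmin(1, p * n_tests)
}

#' Probability distribution ratios
#'
#' Each count's share of the total, in percent (`100 * x_i / sum(x)`),
#' plus the cumulative series over the entries sorted descending (ties
#' broken by the given order). Used to rank biomarker features and EEG
#' channels by their share of all significant tests.
#'
#' @param counts non-negative integer counts with `sum(counts) > 0`;
#'   names are carried through.
#' @return List with `ratio` (in input order), `order` (indices sorted
#'   descending), and `cumulative` (over the sorted entries).
#' @export
#' @examples
#' distribution_ratio(c(a = 74, b = 401))$ratio[1]  # 15.579...
distribution_ratio <- function(counts) {
  if (any(counts < 0)) stop("'counts' must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop("all counts are zero; ratios undefined")
  ratio <- 100 * counts / tot
  ord <- order(-counts, names(counts) %||% seq_along(counts))
  list(ratio = ratio, order = ord, cumulative = cumsum(ratio[ord]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cumulative-threshold prefix selection
#'
#' Given ratios sorted descending, returns the shortest prefix whose
#' cumulative ratio reaches the threshold (an item tying exactly at the
#' boundary is included).
#'
#' @param ratios percentages sorted descending.
#' @param threshold cumulative percentage in `(0, 100]` (default 80).
#' @return Integer indices of the selected prefix.
#' @export
cumulative_select <- function(ratios, threshold = 80) {
  if (threshold <= 0 || threshold > 100) stop("'threshold' must be in (0,100]")
  if (length(ratios) == 0) return(integer(0))
  if (is.unsorted(-ratios)) stop("'ratios' must be sorted descending")
  cum <- cumsum(ratios)
  k <- which(cum >= threshold - 1e-9)[1]
  if (is.na(k)) k <- length(ratios)
  seq_len(k)
}

#' Statistical feature and channel screen
#'
#' Computes per-feature two-sample p-values, Bonferroni-corrected values
#' (per location family: 19 channels for single-channel features, 171
#' pairs for coherence), significance counts, probability distribution
#' ratios, and the cumulative-threshold selections:
#'
#' * band-spec ranking over all methods (selected set = shortest prefix
#'   reaching `cum_threshold`),
#' * channel ranking over the seven single-channel methods only,
#' * coherence pairs: all pairs with at least one significant biomarker.
#'
#' Selection is gated by the raw `p <= p_threshold` rule; corrected values
#' are reported alongside but do not gate.
#'
#' @param table a `biomarker_table` with both groups present.
#' @param p_threshold significance threshold on the raw p-value (0.001).
#' @param cum_threshold cumulative distribution-ratio threshold (80).
#' @param test two-sample test passed to [group_pvalue()].
#' @return A `selection_report` list; see Details.
#' @export
select_features <- function(table, p_threshold = 0.001, cum_threshold = 80,
                            test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  groups <- table$subjects$group
  if (!all(c("AD", "NOLD") %in% groups))
    stop("both AD and NOLD subjects are required for selection")
  ad <- groups == "AD"

  feats <- table$features
  p <- vapply(seq_len(ncol(table$values)), function(j)
    group_pvalue(table$values[ad, j], table$values[!ad, j], test), 0)
  n_family <- ifelse(feats$method == "COH",
                     length(unique(feats$location[feats$method == "COH"])),
                     length(unique(feats$location[feats$method != "COH"])))
  pvals <- data.frame(feats, p = p, p_bonf = bonferroni(p, n_family),
                      significant = !is.na(p) & p <= p_threshold)

  specs <- band_specs()
  methods <- intersect(method_names(), unique(feats$method))
  count_cell <- function(spec, m)
    sum(pvals$significant[pvals$band_spec == spec & pvals$method == m])
  feature_counts <- sapply(methods, function(m)
    vapply(specs, count_cell, 0L, m = m))
  if (is.null(dim(feature_counts)))
    feature_counts <- matrix(feature_counts, nrow = length(specs),
                             dimnames = list(specs, methods))
  feature_totals <- rowSums(feature_counts)

  sc <- intersect(single_channel_methods(), methods)
  channels <- unique(feats$location[feats$method %in% sc])
  channel_counts <- if (length(sc) && length(channels)) {
    sapply(sc, function(m) vapply(channels, function(ch)
      sum(pvals$significant[pvals$location == ch & pvals$method == m]),
      0L))
  } else matrix(0L, 0, 0)
  if (length(sc) == 1 && length(channels))
    channel_counts <- matrix(channel_counts, ncol = 1,
                             dimnames = list(channels, sc))
  channel_totals <- if (length(channels)) rowSums(channel_counts) else integer(0)

  pair_totals <- if ("COH" %in% methods) {
    prs <- unique(feats$location[feats$method == "COH"])
    vapply(setNames(prs, prs), function(pr)
      sum(pvals$significant[pvals$location == pr & pvals$method == "COH"]),
      0L)
  } else integer(0)

  rank_select <- function(totals) {
    if (!length(totals) || sum(totals) == 0)
      return(list(ranked = data.frame(), selected = character(0)))
    dr <- distribution_ratio(totals)
    ranked <- data.frame(
      id = names(totals)[dr$order],
      count = as.integer(totals[dr$order]),
      ratio = dr$ratio[dr$order],
      cumulative = dr$cumulative, row.names = NULL)
    sel <- ranked$id[cumulative_select(ranked$ratio, cum_threshold)]
    list(ranked = ranked, selected = sel)
  }

  fsel <- rank_select(feature_totals)
  csel <- rank_select(channel_totals)
  selected_pairs <- names(pair_totals)[pair_totals > 0]
  # rank pairs by count for reporting
  psel <- if (length(selected_pairs))
    rank_select(pair_totals[pair_totals > 0]) else
    list(ranked = data.frame(), selected = character(0))

  structure(list(
    pvalues = pvals,
    feature_counts = feature_counts, feature_totals = feature_totals,
    channel_counts = channel_counts, channel_totals = channel_totals,
    pair_totals = pair_totals,
    feature_ranking = fsel$ranked, channel_ranking = csel$ranked,
    pair_ranking = psel$ranked,
    selected_features = fsel$selected,
    selected_channels = csel$selected,
    selected_pairs = selected_pairs,
    thresholds = list(p = p_threshold, cumulative = cum_threshold,
                      test = test)),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<selection_report> %d features screened (p <= %g rule)\n",
    "  significant: %d | selected band specs: %d | channels: %d | pairs: %d\n"),
    nrow(x$pvalues), x$thresholds$p, sum(x$pvalues$significant),
    length(x$selected_features), length(x$selected_channels),
    length(x$selected_pairs)))
  invisible(x)
}

#' Write the selection report as CSV tables
#'
#' Emits the count matrix with ratios per band spec, the analogous channel
#' table, and the coherence-pair table into `dir`.
#'
#' @param report a `selection_report`.
#' @param dir output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_selection_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "feature_ranking.csv"),
             file.path(dir, "channel_ranking.csv"),
             file.path(dir, "pair_ranking.csv"),
             file.path(dir, "pvalues.csv"))
  write.csv(report$feature_ranking, paths[1], row.names = FALSE)
  write.csv(report$channel_ranking, paths[2], row.names = FALSE)
  write.csv(report$pair_ranking, paths[3], row.names = FALSE)
  write.csv(report$pvalues, paths[4], row.names = FALSE)
  invisible(paths)
}
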