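# Exhaustive panel enumeration. Enumeration is lazy: a combination stream
# holds only the current index vector, so the 919,310 optimisation panels
# are generated without ever being materialised.

#' Closed-form combination count
#'
#' `sum(choose(n, k))` for `k` in `[min_len, max_len]` (lengths clamped to
#' `n`).
#'
#' @param n number of items.
#' @param min_len,max_len subset size range.
#' @return The number of subsets.
#' @export
#' @examples
#' n_combinations(12, 1, 10)  # 4082
n_combinations <- function(n, min_len = 1, max_len = n) {
  if (n == 0) return(0)
  max_len <- min(max_len, n)
  if (min_len > max_len) return(0)
  sum(choose(n, min_len:max_len))
}

#' Lazy stream over item subsets
#'
#' Yields subsets in deterministic size-then-lexicographic order (all
#' 1-subsets in item order, then 2-subsets, ...), so threshold-passing
#' panels with the fewest members are reached first. Only the current
#' combination is held in memory.
#'
#' @param items vector of items.
#' @param min_len,max_len subset size range (`max_len` clamped to
#'   `length(items)`).
#' @return A stream object: `$nextval()` returns the next subset or `NULL`
#'   when exhausted; `$count` is the closed-form total.
#' @export
#' @examples
#' s <- combination_stream(letters[1:3], 1, 2)
#' s$nextval(); s$nextval()
combination_stream <- function(items, min_len = 1,
                               max_len = length(items)) {
  n <- length(items)
  max_len <- min(max_len, n)
  if (min_len < 1) stop("'min_len' must be >= 1")
  k <- min_len
  idx <- NULL
  done <- n == 0 || min_len > max_len
  nextval <- function() {
    if (done) return(NULL)
    if (is.null(idx)) {
      idx <<- seq_len(k)
      return(items[idx])
    }
    # lexicographic successor of the current k-combination
    j <- k
    while (j >= 1 && idx[j] == n - k + j) j <- j - 1
    if (j < 1) {
      k <<- k + 1
      if (k > max_len) { done <<- TRUE; return(NULL) }
      idx <<- seq_len(k)
      return(items[idx])
    }
    idx[j] <<- idx[j] + 1L
    if (j < k) idx[(j + 1):k] <<- idx[j] + seq_len(k - j)
    items[idx]
  }
  list(nextval = nextval,
       count = n_combinations(n, min_len, max_len))
}

#' Enumerate subsets of a set of items
#'
#' Convenience wrapper over [combination_stream()]: applies `fun` to every
#' subset (or collects the subsets when `fun` is `NULL` and the count is
#' small).
#'
#' @param items vector of items.
#' @param min_len,max_len subset size range.
#' @param fun optional callback applied to each subset; when supplied, only
#'   the count is returned.
#' @param limit guard for materialisation (default 1e6 subsets).
#' @return List of subsets plus count attribute, or the count when `fun`
#'   is given.
#' @export
enumerate_combinations <- function(items, min_len = 1,
                                   max_len = length(items), fun = NULL,
                                   limit = 1e6) {
  s <- combination_stream(items, min_len, max_len)
  if (is.null(fun)) {
    if (s$count > limit)
      stop("refusing to materialise ", s$count, " subsets; pass 'fun' to stream")
    out <- vector("list", s$count)
    i <- 0L
    while (!is.null(cmb <- s$nextval())) { i <- i + 1L; out[[i]] <- cmb }
    attr(out, "count") <- s$count
    out
  } else {
    i <- 0L
    while (!is.null(cmb <- s$nextval())) { i <- i + 1L; fun(cmb) }
    i
  }
}

#' Stage-1 panel audit: counts of homogeneous biomarker panels
#'
#' Stage-1 panels pair one selected band-spec feature with one combination
#' of selected locations, homogeneously per method: each of the seven
#' single-channel methods contributes `n_features * sum(choose(n_channels,
#' 1..max_len))` panels, and coherence contributes `n_features *
#' sum(choose(n_pairs, 1..max_len))`. With the 11 features, 12 channels
#' and 10 pairs of the reference configuration this gives 44,902 panels
#' per single-channel method and 325,567 in total.
#'
#' @param n_features selected band specs (11 in the reference analysis).
#' @param n_channels selected channels (12).
#' @param n_pairs selected coherence pairs (10).
#' @param max_len maximum locations per panel (10).
#' @param n_single_methods number of single-channel methods (7).
#' @return List with `per_single_method`, `single_total`, `coherence`,
#'   `total`, and `channel_combinations`.
#' @export
#' @examples
#' stage1_panel_counts(11, 12, 10)$total  # 325567
stage1_panel_counts <- function(n_features, n_channels, n_pairs,
                                max_len = 10, n_single_methods = 7) {
  ch_comb <- n_combinations(n_channels, 1, max_len)
  pr_comb <- n_combinations(n_pairs, 1, max_len)
  per <- n_features * ch_comb
  coh <- n_features * pr_comb
  list(channel_combinations = ch_comb, pair_combinations = pr_comb,
       per_single_method = per, single_total = n_single_methods * per,
       coherence = coh, total = n_single_methods * per + coh)
}

#' Stream Stage-1 panels
#'
#' Applies `fun(method, band_spec, locations)` to every Stage-1 panel:
#' every selected band spec crossed with every combination (sizes
#' `1..max_len`) of the selected channels for each single-channel method,
#' and of the selected pairs for coherence.
#'
#' @param selected_features character vector of band specs.
#' @param selected_channels character vector of channels.
#' @param selected_pairs character vector of `"A-B"` pairs.
#' @param max_len maximum number of locations per panel (default 10).
#' @param methods single-channel methods to include (default all seven).
#' @param fun callback `function(method, band_spec, locations)`; when
#'   `NULL` only the audit counts are returned. A callback returning
#'   `FALSE` stops the enumeration early (used by capped screens).
#' @return The audit list from [stage1_panel_counts()] with an added
#'   `emitted` count when `fun` was supplied.
#' @export
build_stage1_panels <- function(selected_features, selected_channels,
                                selected_pairs = character(0), max_len = 10,
                                methods = single_channel_methods(),
                                fun = NULL) {
  audit <- stage1_panel_counts(length(selected_features),
                               length(selected_channels),
                               length(selected_pairs), max_len,
                               length(methods))
  if (is.null(fun)) return(audit)
  emitted <- 0L
  stopped <- FALSE
  emit <- function(m, bs, locs) {
    if (identical(fun(m, bs, locs), FALSE)) stopped <<- TRUE
    emitted <<- emitted + 1L
  }
  # size-major order: all 1-location panels of every method and feature
  # first, so capped screens always see the smallest panels
  for (size in seq_len(max_len)) {
    if (stopped) break
    for (m in methods) {
      if (stopped || size > length(selected_channels)) break
      for (bs in selected_features) {
        if (stopped) break
        s <- combination_stream(selected_channels, size, size)
        while (!stopped && !is.null(locs <- s$nextval())) emit(m, bs, locs)
      }
    }
    if (length(selected_pairs) && size <= length(selected_pairs)) {
      for (bs in selected_features) {
        if (stopped) break
        s <- combination_stream(selected_pairs, size, size)
        while (!stopped && !is.null(locs <- s$nextval())) emit("COH", bs, locs)
      }
    }
  }
  audit$emitted <- emitted
  audit$stopped_early <- stopped
  audit
}

#' Stage-2 panels: subsets of individual biomarkers
#'
#' The optimisation stage mixes methods freely: panels are all subsets of
#' the candidate biomarker list up to `max_size` members. With 69
#' candidates and `max_size = 4` the sizes are 69 / 2346 / 52,394 /
#' 864,501, 919,310 panels in total.
#'
#' @param biomarkers character vector of feature ids.
#' @param max_size maximum panel size (default 4).
#' @param fun optional callback applied to each panel (character vector of
#'   feature ids).
#' @return List with `per_size` counts, `total`, and `emitted` when `fun`
#'   was supplied.
#' @export
#' @examples
#' build_stage2_panels(paste0("f", 1:69))$total  # 919310
build_stage2_panels <- function(biomarkers, max_size = 4, fun = NULL) {
  n <- length(biomarkers)
  max_size <- min(max_size, n)
  per <- setNames(choose(n, seq_len(max_size)), seq_len(max_size))
  out <- list(per_size = per, total = sum(per))
  if (!is.null(fun))
    out$emitted <- enumerate_combinations(biomarkers, 1, max_size, fun = fun)
  out
}
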