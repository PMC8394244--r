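# Independent oracle implementations kept deliberately naive; they verify
# the package's optimised paths and are never called by package code.

# Exhaustive-history Lempel-Ziv parser by direct substring search: grow the
# current phrase while it can be copied from everything seen so far
# (including its own first characters); the final phrase counts even when
# still reproducible at the end of the string.
lzc_phrase_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  count <- 0L
  i <- 1L
  while (i <= n) {
    l <- 1L
    repeat {
      q <- substr(s, i, i + l - 1L)
      hist <- substr(s, 1L, i + l - 2L)
      reproducible <- l <= nchar(hist) + 1L && grepl(q, hist, fixed = TRUE)
      if (!reproducible || i + l - 1L == n) break
      l <- l + 1L
    }
    count <- count + 1L
    i <- i + l
  }
  count
}

# Naive O(N^2) approximate entropy with self-matches and Chebyshev distance
apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    cnt <- n - mm + 1L
    logs <- numeric(cnt)
    for (i in seq_len(cnt)) {
      nm <- 0L
      for (j in seq_len(cnt)) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= r)
          nm <- nm + 1L
      }
      logs[i] <- log(nm / cnt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1L)
}

# direct positive-to-negative crossing scan (strict signs)
zci_oracle <- function(x, fs) {
  t <- integer(0)
  for (i in seq_len(length(x) - 1L))
    if (x[i] > 0 && x[i + 1L] < 0) t <- c(t, i)
  if (length(t) < 2) return(NaN)
  mean(diff(t)) / fs
}

make_record <- function(nch = 2, secs = 8, fs = 128, channels = NULL,
                        id = "s1", group = "UNKNOWN", seed = 1) {
  set.seed(seed)
  if (is.null(channels)) channels <- montage_1020()[seq_len(nch)]
  eeg_record(matrix(rnorm(length(channels) * fs * secs), length(channels)),
             fs = fs, channels = channels, subject_id = id, group = group)
}

# small tabular cohort with optional informative features (mean shift d)
make_feature_cohort <- function(n_per_group = 20, n_features = 10,
                                informative = integer(0), d = 3, seed = 1,
                                ids = NULL) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(rnorm(n * n_features), n)
  groups <- rep(c("NOLD", "AD"), each = n_per_group)
  for (j in informative) x[groups == "AD", j] <- x[groups == "AD", j] + d
  if (is.null(ids)) {
    pool <- as.vector(outer(band_specs(), montage_1020(),
                            feature_id, method = "TSEN"))
    ids <- pool[seq_len(n_features)]
  }
  colnames(x) <- ids
  biomarker_table(x, groups)
}
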