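fs <- 128

test_that("Tsallis entropy matches its closed forms", {
  expect_equal(tsallis_entropy(rep(3.2, 100)), 0)
  # two bins with equal mass, q = 0.5: (1 - 2*sqrt(0.5)) / (q - 1)
  two_bin <- (1 - 2 * 0.5^0.5) / (0.5 - 1)
  expect_equal(tsallis_entropy(rep(c(0, 1), 50), q = 0.5), two_bin,
               tolerance = 1e-12)
  # defaults: k = 2200 states, q = 0.5
  expect_identical(formals(tsallis_entropy)$k_states, 2200)
  expect_identical(formals(tsallis_entropy)$q, 0.5)
  expect_error(tsallis_entropy(rnorm(10), q = 1), "must not be 1")
})

test_that("Higuchi fractal dimension recovers known dimensions", {
  expect_equal(higuchi_fd(seq_len(1000), kmax = 8), 1, tolerance = 0.05)
  set.seed(21)
  expect_equal(higuchi_fd(rnorm(4096), kmax = 8), 2, tolerance = 0.15)
  expect_equal(higuchi_fd(rep(1, 100)), 1)  # degenerate constant
  expect_error(higuchi_fd(rnorm(10), kmax = 8), ">= 2 \\* kmax")
  # the literal mean-curve-length variant is a different summary
  expect_gt(higuchi_fd(rnorm(512), variant = "curve-mean"), 0)
})

test_that("Lempel-Ziv complexity agrees with the exhaustive-history oracle", {
  expect_equal(lempel_ziv_complexity(rep(1, 16)), 2 / (16 / 4))
  expect_equal(lempel_ziv_complexity(c(0L, 1L, 0L, 0L)), 3 / (4 / 2))
  # exact agreement with the brute-force parser on all binary strings
  # of length 2..12
  for (n in 2:12) {
    strings <- lapply(0:(2^n - 1), function(v) as.integer(intToBits(v)[1:n]))
    pkg <- vapply(strings, adeeg:::lz76_count, 0L)
    oracle <- vapply(strings, lzc_phrase_oracle, 0L)
    expect_identical(pkg, oracle)
  }
  # random +-1 sequences normalise to ~1
  set.seed(5)
  x <- sample(rep(c(-1, 1), 5000))  # balanced so the median splits the levels
  expect_gt(lempel_ziv_complexity(x), 0.9)
  expect_lt(lempel_ziv_complexity(x), 1.2)
})

test_that("approximate entropy equals the naive O(N^2) oracle", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(30:80, 1)
    x <- rnorm(n)
    r <- 0.15 * sd(x)
    expect_equal(approximate_entropy(x, 2, r), apen_oracle(x, 2, r),
                 tolerance = 1e-9)
  }
  expect_equal(approximate_entropy(rep(2, 50)), 0)
  # alternating two-level sequence is perfectly regular
  alt <- rep(c(0, 1), 50)
  expect_lt(abs(approximate_entropy(alt, 2, 0.1 * diff(range(alt)))), 0.02)
  expect_error(approximate_entropy(rnorm(50), r = -1), "positive")
})

test_that("zero-crossing intervals track oscillation period", {
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  expect_equal(zero_crossing_interval(sin(2 * pi * 10 * t), fs), 0.1,
               tolerance = 1 / fs / 0.1)
  expect_equal(zero_crossing_interval(sin(2 * pi * 5 * t), fs), 0.2,
               tolerance = 1 / fs / 0.2)
  expect_true(is.nan(zero_crossing_interval(abs(rnorm(100)) + 1, fs)))
  # agreement with the direct scan on random signals
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(200)
    expect_identical(zero_crossing_interval(x, fs), zci_oracle(x, fs))
  }
})

test_that("amplitude change rate follows its telescoping closed forms", {
  expect_equal(amplitude_change_rate(rep(7, 256), fs), 0)
  # ramp with slope s uV/sample: rate = s * fs uV/s
  expect_equal(amplitude_change_rate(0.5 * seq_len(257), fs), 0.5 * fs)
  # whole cycles telescope to ~0
  t <- seq(0, 2, by = 1 / fs)
  expect_lt(abs(amplitude_change_rate(sin(2 * pi * 4 * t), fs)),
            1e-6 * 1 * fs)
  expect_error(amplitude_change_rate(rnorm(100), fs), "full second")
})

test_that("band power concentrates on the driving frequency", {
  expect_equal(band_power(rep(0, 1024), fs, "alpha"), 0)
  x10 <- sin(2 * pi * 10 * seq(0, 8 - 1 / fs, by = 1 / fs))
  per_band <- vapply(names(eeg_bands()), band_power, 0, x = x10, fs = fs)
  expect_gte(per_band["alpha"] / sum(per_band), 0.99)
  # flat spectrum: mean band power roughly equal across equal-width bands
  set.seed(11)
  ratios <- replicate(50, {
    w <- rnorm(fs * 8)
    band_power(w, fs, "alpha") / band_power(w, fs, "theta")
  })
  expect_equal(mean(ratios), 1, tolerance = 0.2)
})

test_that("coherence behaves at its closed-form limits", {
  set.seed(12)
  a <- rnorm(fs * 180)
  expect_equal(msc_coherence(a, a, fs, "alpha"), 1, tolerance = 1e-10)
  b <- rnorm(fs * 180)
  for (band in names(eeg_bands()))
    expect_lt(msc_coherence(a, b, fs, band), 0.2)
  # snr / (1 + snr) law at high snr
  noisy <- a + 0.01 * rnorm(length(a))
  expect_gt(msc_coherence(a, noisy, fs, "alpha"), 0.95)
  expect_error(msc_coherence(a[1:256], b[1:256], fs, "alpha"), "4 s")
})

test_that("ordered ratio features are directional and guard zero division", {
  expect_equal(ratio_feature(2, 2), 1)
  expect_equal(ratio_feature(2, 4), 0.5)
  expect_equal(ratio_feature(4, 2), 2)
  expect_true(is.nan(ratio_feature(1, 0)))
  expect_true(is.nan(ratio_feature(NaN, 2)))
})

test_that("extractors have the expected offset and scale invariances", {
  set.seed(13)
  x <- rnorm(600)
  # offset invariance
  expect_equal(tsallis_entropy(x + 100), tsallis_entropy(x))
  expect_equal(lempel_ziv_complexity(x + 100), lempel_ziv_complexity(x))
  expect_equal(higuchi_fd(x + 100), higuchi_fd(x))
  expect_equal(approximate_entropy(x + 100), approximate_entropy(x),
               tolerance = 1e-9)
  # ZCI is deliberately not offset-invariant (crossings move)
  expect_false(isTRUE(all.equal(zero_crossing_interval(x + 10, fs),
                                zero_crossing_interval(x, fs))))
  # positive rescaling invariance (ApEn via r proportional to SD)
  expect_equal(tsallis_entropy(3 * x), tsallis_entropy(x))
  expect_equal(lempel_ziv_complexity(3 * x), lempel_ziv_complexity(x))
  expect_equal(higuchi_fd(3 * x), higuchi_fd(x), tolerance = 1e-9)
  expect_equal(approximate_entropy(3 * x, 2, 0.15 * sd(3 * x)),
               approximate_entropy(x, 2, 0.15 * sd(x)), tolerance = 1e-9)
})
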