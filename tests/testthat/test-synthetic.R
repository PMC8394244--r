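fast_spec <- function(...) {
  cohort_spec(n_ad = 2, n_nold = 2, duration = 8, ...)
}

test_that("cohort generation has the declared shape and determinism", {
  spec <- fast_spec(seed = 71)
  coh <- generate_cohort(spec)
  expect_length(coh$records, 4)
  expect_equal(dim(coh$records[[1]]$data), c(19, 8 * 128))
  expect_identical(coh$records[[1]]$group, "NOLD")
  expect_identical(coh$records[[4]]$group, "AD")

  coh2 <- generate_cohort(spec)
  expect_identical(coh$records[[3]]$data, coh2$records[[3]]$data)

  # per-subject streams: extending the cohort preserves earlier subjects
  spec_big <- cohort_spec(n_ad = 3, n_nold = 2, duration = 8, seed = 71)
  coh3 <- generate_cohort(spec_big)
  expect_identical(coh3$records[[3]]$data, coh$records[[3]]$data)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(ar_base = 0.9, complexity_effect = 0.2))
  expect_error(cohort_spec(slowing_effect = -0.1))
  expect_error(cohort_spec(band_weights = c(delta = 1)), "five bands")
})

test_that("the slowing effect raises the AD theta/alpha power ratio", {
  ratio_of <- function(rec) {
    x <- rec$data[1, ]
    band_power(x, rec$fs, "theta") / band_power(x, rec$fs, "alpha")
  }
  ad <- c(); nold <- c()
  for (s in 1:6) {
    spec <- cohort_spec(n_ad = 4, n_nold = 4, duration = 10,
                        channels = c("P3", "P4"), seed = 700 + s)
    coh <- generate_cohort(spec)
    g <- vapply(coh$records, function(r) r$group, "")
    r <- vapply(coh$records, ratio_of, 0)
    ad <- c(ad, r[g == "AD"]); nold <- c(nold, r[g == "NOLD"])
  }
  expect_lt(t.test(ad, nold, alternative = "greater")$p.value, 0.01)
})

test_that("the complexity effect lowers AD Lempel-Ziv complexity", {
  lzc_of <- function(rec)
    lempel_ziv_complexity(adeeg:::band_filter_vec(rec$data[1, ], rec$fs,
                                                  c(0.5, 45)))
  ad <- c(); nold <- c()
  for (s in 1:6) {
    spec <- cohort_spec(n_ad = 4, n_nold = 4, duration = 10,
                        channels = c("P3", "P4"), slowing_effect = 0,
                        coherence_effect = 0, complexity_effect = 0.4,
                        seed = 710 + s)
    coh <- generate_cohort(spec)
    g <- vapply(coh$records, function(r) r$group, "")
    v <- vapply(coh$records, lzc_of, 0)
    ad <- c(ad, v[g == "AD"]); nold <- c(nold, v[g == "NOLD"])
  }
  expect_lt(t.test(ad, nold, alternative = "less")$p.value, 0.01)
})

test_that("the coherence effect lowers AD inter-channel alpha coherence", {
  coh_of <- function(rec)
    msc_coherence(rec$data[1, ], rec$data[2, ], rec$fs, "alpha")
  ad <- c(); nold <- c()
  for (s in 1:6) {
    spec <- cohort_spec(n_ad = 4, n_nold = 4, duration = 10,
                        channels = c("P3", "P4"), slowing_effect = 0,
                        complexity_effect = 0, coherence_effect = 0.7,
                        seed = 720 + s)
    coh <- generate_cohort(spec)
    g <- vapply(coh$records, function(r) r$group, "")
    v <- vapply(coh$records, coh_of, 0)
    expect_true(all(v >= 0 & v <= 1))
    ad <- c(ad, v[g == "AD"]); nold <- c(nold, v[g == "NOLD"])
  }
  expect_lt(t.test(ad, nold, alternative = "less")$p.value, 0.01)
})

test_that("effects are monotone in their planted strength", {
  mean_ad <- function(effect, what) {
    vals <- c()
    for (s in 1:3) {
      spec <- cohort_spec(n_ad = 3, n_nold = 0, duration = 10,
                          channels = c("P3", "P4"),
                          slowing_effect = if (what == "slow") effect else 0,
                          complexity_effect = if (what == "cplx") effect else 0,
                          coherence_effect = if (what == "coh") effect else 0,
                          seed = 730 + s)
      for (i in 1:3) {
        rec <- generate_subject(spec, "AD", i)
        vals <- c(vals, switch(what,
          slow = band_power(rec$data[1, ], 128, "theta") /
                 band_power(rec$data[1, ], 128, "alpha"),
          cplx = lempel_ziv_complexity(
                   adeeg:::band_filter_vec(rec$data[1, ], 128, c(0.5, 45))),
          coh = msc_coherence(rec$data[1, ], rec$data[2, ], 128, "alpha")))
      }
    }
    mean(vals)
  }
  slow <- vapply(c(0, 0.3, 0.6), mean_ad, 0, what = "slow")
  expect_true(all(diff(slow) > 0))
  cplx <- vapply(c(0, 0.3, 0.6), mean_ad, 0, what = "cplx")
  expect_true(all(diff(cplx) < 0))
  coh <- vapply(c(0, 0.4, 0.8), mean_ad, 0, what = "coh")
  expect_true(all(diff(coh) < 0))
})

test_that("zero effects make the groups exchangeable", {
  ps <- c()
  for (s in 1:8) {
    spec <- cohort_spec(n_ad = 4, n_nold = 4, duration = 8,
                        channels = c("P3", "P4"), slowing_effect = 0,
                        complexity_effect = 0, coherence_effect = 0,
                        seed = 740 + s)
    coh <- generate_cohort(spec)
    g <- vapply(coh$records, function(r) r$group, "")
    v <- vapply(coh$records, function(r)
      band_power(r$data[1, ], r$fs, "alpha"), 0)
    ps <- c(ps, t.test(v[g == "AD"], v[g == "NOLD"])$p.value)
  }
  # p-values should look uniform, not systematically small
  expect_gt(mean(ps), 0.2)
  expect_gt(min(ps), 0.001)
})

test_that("cohorts round-trip through the on-disk CSV + manifest format", {
  spec <- cohort_spec(n_ad = 1, n_nold = 1, duration = 4,
                      channels = c("C3", "C4"), seed = 75)
  coh <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(coh, spec, dir)
  back <- read_cohort(dir)
  expect_length(back$records, 2)
  expect_equal(back$records[[1]]$data, coh$records[[1]]$data,
               tolerance = 1e-12)
  expect_identical(back$records[[2]]$group, "AD")
  expect_equal(back$truth$slowing_effect, 0.3)
})
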