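# Zero-phase Chebyshev-II band filtering.
#
# Each band is isolated by a cascade of an order-8 Chebyshev type II
# highpass (stopband edge at 0.85 * lo) and an order-8 Chebyshev type II
# lowpass (stopband edge at 1.18 * hi), each with 40 dB stopband
# attenuation, applied forward-backward for zero phase. The cascade keeps
# the passband flat (Chebyshev II is monotone in the passband) while the
# stopband edges sit close enough to the band that one octave outside the
# band the attenuation is well past 40 dB, and adjacent band responses
# overlap enough that the five-band sum retains the broadband variance.
# The delta low edge is clamped to 0.5 Hz: DC drift carries no neural
# signal.

design_band_filter <- function(band, fs) {
  nyq <- fs / 2
  lo <- max(band[1], 0.5)
  hi <- band[2]
  if (hi >= nyq) stop("band high edge (", hi, " Hz) must be below Nyquist (",
                      nyq, " Hz)")
  if (lo >= hi) stop("invalid band edges: ", lo, " >= ", hi)
  list(hp = as_biquads(signal::cheby2(8, 40, (0.85 * lo) / nyq,
                                      type = "high")),
       lp = as_biquads(signal::cheby2(8, 40, min(1.18 * hi, 0.99 * nyq) / nyq,
                                      type = "low")))
}

# Factor a transfer-function filter into second-order sections. The
# direct order-8 polynomial form loses stopband accuracy at the small
# normalised frequencies of the delta/theta bands; cascaded biquads are
# the numerically robust realisation.
as_biquads <- function(filt) {
  b <- as.numeric(filt$b); a <- as.numeric(filt$a)
  gain <- b[1] / a[1]
  pair_up <- function(coefs) {
    r <- polyroot(rev(coefs / coefs[1]))
    r <- r[order(-Im(r), Re(r))]
    upper <- r[Im(r) > 1e-8]
    real <- sort(Re(r[abs(Im(r)) <= 1e-8]))
    sections <- lapply(upper, function(z)
      c(1, -2 * Re(z), Mod(z)^2))
    if (length(real)) {
      for (i in seq(1, length(real) - 1, by = 2))
        sections[[length(sections) + 1]] <-
          c(1, -(real[i] + real[i + 1]), real[i] * real[i + 1])
    }
    sections
  }
  zs <- pair_up(b)
  ps <- pair_up(a)
  stopifnot(length(zs) == length(ps))
  list(gain = gain,
       sections = Map(function(bq, aq) list(b = bq, a = aq), zs, ps))
}

# one causal pass through the biquad cascade (a[1] normalised to 1)
sos_pass <- function(bq, x) {
  for (s in bq$sections) {
    v <- stats::filter(c(0, 0, x), filter = s$b, method = "convolution",
                       sides = 1)[-(1:2)]
    x <- as.numeric(stats::filter(v, filter = -s$a[-1],
                                  method = "recursive"))
  }
  x * bq$gain
}

# forward-backward biquad-cascade filtering with reflection padding to
# suppress edge transients
filtfilt_padded <- function(bq, x, fs) {
  n <- length(x)
  np <- min(n - 1L, as.integer(3 * fs))
  if (np >= 2) {
    pre <- 2 * x[1] - x[(np + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - np)]
    x <- c(pre, x, post)
  } else np <- 0L
  x <- rev(sos_pass(bq, rev(sos_pass(bq, x))))
  if (np > 0) x[(np + 1):(np + n)] else x
}

band_filter_vec <- function(x, fs, band) {
  d <- design_band_filter(band, fs)
  filtfilt_padded(d$lp, filtfilt_padded(d$hp, x, fs), fs)
}

#' Band-pass filter an EEG record
#'
#' Zero-phase Chebyshev type II band-pass (order-8 highpass plus order-8
#' lowpass, 40 dB stopband attenuation, forward-backward). `band` may be a
#' canonical band name or a `c(lo, hi)` pair in Hz; the delta low edge is
#' clamped to 0.5 Hz.
#'
#' @param record an [eeg_record()].
#' @param band band name (`"delta"`, ..., `"gamma"`) or numeric `c(lo, hi)`.
#' @return The filtered record.
#' @export
#' @examples
#' rec <- eeg_record(matrix(rnorm(512), 1), 128, "C3")
#' alpha <- band_filter(rec, "alpha")
band_filter <- function(record, band) {
  if (is.character(band)) {
    band <- eeg_bands()[[match.arg(band, band_names())]]
  }
  filtered <- t(apply(record$data, 1, band_filter_vec, fs = record$fs,
                      band = band))
  eeg_record(filtered, fs = record$fs, channels = record$channels,
             subject_id = record$subject_id, group = record$group)
}

# filter one channel into all five bands at once; returns a named list of
# numeric vectors (used heavily by extract_features and the generator)
filter_bank_vec <- function(x, fs) {
  lapply(eeg_bands(), function(b) band_filter_vec(x, fs, b))
}
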