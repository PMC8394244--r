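# The eight biomarker families. All extractors take a plain numeric
# amplitude sequence (one channel, usually band-filtered) and return a
# scalar; non-finite sentinels mark undefined values and are excluded (with
# a reason) when the biomarker table is assembled.

#' Tsallis entropy of an amplitude sequence
#'
#' Amplitudes are quantised into `k_states` equal-width bins spanning
#' `[min(x), max(x)]`; with bin probabilities `P_i` the statistic is
#' `sum(P_i - P_i^q) / (q - 1)` (empty bins contribute zero). Lower values
#' indicate a more concentrated amplitude distribution; EEG complexity
#' falls in Alzheimer's disease. Defaults `k_states = 2200`, `q = 0.5`.
#'
#' @param x numeric amplitude sequence (length >= 2).
#' @param k_states number of quantisation states (>= 2).
#' @param q Tsallis order, any real except 1.
#' @return The Tsallis entropy (0 for a constant sequence).
#' @export
#' @examples
#' tsallis_entropy(rep(c(0, 1), 50))  # two equal-mass bins: ~0.8284
tsallis_entropy <- function(x, k_states = 2200, q = 0.5) {
  if (length(x) < 2) stop("'x' must have length >= 2")
  if (k_states < 2) stop("'k_states' must be >= 2")
  if (q == 1) stop("'q' must not be 1 (use the Shannon limit explicitly)")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  bins <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * k_states) + 1L,
               k_states)
  p <- tabulate(bins, nbins = k_states) / length(x)
  p <- p[p > 0]
  sum(p - p^q) / (q - 1)
}

#' Higuchi fractal dimension
#'
#' Builds the `k`-decimated subseries `x(m), x(m+k), ...` for
#' `m = 1..k`, computes the normalised curve length `L_m(k)`, averages over
#' `m`, and estimates the fractal dimension as the negative slope of the
#' least-squares fit of `log L(k)` on `log k` for `k = 1..kmax`
#' (`variant = "slope"`, the canonical Higuchi estimator). The literal
#' mean-of-curve-lengths variant is available as `variant = "curve-mean"`
#' for comparison. A smooth curve has dimension ~1, uncorrelated noise ~2.
#'
#' @param x numeric sequence with `length(x) >= 2 * kmax`.
#' @param kmax maximum decimation factor (default 8).
#' @param variant `"slope"` (fractal dimension) or `"curve-mean"` (mean of
#'   `L(k)`, a curve-length summary rather than a dimension).
#' @return Fractal dimension (1 for a degenerate constant signal).
#' @export
higuchi_fd <- function(x, kmax = 8, variant = c("slope", "curve-mean")) {
  variant <- match.arg(variant)
  n <- length(x)
  if (n < 2 * kmax) stop("length(x) must be >= 2 * kmax")
  lk <- vapply(seq_len(kmax), function(k) {
    lm <- vapply(seq_len(k), function(m) {
      idx <- seq.int(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      nseg <- length(idx) - 1L
      sum(abs(diff(x[idx]))) * (n - 1) / (nseg * k) / k
    }, 0)
    mean(lm, na.rm = TRUE)
  }, 0)
  if (variant == "curve-mean") return(mean(lk))
  if (all(lk == 0)) return(1)  # constant signal: zero-length curve
  pos <- lk > 0
  if (sum(pos) < 2) return(1)
  fit <- stats::lm.fit(cbind(1, log(seq_len(kmax)[pos])), log(lk[pos]))
  -fit$coefficients[[2]]
}

#' Lempel-Ziv complexity of an amplitude sequence
#'
#' The sequence is binarised at its median (`x >= median -> 1`), parsed
#' left-to-right with the exhaustive-history rule into `c(N)` phrases, and
#' normalised by the asymptotic bound `N / log2(N)`:
#' `C(N) = c(N) / (N / log2 N)`. Random sequences score ~1; regular ones
#' score lower. EEG complexity falls in Alzheimer's disease.
#'
#' @param x numeric amplitude sequence (length >= 2), or an integer 0/1
#'   vector that is used as the binary sequence directly.
#' @return Normalised complexity `C(N) > 0`.
#' @export
#' @examples
#' lempel_ziv_complexity(rep(1, 16))  # c = 2, C = 0.5
lempel_ziv_complexity <- function(x) {
  n <- length(x)
  if (n < 2) stop("'x' must have length >= 2")
  if (is.integer(x) && all(x %in% c(0L, 1L))) {
    bits <- x
  } else {
    bits <- as.integer(x >= median(x))
  }
  cN <- lz76_count(bits)
  cN / (n / log2(n))
}

#' Approximate entropy
#'
#' `ApEn(m, r, N) = phi^m(r) - phi^(m+1)(r)` where `phi^m(r)` is the mean
#' log fraction of length-`m` templates within Chebyshev distance `r`
#' (self-matches included). Regular signals score near 0, irregular ones
#' higher. Default tolerance is `0.15 * sd(x)`, the usual physiologic
#' convention.
#'
#' @param x numeric sequence with `length(x) >= m + 2`.
#' @param m template (run) length, default 2.
#' @param r tolerance (> 0); default `0.15 * sd(x)`.
#' @return Approximate entropy (0 for a constant sequence).
#' @export
approximate_entropy <- function(x, m = 2, r = 0.15 * sd(x)) {
  if (length(x) < m + 2) stop("length(x) must be >= m + 2")
  if (!is.finite(r) || r <= 0) {
    if (sd(x) == 0) return(0)  # constant signal: all templates identical
    stop("'r' must be positive")
  }
  apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Mean zero-crossing interval
#'
#' Collects the sample times `t` with `x[t] > 0` and `x[t+1] < 0` (strict
#' positive-to-negative transitions; exact zeros never open or close a
#' crossing) and returns the mean interval between successive crossings in
#' seconds. Slower EEG has longer intervals. With fewer than two crossings
#' the value is undefined and `NaN` is returned (excluded downstream).
#'
#' @param x numeric amplitude sequence (length >= 2).
#' @param fs sampling rate in Hz.
#' @return Mean inter-crossing interval in seconds, or `NaN`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 128)
#' zero_crossing_interval(sin(2 * pi * 10 * t), 128)  # ~0.1 s
zero_crossing_interval <- function(x, fs) {
  if (length(x) < 2) stop("'x' must have length >= 2")
  n <- length(x)
  t <- which(x[-n] > 0 & x[-1] < 0)
  if (length(t) < 2) return(NaN)
  mean(diff(t)) / fs
}

#' Mean per-second amplitude change rate
#'
#' Partitions the signal into one-second blocks; within each block the
#' rate is the sum of successive amplitude differences over the summed
#' time steps (`sum(dx) / sum(dt)`, uV/s), and the biomarker is the mean
#' rate over blocks. Each block spans a full second of differences (its
#' closing sample is the next block's opening sample), so the signed
#' differences telescope and a sinusoid over whole cycles scores ~0 —
#' the statistic tracks net drift per second, a slowing-sensitive measure.
#'
#' @param x numeric amplitude sequence with `length(x) >= fs`.
#' @param fs sampling rate in Hz (integer samples per block).
#' @return Mean amplitude change rate in uV/s.
#' @export
amplitude_change_rate <- function(x, fs) {
  fs <- as.integer(fs)
  n <- length(x)
  if (n < fs) stop("'x' must contain at least one full second of samples")
  k <- (n - 1) %/% fs
  if (k < 1) return(sum(diff(x)) / ((n - 1) / fs))
  # block i: samples [(i-1)*fs + 1, i*fs + 1]; sum(dx) telescopes, sum(dt) = 1 s
  starts <- (seq_len(k) - 1L) * fs + 1L
  mean(x[starts + fs] - x[starts])
}

#' Mean band power from the FFT power spectrum
#'
#' Computes `|FFT(x)|^2 / N` and returns the mean over the positive
#' frequency bins falling in `[lo, hi)`. The DC bin is excluded (a constant
#' offset carries no neural signal, consistent with the 0.5 Hz delta
#' clamp used in filtering).
#'
#' @param x numeric amplitude sequence (length >= 2).
#' @param fs sampling rate in Hz.
#' @param band band name or numeric `c(lo, hi)` in Hz.
#' @return Mean power in uV^2 over the band bins.
#' @export
band_power <- function(x, fs, band) {
  if (is.character(band)) band <- eeg_bands()[[match.arg(band, band_names())]]
  n <- length(x)
  if (n < 2) stop("'x' must have length >= 2")
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2 & f > 0
  sel <- half & f >= band[1] & f < band[2]
  if (!any(sel)) stop("no positive-frequency bins in band [", band[1], ", ",
                      band[2], ") at fs = ", fs)
  mean(p[sel])
}

# Welch segment FFTs: matrix of windowed segment spectra (bins x segments),
# 50% overlap Hann by default; segment means removed.
welch_segments <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nseg <- as.integer(round(seg_s * fs))
  if (length(x) < 2 * nseg)
    stop("signal too short for Welch estimation (need >= ", 2 * seg_s, " s)")
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq.int(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0, nseg - 1) / (nseg - 1))  # Hann
  vapply(starts, function(s) {
    seg <- x[s:(s + nseg - 1L)]
    fft((seg - mean(seg)) * w)
  }, complex(nseg))
}

#' Magnitude-squared coherence between two channels, averaged over a band
#'
#' Welch estimate (2 s Hann segments, 50% overlap) of
#' `|P_ab(f)|^2 / (P_aa(f) * P_bb(f))`, averaged over the positive
#' frequency bins in `[lo, hi)`. Values lie in `[0, 1]`; functional
#' connectivity (and hence coherence) is reduced in Alzheimer's disease.
#'
#' @param a,b equal-length numeric sequences (>= 4 s of data).
#' @param fs sampling rate in Hz.
#' @param band band name or numeric `c(lo, hi)` in Hz.
#' @param seg_s Welch segment length in seconds (default 2).
#' @param overlap fractional segment overlap (default 0.5).
#' @return Band-averaged magnitude-squared coherence in `[0, 1]`.
#' @export
msc_coherence <- function(a, b, fs, band, seg_s = 2, overlap = 0.5) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  sa <- welch_segments(a, fs, seg_s, overlap)
  sb <- welch_segments(b, fs, seg_s, overlap)
  coh <- msc_from_segments(sa, sb)
  mean(coh[band_bins(nrow(sa), fs, band)])
}

# coherence spectrum from two segment-FFT matrices
msc_from_segments <- function(sa, sb) {
  pab <- rowMeans(sa * Conj(sb))
  paa <- rowMeans(Mod(sa)^2)
  pbb <- rowMeans(Mod(sb)^2)
  out <- Mod(pab)^2 / (paa * pbb)
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

band_bins <- function(nfft, fs, band) {
  if (is.character(band)) band <- eeg_bands()[[match.arg(band, band_names())]]
  f <- (seq_len(nfft) - 1) * fs / nfft
  sel <- f <= fs / 2 & f > 0 & f >= band[1] & f < band[2]
  if (!any(sel)) stop("no frequency bins in band [", band[1], ", ", band[2],
                      ") for Welch grid")
  which(sel)
}

#' Ordered band-ratio feature
#'
#' A ratio feature divides the same biomarker evaluated on two band-filtered
#' versions of the signal; theta/alpha and alpha/theta are distinct
#' features. A denominator within `1e-12` of zero yields `NaN`, which is
#' excluded downstream with a logged reason.
#'
#' @param value_num,value_den the biomarker values for the numerator and
#'   denominator bands.
#' @return `value_num / value_den`, or `NaN` when undefined.
#' @export
ratio_feature <- function(value_num, value_den) {
  if (!is.finite(value_num) || !is.finite(value_den)) return(NaN)
  if (abs(value_den) < 1e-12) return(NaN)
  value_num / value_den
}
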