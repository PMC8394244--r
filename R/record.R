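#' Construct a multichannel EEG record
#'
#' The basic container for one subject's EEG: a channels x samples matrix
#' of amplitudes in microvolts together with the sampling rate, channel
#' labels and the subject's diagnostic group.
#'
#' @param data numeric matrix, one row per channel, amplitudes in uV.
#' @param fs sampling rate in Hz (positive).
#' @param channels character vector of unique channel labels, one per row.
#' @param subject_id subject identifier.
#' @param group `"AD"`, `"NOLD"` or `"UNKNOWN"`.
#' @return An object of class `eeg_record`.
#' @export
#' @examples
#' rec <- eeg_record(matrix(rnorm(2 * 512), 2), fs = 128,
#'                   channels = c("C3", "C4"), subject_id = "s1")
#' rec
eeg_record <- function(data, fs, channels, subject_id = "subject",
                       group = c("UNKNOWN", "AD", "NOLD")) {
  group <- match.arg(toupper(group[1]), c("UNKNOWN", "AD", "NOLD"))
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix (channels x samples)")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  if (length(channels) != nrow(data))
    stop("channel label count (", length(channels),
         ") does not match data rows (", nrow(data), ")")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  if (ncol(data) < 2 * fs)
    stop("record must contain at least 2 seconds of data (",
         ncol(data), " samples at ", fs, " Hz)")
  rownames(data) <- channels
  structure(list(subject_id = as.character(subject_id), group = group,
                 fs = fs, channels = as.character(channels), data = data),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

record_duration <- function(record) ncol(record$data) / record$fs

#' Halve the sampling rate by averaging consecutive sample pairs
#'
#' Output sample `t` is the mean of input samples `2t` and `2t + 1`
#' (0-based); an odd trailing sample is dropped with a warning. This is the
#' storage downsampling applied to 256 Hz clinical records to obtain 128 Hz.
#'
#' @param record an [eeg_record()].
#' @return The record at half the sampling rate.
#' @export
#' @examples
#' r <- eeg_record(matrix(c(1, 3, 5, 7) , 1, 4), fs = 2, channels = "C3")
#' downsample_pair_average(r)$data  # 2, 6 at 1 Hz
downsample_pair_average <- function(record) {
  n <- ncol(record$data)
  if (n %% 2 == 1) {
    warning("odd sample count (", n, "); dropping trailing sample")
    n <- n - 1
  }
  even <- record$data[, seq(1, n, by = 2), drop = FALSE]
  odd <- record$data[, seq(2, n, by = 2), drop = FALSE]
  eeg_record((even + odd) / 2, fs = record$fs / 2, channels = record$channels,
             subject_id = record$subject_id, group = record$group)
}

#' Trim a record to a fixed time interval
#'
#' Returns the samples in the half-open interval `[start_s, end_s)`
#' (seconds, 0-based samples). The default 61-240 s window skips the
#' electrical artefact common at the start of clinical records; records too
#' short for the window are returned unchanged with a warning.
#'
#' @param record an [eeg_record()].
#' @param start_s,end_s interval bounds in seconds.
#' @return The trimmed record.
#' @export
trim_interval <- function(record, start_s = 61, end_s = 240) {
  if (start_s >= end_s) stop("'start_s' must be < 'end_s'")
  if (start_s < 0) stop("'start_s' must be >= 0")
  dur <- record_duration(record)
  if (end_s > dur) {
    warning(sprintf(
      "record '%s' is %.1f s, shorter than the %g-%g s window; using full record",
      record$subject_id, dur, start_s, end_s))
    return(record)
  }
  idx <- seq.int(floor(start_s * record$fs) + 1L, floor(end_s * record$fs))
  eeg_record(record$data[, idx, drop = FALSE], fs = record$fs,
             channels = record$channels, subject_id = record$subject_id,
             group = record$group)
}
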