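# Minimal EDF (European Data Format) I/O.
#
# EDF is a fixed-layout format: a 256-byte ASCII header, 256 ASCII bytes of
# per-signal header fields per signal, then data records of little-endian
# int16 samples, signal-by-signal within each record. The reader below
# covers that core layout (EDF and the EDF+ continuous flavour), which is
# all that resting-state clinical exports use.

read_ascii <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  trimws(rawToChar(raw))
}

#' Read an EDF file into an [eeg_record()]
#'
#' Channel labels are normalised onto the 10-20 montage (case-insensitive,
#' reference suffixes such as `"T3-A1"` stripped, modern `T7/T8/P7/P8`
#' names mapped to `T3/T4/T5/T6`). Signals whose label does not match a
#' montage channel are dropped with a warning; a file with no montage
#' channel at all is an error.
#'
#' @param path path to an EDF file.
#' @param subject_id subject id; default the file name.
#' @param group diagnostic group label.
#' @return An [eeg_record()] with amplitudes scaled to physical units (uV).
#' @export
read_edf <- function(path, subject_id = NULL,
                     group = c("UNKNOWN", "AD", "NOLD")) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  version <- read_ascii(con, 8)
  if (!grepl("^0", version)) stop("not an EDF file (bad version field): ", path)
  invisible(read_ascii(con, 80))  # patient
  invisible(read_ascii(con, 80))  # recording
  invisible(read_ascii(con, 16))  # start date + time
  header_bytes <- as.integer(read_ascii(con, 8))
  invisible(read_ascii(con, 44))  # reserved
  n_records <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF header reports no signals: ", path)

  field <- function(width) vapply(seq_len(ns), function(i) read_ascii(con, width), "")
  labels <- field(16)
  invisible(field(80))  # transducer
  invisible(field(8))   # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  invisible(field(80))  # prefiltering
  spr <- as.integer(field(8))
  invisible(field(32))  # reserved

  seek(con, where = header_bytes, origin = "start")
  total <- sum(spr)
  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- numeric(0)
  chunks <- lapply(seq_len(ns), function(i) matrix(0, spr[i], n_records))
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                     endian = "little")
    if (length(block) < total)
      stop("EDF file truncated at record ", r, ": ", path)
    off <- 0L
    for (i in seq_len(ns)) {
      chunks[[i]][, r] <- block[(off + 1L):(off + spr[i])]
      off <- off + spr[i]
    }
  }

  norm <- normalise_channel_label(labels)
  keep <- !is.na(norm)
  if (!any(keep))
    stop("no 10-20 montage channel matched in EDF labels: ",
         paste(labels, collapse = ", "))
  if (any(!keep))
    warning("dropping non-montage EDF signals: ",
            paste(labels[!keep], collapse = ", "))
  keep <- which(keep)
  # duplicated montage labels after normalisation: keep the first
  dup <- duplicated(norm[keep])
  if (any(dup)) {
    warning("dropping duplicated montage channels: ",
            paste(norm[keep][dup], collapse = ", "))
    keep <- keep[!dup]
  }

  fs <- spr[keep] / rec_dur
  if (length(unique(fs)) != 1)
    stop("montage channels have differing sampling rates in ", path)
  data <- t(vapply(keep, function(i) {
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    as.vector(chunks[[i]]) * gain + phys_min[i] - dig_min[i] * gain
  }, numeric(spr[keep[1]] * n_records)))

  if (is.null(subject_id)) subject_id <- sub("\\.edf$", "", basename(path),
                                             ignore.case = TRUE)
  eeg_record(data, fs = fs[1], channels = norm[keep],
             subject_id = subject_id, group = group)
}

#' Write an [eeg_record()] as an EDF file
#'
#' Companion writer used for round-trip testing and for exporting synthetic
#' cohorts; one data record per second, int16 quantisation over the
#' per-channel physical range.
#'
#' @param record an [eeg_record()] with an integer sampling rate.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  fs <- record$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  ns <- nrow(record$data)
  n_records <- floor(ncol(record$data) / fs)
  if (n_records < 1) stop("record shorter than one EDF data record")
  data <- record$data[, seq_len(n_records * fs), drop = FALSE]

  pad <- function(x, width) {
    s <- substr(format(x, width = width), 1, width)
    formatC(s, width = width, flag = "-")
  }
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8), pad(header_bytes, 8),
    pad("EDF+C", 44), pad(n_records, 8), pad(1, 8), pad(ns, 4)),
    con, eos = NULL)

  phys_min <- apply(data, 1, min); phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min < 1e-9
  phys_max[flat] <- phys_min[flat] + 1
  wr <- function(vals, width) writeChar(paste(pad(vals, width), collapse = ""),
                                        con, eos = NULL)
  wr(record$channels, 16)
  wr(rep("", ns), 80)
  wr(rep("uV", ns), 8)
  wr(formatC(phys_min, digits = 4, format = "g"), 8)
  wr(formatC(phys_max, digits = 4, format = "g"), 8)
  wr(rep(-32768, ns), 8)
  wr(rep(32767, ns), 8)
  wr(rep("", ns), 80)
  wr(rep(fs, ns), 8)
  wr(rep("", ns), 32)

  gain <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- unlist(lapply(seq_len(ns), function(i) {
      as.integer(round((data[i, idx] - phys_min[i]) / gain[i])) - 32768L
    }))
    writeBin(block, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a delimited numeric matrix as an [eeg_record()]
#'
#' Rows are channels, columns samples; any whitespace/comma delimiter
#' accepted. Non-numeric cells are reported with their row and column.
#'
#' @param path path to the delimited text file.
#' @param fs sampling rate in Hz.
#' @param labels channel labels, one per matrix row.
#' @param subject_id,group subject metadata.
#' @return An [eeg_record()].
#' @export
read_matrix <- function(path, fs, labels, subject_id = NULL,
                        group = c("UNKNOWN", "AD", "NOLD")) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) strsplit(trimws(l), "[,;\t ]+")[[1]])
  if (length(unique(lengths(rows))) != 1)
    stop("ragged matrix in ", path, ": differing row lengths")
  mat <- matrix(NA_real_, length(rows), length(rows[[1]]))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column %d of %s ('%s')",
                   i, bad[1], path, rows[[i]][bad[1]]))
    mat[i, ] <- v
  }
  if (length(labels) != nrow(mat))
    stop("matrix has ", nrow(mat), " rows but ", length(labels),
         " labels were given")
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  eeg_record(mat, fs = fs, channels = labels, subject_id = subject_id,
             group = group)
}
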