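# Assembly of the subjects x features biomarker table.

default_feature_params <- function() {
  list(k_states = 2200, q = 0.5,        # Tsallis entropy
       kmax = 8,                         # Higuchi
       m = 2, r_factor = 0.15,           # ApEn: r = r_factor * sd(band signal)
       seg_s = 2, overlap = 0.5)         # Welch coherence
}

#' Extract the full biomarker table from a set of EEG records
#'
#' For each of the seven single-channel families (`DPS`, `DEEGA`, `ZCI`,
#' `TSEN`, `HFD`, `APEN`, `LZC`) every record channel is band-filtered into
#' the five canonical bands, the family statistic is computed per band, and
#' the twenty ordered band ratios are formed from those five values —
#' 25 features per channel per family. Coherence (`COH`) contributes 25
#' features per unordered channel pair. A full 19-channel montage therefore
#' yields `7 * 25 * 19 = 3325` single-channel features plus
#' `25 * 171 = 4275` coherence features, 7600 in total
#' (`7 * 25 * C + 25 * C * (C - 1) / 2` for `C` channels).
#'
#' Non-finite biomarker values (e.g. a zero-crossing interval with fewer
#' than two crossings) are recorded as `NA` and listed in the exclusion
#' log attached to the table.
#'
#' @param records list of [eeg_record()]s sharing sampling rate and montage
#'   subset.
#' @param methods biomarker families to compute (default all eight).
#' @param params method parameters; see `default_feature_params()` —
#'   `k_states`, `q` (Tsallis), `kmax` (Higuchi), `m`, `r_factor` (ApEn),
#'   `seg_s`, `overlap` (Welch).
#' @return A `biomarker_table`: list with `values` (subjects x features
#'   matrix), `features` (data frame: method, band_spec, location),
#'   `subjects` (data frame: id, group), `exclusions` (data frame) and
#'   `params`.
#' @export
extract_features <- function(records, methods = method_names(),
                             params = list()) {
  methods <- match.arg(toupper(methods), method_names(), several.ok = TRUE)
  params <- modifyList(default_feature_params(), params)
  if (length(records) == 0) {
    return(new_biomarker_table(matrix(numeric(0), 0, 0), character(0),
                               data.frame(id = character(0),
                                          group = character(0)), params))
  }
  fs <- unique(vapply(records, function(r) r$fs, 0))
  if (length(fs) != 1) stop("all records must share one sampling rate")
  channels <- records[[1]]$channels
  same <- vapply(records, function(r) identical(r$channels, channels), TRUE)
  if (!all(same)) stop("all records must share the same channel set/order")

  ids <- feature_table_ids(channels, methods)
  rows <- lapply(records, extract_subject, methods = methods, params = params,
                 feature_ids = ids)
  values <- do.call(rbind, rows)
  colnames(values) <- ids
  subjects <- data.frame(
    id = vapply(records, function(r) r$subject_id, ""),
    group = vapply(records, function(r) r$group, ""))
  new_biomarker_table(values, ids, subjects, params)
}

feature_table_ids <- function(channels, methods) {
  specs <- band_specs()
  ids <- character(0)
  for (m in intersect(single_channel_methods(), methods))
    ids <- c(ids, as.vector(t(outer(specs, channels, feature_id, method = m))))
  if ("COH" %in% methods) {
    prs <- montage_pairs(channels)
    if (length(prs))
      ids <- c(ids, as.vector(t(outer(specs, prs, feature_id, method = "COH"))))
  }
  ids
}

# per-band scalar for one single-channel family
band_value <- function(method, raw, banded, fs, band_name, params) {
  x <- banded[[band_name]]
  switch(method,
    DPS = band_power(raw, fs, band_name),
    DEEGA = amplitude_change_rate(x, fs),
    ZCI = zero_crossing_interval(x, fs),
    TSEN = tsallis_entropy(x, params$k_states, params$q),
    HFD = higuchi_fd(x, params$kmax),
    APEN = {
      s <- sd(x)
      if (s == 0) 0 else approximate_entropy(x, params$m, params$r_factor * s)
    },
    LZC = lempel_ziv_complexity(x),
    stop("unknown method: ", method))
}

spec_values_from_bands <- function(bv) {
  specs <- band_specs()
  vapply(specs, function(sp) {
    p <- parse_band_spec(sp)
    if (is.na(p[2])) bv[[p[1]]] else ratio_feature(bv[[p[1]]], bv[[p[2]]])
  }, 0)
}

extract_subject <- function(record, methods, params, feature_ids) {
  fs <- record$fs
  channels <- record$channels
  sc <- intersect(single_channel_methods(), methods)
  vals <- setNames(rep(NA_real_, length(feature_ids)), feature_ids)

  if (length(sc)) {
    for (ch in channels) {
      raw <- record$data[ch, ]
      banded <- filter_bank_vec(raw, fs)
      for (m in sc) {
        bv <- lapply(setNames(band_names(), band_names()), function(b)
          tryCatch(band_value(m, raw, banded, fs, b, params),
                   error = function(e) NaN))
        sv <- spec_values_from_bands(bv)
        vals[feature_id(m, names(sv), ch)] <- sv
      }
    }
  }

  if ("COH" %in% methods && length(channels) >= 2) {
    segs <- lapply(setNames(channels, channels), function(ch)
      welch_segments(record$data[ch, ], fs, params$seg_s, params$overlap))
    nfft <- nrow(segs[[1]])
    bins <- lapply(setNames(band_names(), band_names()), function(b)
      band_bins(nfft, fs, b))
    cb <- combn(channels, 2)
    for (i in seq_len(ncol(cb))) {
      a <- cb[1, i]; b <- cb[2, i]
      coh <- msc_from_segments(segs[[a]], segs[[b]])
      bv <- lapply(bins, function(ix) mean(coh[ix]))
      sv <- spec_values_from_bands(bv)
      vals[feature_id("COH", names(sv), paste(a, b, sep = "-"))] <- sv
    }
  }
  vals[!is.finite(vals)] <- NA_real_
  vals
}

new_biomarker_table <- function(values, ids, subjects, params) {
  excl <- data.frame(subject = character(0), feature = character(0),
                     reason = character(0))
  if (length(values) && any(is.na(values))) {
    w <- which(is.na(values), arr.ind = TRUE)
    excl <- data.frame(subject = subjects$id[w[, 1]],
                       feature = ids[w[, 2]],
                       reason = "non-finite biomarker value")
  }
  structure(list(values = values,
                 features = if (length(ids)) parse_feature_id(ids) else
                   data.frame(method = character(0), band_spec = character(0),
                              location = character(0)),
                 subjects = subjects, exclusions = excl, params = params),
            class = "biomarker_table")
}

#' @export
print.biomarker_table <- function(x, ...) {
  cat(sprintf("<biomarker_table> %d subjects x %d features (%d AD / %d Nold)\n",
              nrow(x$values), ncol(x$values),
              sum(x$subjects$group == "AD"), sum(x$subjects$group == "NOLD")))
  if (nrow(x$exclusions))
    cat("  ", nrow(x$exclusions), "values excluded (see $exclusions)\n")
  invisible(x)
}

#' Assemble a biomarker table from a plain matrix
#'
#' Convenience constructor for pre-computed feature matrices (used by the
#' minimal-subset stage and in tests).
#'
#' @param values numeric matrix, subjects in rows, features in columns
#'   (column names must be feature ids from [feature_id()]).
#' @param groups character vector of `"AD"`/`"NOLD"` labels per row.
#' @param ids subject ids (default `S1..Sn`).
#' @return A `biomarker_table`.
#' @export
biomarker_table <- function(values, groups, ids = NULL) {
  if (is.null(colnames(values))) stop("'values' must have feature-id colnames")
  if (length(groups) != nrow(values))
    stop("one group label per subject row is required")
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(values)))
  new_biomarker_table(values, colnames(values),
                      data.frame(id = ids, group = toupper(groups)),
                      default_feature_params())
}

#' Write / read a biomarker table as CSV
#'
#' The CSV stores subject id and group in the first two columns, one
#' feature per remaining column.
#'
#' @param table a `biomarker_table`.
#' @param path output path.
#' @return `path` (write) or the re-read `biomarker_table` (read).
#' @export
write_biomarker_table <- function(table, path) {
  df <- data.frame(subject = table$subjects$id, group = table$subjects$group,
                   table$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biomarker_table
#' @export
read_biomarker_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  biomarker_table(vals, df$group, df$subject)
}

# subset columns, keeping metadata consistent
subset_features <- function(table, ids) {
  missing <- setdiff(ids, colnames(table$values))
  if (length(missing))
    stop("features not present in table: ", paste(missing, collapse = ", "))
  new_biomarker_table(table$values[, ids, drop = FALSE], ids,
                      table$subjects, table$params)
}
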