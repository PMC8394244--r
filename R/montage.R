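#' The 19-channel 10-20 montage
#'
#' Ordered channel labels of the international 10-20 system as used
#' throughout the package (temporal channels in the older T3/T4/T5/T6
#' nomenclature). The montage has exactly 19 channels and therefore
#' `choose(19, 2) = 171` unordered channel pairs.
#'
#' @return Character vector of 19 channel labels.
#' @export
#' @examples
#' montage_1020()
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "FZ", "F4", "F8", "T3", "C3", "CZ",
    "C4", "T4", "T5", "P3", "PZ", "P4", "T6", "O1", "O2")
}

#' All unordered channel pairs of a montage
#'
#' @param channels character vector of channel labels (default full montage).
#' @return Character vector of pair labels `"A-B"` with A before B in
#'   montage order; 171 pairs for the full montage.
#' @export
montage_pairs <- function(channels = montage_1020()) {
  if (length(channels) < 2) return(character(0))
  cb <- combn(channels, 2)
  paste(cb[1, ], cb[2, ], sep = "-")
}

#' Canonical EEG frequency bands
#'
#' The five classical bands: delta 0-4, theta 4-8, alpha 8-12, beta 12-30
#' and gamma 30-45 Hz. For filtering, the delta low edge is clamped to
#' 0.5 Hz so that DC drift is not passed (see [band_filter()]).
#'
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
#' @examples
#' eeg_bands()$alpha
eeg_bands <- function() {
  list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 45))
}

band_names <- function() names(eeg_bands())

#' Band specifications: five bands plus twenty ordered ratios
#'
#' Every biomarker family is evaluated on each band and on each ordered
#' ratio of two distinct bands (theta/alpha and alpha/theta are distinct
#' features), giving 25 band specifications per family.
#'
#' @return Character vector of 25 specs, e.g. `"alpha"`, `"theta/alpha"`.
#' @export
band_specs <- function() {
  b <- band_names()
  ratios <- unlist(lapply(b, function(num)
    paste(num, setdiff(b, num), sep = "/")))
  c(b, ratios)
}

# split "theta/alpha" -> c("theta", "alpha"); single band -> the band + NA
parse_band_spec <- function(spec) {
  parts <- strsplit(spec, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1) c(parts, NA_character_) else parts
}

method_names <- function() {
  c("DPS", "DEEGA", "ZCI", "TSEN", "HFD", "APEN", "LZC", "COH")
}

single_channel_methods <- function() setdiff(method_names(), "COH")

#' Compose a feature identifier
#'
#' Feature columns are named `METHOD_bandspec_location`, with `/` in a
#' band ratio written as `-` (e.g. `"TSEN_theta-alpha_T6"`,
#' `"COH_alpha_F4-T4"`).
#'
#' @param method one of `DPS, DEEGA, ZCI, TSEN, HFD, APEN, LZC, COH`.
#' @param band_spec a band name or ordered ratio such as `"theta/alpha"`.
#' @param location a channel label, or `"A-B"` pair for coherence.
#' @return Character feature id.
#' @export
feature_id <- function(method, band_spec, location) {
  paste(toupper(method), gsub("/", "-", band_spec, fixed = TRUE),
        location, sep = "_")
}

#' Parse feature identifiers back into their components
#'
#' @param ids character vector of feature ids from [feature_id()].
#' @return Data frame with columns `method`, `band_spec`, `location`.
#' @export
parse_feature_id <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed feature id(s): ", paste(ids[bad], collapse = ", "))
  m <- vapply(parts, `[[`, "", 1L)
  bs <- vapply(parts, `[[`, "", 2L)
  loc <- vapply(parts, `[[`, "", 3L)
  # a band-spec ratio uses '-' in the id; restore '/', but only between bands
  restore <- function(s) {
    if (grepl("-", s, fixed = TRUE)) sub("-", "/", s, fixed = TRUE) else s
  }
  data.frame(method = m, band_spec = vapply(bs, restore, ""),
             location = loc, row.names = NULL)
}

# Normalise raw channel labels to the montage dialect:
# strip "EEG " prefixes and reference suffixes ("T3-A1" -> "T3"), map the
# modern T7/T8/P7/P8 names onto T3/T4/T5/T6, fix case.
normalise_channel_label <- function(label) {
  lab <- trimws(label)
  lab <- sub("^(?i)EEG[ _]*", "", lab, perl = TRUE)
  lab <- sub("[-_ ].*$", "", lab)
  dialect <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  up <- toupper(lab)
  idx <- match(up, names(dialect))
  up[!is.na(idx)] <- dialect[idx[!is.na(idx)]]
  canon <- montage_1020()
  hit <- match(up, toupper(canon))
  out <- ifelse(is.na(hit), NA_character_, canon[hit])
  out
}
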