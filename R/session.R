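#' Multichannel recording session
#'
#' The unit of I/O for the pipeline: a channels-by-samples signal matrix, its
#' sampling rate, a channel metadata table and an events table. All analysis
#' functions in ptenet consume and return this container (or the epoch set
#' derived from it).
#'
#' @param signal numeric matrix, channels x samples; row names are ignored
#'   (channel names come from `channels$name`).
#' @param fs sampling rate in Hz.
#' @param channels tibble/data.frame with columns `name`, `group` (contact
#'   group, e.g. one depth probe or strip) and `region` (anatomical label,
#'   e.g. `"AI"`, `"PCC/Pr"`, `"mPFC"`, `"dPPC"`, `"MFG"`, `"IFG"`,
#'   `"other"`).
#' @param events tibble/data.frame with columns `onset_s`, `duration_s`,
#'   `trial_type` (`"encoding"`, `"recall_vocal_onset"` or `"rest"`), `task`,
#'   `subject_id` and `recalled` (0/1/NA).
#'
#' @return An object of class `rec_session`.
#' @export
new_session <- function(signal, fs, channels, events) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric channels x samples matrix.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  channels <- as_tibble(channels)
  events <- as_tibble(events)
  need_ch <- c("name", "group", "region")
  if (!all(need_ch %in% names(channels))) {
    abort(paste0("`channels` must have columns: ", paste(need_ch, collapse = ", ")))
  }
  need_ev <- c("onset_s", "duration_s", "trial_type", "task", "subject_id", "recalled")
  missing_ev <- setdiff(need_ev, names(events))
  if (length(missing_ev)) {
    abort(paste0("`events` is missing columns: ", paste(missing_ev, collapse = ", ")))
  }
  if (nrow(channels) != nrow(signal)) {
    abort("`channels` must have one row per signal row.")
  }
  dur <- ncol(signal) / fs
  bad <- events$onset_s < 0 | events$onset_s > dur
  if (any(bad, na.rm = TRUE)) {
    abort("event onsets must lie within [0, recording duration].")
  }
  rownames(signal) <- channels$name
  structure(
    list(signal = signal, fs = fs, channels = channels, events = events),
    class = "rec_session"
  )
}

#' @export
print.rec_session <- function(x, ...) {
  cat(sprintf(
    "<rec_session> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs, nrow(x$events)
  ))
  regs <- table(x$channels$region)
  cat("  regions:", paste(sprintf("%s(%d)", names(regs), regs), collapse = " "), "\n")
  invisible(x)
}

#' Session duration in seconds
#' @param session a `rec_session`.
#' @return length of the recording in seconds.
#' @export
session_duration <- function(session) ncol(session$signal) / session$fs

#' Frequency band definition
#'
#' @param name band label.
#' @param low,high band edges in Hz; `0 <= low < high`.
#' @return A `band_spec` (named list).
#' @export
band_spec <- function(name, low, high) {
  if (!(is.numeric(low) && is.numeric(high) && low >= 0 && low < high)) {
    abort("band edges must satisfy 0 <= low < high.")
  }
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' Canonical iEEG analysis bands
#'
#' The broadband range used for directed-connectivity analysis plus the five
#' narrowband ranges used for phase-locking: delta-theta 0.5-8, alpha 8-12,
#' beta 12-30, gamma 30-80, high-gamma 80-160 Hz, broadband 0.5-80 Hz.
#'
#' @return tibble with columns `name`, `low`, `high` (Hz).
#' @export
band_presets <- function() {
  tibble(
    name = c("broadband", "delta-theta", "alpha", "beta", "gamma", "high-gamma"),
    low  = c(0.5, 0.5, 8, 12, 30, 80),
    high = c(80, 8, 12, 30, 80, 160)
  )
}

as_band <- function(band, fs) {
  if (inherits(band, "band_spec")) b <- band
  else if (is.character(band) && length(band) == 1L) {
    tb <- band_presets()
    hit <- tb[tb$name == band, ]
    if (nrow(hit) != 1L) abort(sprintf("unknown band name '%s'.", band))
    b <- band_spec(hit$name, hit$low, hit$high)
  } else if (is.numeric(band) && length(band) == 2L) {
    b <- band_spec(sprintf("%g-%g Hz", band[1], band[2]), band[1], band[2])
  } else abort("`band` must be a band_spec, a preset name, or c(low, high).")
  if (b$high >= fs / 2) {
    abort(sprintf("band high edge %g Hz is at or above Nyquist (%g Hz).", b$high, fs / 2))
  }
  b
}
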