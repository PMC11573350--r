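# Zero-phase Butterworth filtering. "order" is the one-pass design order;
# forward-backward application doubles the effective order and cancels phase.
filt_zero_phase <- function(x, flt) {
  as.numeric(signal::filtfilt(flt, x))
}

butter_band <- function(low, high, fs, order = 4L, type = "pass") {
  ny <- fs / 2
  if (high >= ny) abort(sprintf("band edge %g Hz is at or above Nyquist (%g Hz).", high, ny))
  signal::butter(order, c(low, high) / ny, type = type)
}

bandpass_vec <- function(x, low, high, fs, order = 4L) {
  filt_zero_phase(x, butter_band(low, high, fs, order))
}

resample_vec <- function(x, fs, target_fs) {
  lp <- signal::butter(8L, (0.9 * target_fs / 2) / (fs / 2), type = "low")
  xf <- filt_zero_phase(x, lp)
  n_new <- floor(length(x) * target_fs / fs)
  t_new <- (seq_len(n_new) - 1) / target_fs
  stats::spline(x = (seq_along(x) - 1) / fs, y = xf, xout = t_new)$y
}

apply_channels <- function(session, f) {
  out <- t(apply(session$signal, 1L, f))
  if (nrow(out) != nrow(session$signal)) out <- t(out)  # guard for 1-sample edge
  session$signal <- out
  rownames(session$signal) <- session$channels$name
  session
}

#' Downsample a session
#'
#' Anti-aliased resampling to `target_fs` (zero-phase 8th-order Butterworth
#' low-pass at 0.9 x the new Nyquist, then spline evaluation at the new
#' sample times). Event onsets are in seconds and are unchanged. Recordings
#' already at `target_fs` pass through untouched; upsampling is refused.
#'
#' @param session a `rec_session`.
#' @param target_fs target sampling rate, Hz (default 500).
#' @return resampled `rec_session`.
#' @export
resample_session <- function(session, target_fs = 500) {
  if (target_fs > session$fs) abort("upsampling is not supported (target_fs > fs).")
  if (target_fs == session$fs) return(session)
  fs0 <- session$fs
  new_sig <- t(apply(session$signal, 1L, resample_vec, fs = fs0, target_fs = target_fs))
  rownames(new_sig) <- session$channels$name
  session$signal <- new_sig
  session$fs <- target_fs
  session
}

#' Bipolar montage
#'
#' Re-references to the difference of adjacent contacts within each contact
#' group: a group with contacts c1..ck (in the order given by the channel
#' table) yields k-1 virtual channels c1-c2, ..., c(k-1)-ck. The virtual
#' channel is named `"A-B"` and inherits the region label of its first
#' contact. Groups with a single contact yield nothing (reported via a
#' message). Bipolar differencing cancels signal components common to both
#' contacts (shared reference, volume-conducted far fields).
#'
#' @param session a `rec_session` whose channel table has a `group` column.
#' @return a `rec_session` of virtual bipolar channels.
#' @export
bipolar_montage <- function(session) {
  ch <- session$channels
  if (!"group" %in% names(ch)) abort("channel table has no `group` column.")
  groups <- unique(ch$group)
  rows <- list(); sig_rows <- list()
  dropped <- 0L
  for (g in groups) {
    idx <- which(ch$group == g)
    if (length(idx) < 2L) { dropped <- dropped + 1L; next }
    for (j in seq_len(length(idx) - 1L)) {
      a <- idx[j]; b <- idx[j + 1L]
      rows[[length(rows) + 1L]] <- tibble(
        name = paste0(ch$name[a], "-", ch$name[b]),
        group = g, region = ch$region[a]
      )
      sig_rows[[length(sig_rows) + 1L]] <- session$signal[a, ] - session$signal[b, ]
    }
  }
  if (dropped > 0L) {
    inform(sprintf("bipolar_montage: %d single-contact group(s) produced no virtual channels.", dropped))
  }
  if (!length(rows)) abort("no contact group has >= 2 contacts; bipolar montage is empty.")
  new_ch <- bind_rows(rows)
  new_sig <- do.call(rbind, sig_rows)
  rownames(new_sig) <- new_ch$name
  session$signal <- new_sig
  session$channels <- new_ch
  session
}

#' Remove power-line noise
#'
#' Zero-phase 4th-order Butterworth band-stop filters at 57-63, 117-123 and
#' 177-183 Hz (60 Hz mains and harmonics). Stop bands at or above Nyquist
#' are skipped.
#'
#' @param session a `rec_session`.
#' @param stops list of c(low, high) stop bands in Hz.
#' @return filtered `rec_session`.
#' @export
remove_line_noise <- function(session,
                              stops = list(c(57, 63), c(117, 123), c(177, 183))) {
  ny <- session$fs / 2
  for (s in stops) {
    if (s[2] >= ny) next
    flt <- butter_band(s[1], s[2], session$fs, order = 4L, type = "stop")
    session <- apply_channels(session, function(x) filt_zero_phase(x, flt))
  }
  session
}

#' Z-normalize channels
#'
#' Removes each channel's mean and scales by its standard deviation over the
#' full recording.
#'
#' @param session a `rec_session`.
#' @return normalized `rec_session`.
#' @export
zscore_channels <- function(session) {
  sds <- apply(session$signal, 1L, sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) {
    abort(sprintf(
      "zero-variance channel(s): %s",
      paste(session$channels$name[zero], collapse = ", ")
    ))
  }
  mns <- rowMeans(session$signal)
  session$signal <- (session$signal - mns) / sds
  rownames(session$signal) <- session$channels$name
  session
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (two-way) 4th-order Butterworth band-pass: zero net phase
#' shift, effective order doubled by the two passes. Works on a whole session
#' or on an epoch set (each trial x channel filtered independently).
#'
#' @param x a `rec_session` or `epoch_set`.
#' @param band a [band_spec()], a preset name from [band_presets()], or
#'   `c(low, high)` in Hz.
#' @param order one-pass filter order (default 4).
#' @return same type as `x`, filtered.
#' @export
bandpass_filter <- function(x, band, order = 4L) UseMethod("bandpass_filter")

#' @export
bandpass_filter.rec_session <- function(x, band, order = 4L) {
  b <- as_band(band, x$fs)
  flt <- butter_band(b$low, b$high, x$fs, order)
  out <- apply_channels(x, function(v) filt_zero_phase(v, flt))
  attr(out, "band") <- b
  out
}

#' @export
bandpass_filter.epoch_set <- function(x, band, order = 4L) {
  b <- as_band(band, x$fs)
  flt <- butter_band(b$low, b$high, x$fs, order)
  d <- x$data
  for (tr in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[2])) {
      d[tr, ch, ] <- filt_zero_phase(d[tr, ch, ], flt)
    }
  }
  x$data <- d
  x$band <- b
  x
}

#' Autoregressive spectral radius (stationarity check)
#'
#' Fits an AR(p) model by ordinary least squares and returns the largest
#' modulus among the eigenvalues of the companion matrix. Values very close
#' to one indicate a (near) unit root, i.e. a nonstationary series for which
#' Granger-type parametric causality is unreliable and a phase-based measure
#' is preferred.
#'
#' @param x numeric series, length > 10 x `order`.
#' @param order AR model order (default 10).
#' @return largest companion-matrix eigenvalue modulus.
#' @export
ar_spectral_radius <- function(x, order = 10L) {
  if (!all(is.finite(x))) abort("input must be finite.")
  if (length(x) <= 10L * order) abort("series too short for the requested AR order.")
  fit <- stats::ar.ols(x, aic = FALSE, order.max = order, demean = TRUE, intercept = FALSE)
  a <- as.numeric(fit$ar)
  p <- length(a)
  if (p == 0L) return(0)
  comp <- matrix(0, p, p)
  comp[1L, ] <- a
  if (p > 1L) comp[2:p, 1:(p - 1L)] <- diag(p - 1L)
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Standard preprocessing pipeline
#'
#' Runs the conditioning stages in their canonical order: resample to 500 Hz,
#' bipolar montage, line-noise removal, per-channel z-normalization, and
#' band-pass filtering (broadband 0.5-80 Hz by default).
#'
#' @param session a `rec_session`.
#' @param target_fs resampling target, Hz.
#' @param band band for the final filter (see [bandpass_filter()]); `NULL`
#'   skips filtering.
#' @param bipolar apply the bipolar montage (default TRUE).
#' @return preprocessed `rec_session`.
#' @export
preprocess_session <- function(session, target_fs = 500, band = "broadband",
                               bipolar = TRUE) {
  s <- resample_session(session, target_fs)
  if (bipolar) s <- bipolar_montage(s)
  s <- remove_line_noise(s)
  s <- zscore_channels(s)
  if (!is.null(band)) s <- bandpass_filter(s, band)
  s
}
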