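#' High-gamma envelope of an epoch set
#'
#' Decomposes the 80-160 Hz range into eight 10 Hz sub-bands (80-90, ...,
#' 150-160 Hz), which corrects for the 1/f decay of spectral power across the
#' range. Each sub-band is band-passed (zero-phase 4th-order Butterworth),
#' its envelope taken as the modulus of the analytic signal, normalized to
#' that band's own mean envelope over the epoch interior and expressed as a
#' percentage of the mean; the across-band mean yields one amplitude series
#' per trial and channel. The first and last 50 ms of each epoch carry
#' filter/Hilbert edge transients: they are excluded from the normalizing
#' mean (and later from statistics), so that a band's normalization reflects
#' its steady-state level. Sub-bands with no appreciable signal — interior
#' median envelope below 1e-3 x the epoch RMS, i.e. at the filter's stopband
#' floor, as for band-free synthetic inputs — are excluded from the
#' across-band mean with a warning (normalizing such a band would amplify
#' pure filter transients); bands above Nyquist are skipped with a warning.
#'
#' The normalization is per epoch, so the interior across-time mean of each
#' retained band is exactly 100 before baseline correction, and the output
#' is invariant to any positive rescaling of the raw signal.
#'
#' @param epochs an `epoch_set` (unfiltered; sub-band filtering happens
#'   here). Sampling rate must exceed 180 Hz for at least one sub-band.
#' @return `hg_envelope`: trials x channels x samples array (% of own-band
#'   mean), with attributes `fs`, `window`, `edge_s` (0.05 s of each epoch
#'   edge to exclude from statistics) and the epoch metadata.
#' @export
highgamma_envelope <- function(epochs) {
  fs <- epochs$fs
  edges <- seq(80, 160, by = 10)
  lows <- edges[-length(edges)]
  highs <- edges[-1]
  usable <- highs < fs / 2
  if (!any(usable)) abort("fs/2 must exceed 90 Hz for at least one high-gamma sub-band.")
  if (!all(usable)) {
    warn(sprintf("%d high-gamma sub-band(s) above Nyquist were skipped.", sum(!usable)))
  }
  lows <- lows[usable]; highs <- highs[usable]
  filters <- map2(lows, highs, function(lo, hi) butter_band(lo, hi, fs, 4L))

  d <- epochs$data
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_s <- dim(d)[3]
  edge_s <- 0.05
  edge_n <- min(round(edge_s * fs), floor((n_s - 1) / 2))
  interior <- (edge_n + 1L):(n_s - edge_n)
  out <- array(0, dim = dim(d))
  n_excluded <- 0L
  for (tr in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      x <- d[tr, ch, ]
      rms <- sqrt(mean(x^2))
      acc <- numeric(n_s)
      n_used <- 0L
      for (f in filters) {
        env <- Mod(analytic_vec(filt_zero_phase(x, f)))
        if (median(env[interior]) < 1e-3 * max(rms, .Machine$double.eps)) {
          n_excluded <- n_excluded + 1L
          next
        }
        acc <- acc + env / mean(env[interior]) * 100
        n_used <- n_used + 1L
      }
      if (n_used == 0L) abort("all high-gamma sub-bands had zero power for a trial/channel.")
      out[tr, ch, ] <- acc / n_used
    }
  }
  if (n_excluded > 0L) {
    warn(sprintf("highgamma_envelope: %d zero-power sub-band instance(s) excluded from the across-band mean.", n_excluded))
  }
  structure(
    out,
    fs = fs, window = epochs$window, edge_s = edge_s,
    condition = epochs$condition, task = epochs$task,
    subject_id = epochs$subject_id, channels = epochs$channels,
    class = "hg_envelope"
  )
}

# window-count formula shared with the brute-force property test
n_windows <- function(n_samples, win, step) {
  if (win > n_samples) 0L else as.integer(floor((n_samples - win) / step) + 1L)
}

#' Sliding-window smoothing of an envelope
#'
#' Sliding-window means over `win_s`-second windows with fractional
#' `overlap` (step = win x (1 - overlap)). Window centers are reported in
#' epoch time (seconds relative to the event anchor). Windows overlapping
#' the envelope's excluded epoch edges are dropped.
#'
#' @param x an `hg_envelope`, or any trials x channels x samples array
#'   (supply `fs` for plain arrays).
#' @param win_s window length, s (default 0.2).
#' @param overlap fractional overlap in `[0, 1)` (default 0.9, i.e. 90%).
#' @param fs sampling rate, Hz; defaults to the `fs` attribute of `x`.
#' @return a `power_ts` tibble: `subject`, `task`, `condition`, `region`,
#'   `channel`, `trial`, `window_center_s`, `value`, with window metadata in
#'   attributes (`fs_effective` = windows per second).
#' @export
smooth_windows <- function(x, win_s = 0.2, overlap = 0.9, fs = NULL) {
  fs <- fs %||% attr(x, "fs")
  if (is.null(fs)) abort("supply `fs` (or an array carrying an fs attribute).")
  window <- attr(x, "window") %||% c(0, dim(x)[3] / fs)
  edge_s <- attr(x, "edge_s") %||% 0
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  win <- round(win_s * fs)
  if (win < 1L) abort("window shorter than one sample.")
  step <- max(1L, round(win * (1 - overlap)))
  n_s <- dim(x)[3]
  if (win > n_s) abort("epoch shorter than one smoothing window.")
  nw <- n_windows(n_s, win, step)
  starts <- (seq_len(nw) - 1L) * step                     # 0-based
  centers_s <- window[1] + (starts + (win - 1) / 2) / fs

  keep <- (starts / fs >= edge_s) & ((starts + win) / fs <= (n_s / fs - edge_s))
  if (!any(keep)) abort("no smoothing window survives edge exclusion.")

  n_tr <- dim(x)[1]; n_ch <- dim(x)[2]
  ch_tbl <- attr(x, "channels") %||%
    tibble(name = as.character(seq_len(n_ch)), region = NA_character_)
  csum_w <- function(v) {
    cs <- c(0, cumsum(v))
    (cs[starts + win + 1L] - cs[starts + 1L]) / win
  }
  rows <- vector("list", n_tr * n_ch)
  k <- 0L
  for (tr in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      vals <- csum_w(x[tr, ch, ])
      k <- k + 1L
      rows[[k]] <- tibble(
        trial = tr, channel = ch_tbl$name[ch], region = ch_tbl$region[ch],
        window_center_s = centers_s[keep], value = vals[keep]
      )
    }
  }
  res <- bind_rows(rows) |>
    mutate(
      subject = attr(x, "subject_id") %||% NA_character_,
      task = attr(x, "task") %||% NA_character_,
      condition = attr(x, "condition") %||% NA_character_
    ) |>
    select(
      "subject", "task", "condition", "region", "channel", "trial",
      "window_center_s", "value"
    )
  structure(
    res,
    fs_effective = fs / step, win_s = win_s, step_s = step / fs,
    baseline = "none",
    class = c("power_ts", class(res))
  )
}

#' Baseline-correct a power time series
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus baseline
#' windows (window centers within `[-baseline_s, 0)` relative to the event
#' anchor) from every window. For epochs with no pre-anchor signal (the
#' pre-vocal recall windows), supply a matched rest-period `power_ts` as
#' `rest`: its per-channel mean is used as the baseline instead, and the
#' result is flagged `baseline = "rest"` in the attributes.
#'
#' @param p a `power_ts` from [smooth_windows()].
#' @param baseline_s pre-stimulus baseline length, s (default 0.2).
#' @param rest optional matched rest `power_ts` used as baseline.
#' @return baseline-corrected `power_ts`.
#' @export
baseline_correct <- function(p, baseline_s = 0.2, rest = NULL) {
  if (!is.null(rest)) {
    base <- rest |>
      group_by(.data$channel) |>
      summarise(.base = mean(.data$value), .groups = "drop")
    out <- p |>
      left_join(base, by = "channel") |>
      mutate(value = .data$value - .data$.base) |>
      select(-".base")
    mode <- "rest"
  } else {
    base <- p |>
      filter(.data$window_center_s >= -baseline_s, .data$window_center_s < 0) |>
      group_by(.data$trial, .data$channel) |>
      summarise(.base = mean(.data$value), .groups = "drop")
    if (!nrow(base)) abort("no baseline windows: epochs carry no pre-anchor signal (supply `rest`).")
    out <- p |>
      left_join(base, by = c("trial", "channel")) |>
      mutate(value = .data$value - .data$.base) |>
      select(-".base")
    mode <- "prestim"
  }
  for (a in c("fs_effective", "win_s", "step_s")) attr(out, a) <- attr(p, a)
  attr(out, "baseline") <- mode
  class(out) <- class(p)
  out
}

#' Window-wise condition contrast
#'
#' Runs the mixed-effects condition contrast ([condition_contrast()]) on each
#' shared 0.2 s window of two power time series (e.g. one region vs another,
#' or task vs rest), returning per-window F, p, FDR-adjusted p and a
#' significance mask whose contiguous runs mark significant time spans.
#'
#' @param p_a,p_b `power_ts` tibbles on identical window grids. Condition A
#'   is `p_a`.
#' @param alpha FDR level (default 0.05).
#' @param normalize apply the rank-based normalizing transform within each
#'   window before fitting (default TRUE).
#' @return tibble: `window_center_s`, `f`, `df1`, `df2`, `p`, `p_fdr`,
#'   `significant`, `direction`.
#' @export
windowwise_contrast <- function(p_a, p_b, alpha = 0.05, normalize = TRUE) {
  ga <- sort(unique(p_a$window_center_s))
  gb <- sort(unique(p_b$window_center_s))
  if (length(ga) != length(gb) || max(abs(ga - gb)) > 1e-9) {
    abort("the two power series are not on the same window grid.")
  }
  res <- map(ga, function(w) {
    tab <- bind_rows(
      p_a |> filter(abs(.data$window_center_s - w) < 1e-9) |> mutate(condition = "A"),
      p_b |> filter(abs(.data$window_center_s - w) < 1e-9) |> mutate(condition = "B")
    ) |>
      group_by(.data$subject, .data$condition, .data$channel) |>
      summarise(value = mean(.data$value), .groups = "drop") |>
      rename(pair = "channel")
    ct <- condition_contrast(tab, normalize = normalize)
    tibble(
      window_center_s = w, f = ct$f, df1 = ct$df1, df2 = ct$df2,
      p = ct$p, direction = ct$direction
    )
  }) |> bind_rows()
  adj <- fdr_bh(res$p, alpha)
  res$p_fdr <- adj$p_adj
  res$significant <- adj$reject
  res
}
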