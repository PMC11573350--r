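# Seed the RNG for the calling function's scope while leaving the caller's
# RNG stream untouched afterwards.
local_rng <- function(seed, envir = parent.frame()) {
  seed <- as.integer(seed)   # force before snapshotting the caller's RNG state
  withr::local_preserve_seed(.local_envir = envir)
  set.seed(seed)
}

# --- noise primitives -------------------------------------------------------

# Gaussian 1/f^alpha noise, unit variance, via spectral shaping of white noise.
oneover_f_noise <- function(n, alpha = 1) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))                     # avoid DC blow-up
  f <- pmin(f, n - f + 1)                       # two-sided frequency index
  X <- X * f^(-alpha / 2)
  y <- Re(fft(X, inverse = TRUE)) / n
  as.numeric(scale(y))
}

# Band-limited Gaussian noise, unit variance.
bandlimited_noise <- function(n, fs, band) {
  x <- bandpass_vec(rnorm(n), band[1], band[2], fs)
  as.numeric(scale(x))
}

circ_shift <- function(x, lag) {
  n <- length(x)
  lag <- lag %% n
  if (lag == 0) return(x)
  c(x[(n - lag + 1L):n], x[1:(n - lag)])
}

# --- specs ------------------------------------------------------------------

#' Directed coupling specification
#'
#' Ground-truth directed influence between two regions in a synthetic
#' session: target-region channels receive a `lag`-sample delayed copy of a
#' band-limited driver shared with the source region, mixed with weight
#' `strength` against independent band-limited noise.
#'
#' @param source_region,target_region region labels (must differ).
#' @param strength mixing weight in `[0, 1]`; 0 = no coupling.
#' @param lag delay in samples (>= 1).
#' @param band driver band `c(low, high)` in Hz.
#' @return a `coupling_spec`.
#' @export
coupling_spec <- function(source_region, target_region, strength = 0.7,
                          lag = 25L, band = c(8, 12)) {
  if (!(strength >= 0 && strength <= 1)) abort("`strength` must be in [0, 1].")
  if (lag < 1) abort("`lag` must be >= 1 sample.")
  if (band[1] >= band[2]) abort("band low edge must be below high edge.")
  if (identical(source_region, target_region)) abort("source and target regions must differ.")
  structure(
    list(
      source_region = source_region, target_region = target_region,
      strength = strength, lag = as.integer(lag), band = band
    ),
    class = "coupling_spec"
  )
}

#' Task-locked high-gamma response specification
#'
#' Emulates event-related increases or suppressions of high-gamma (80-160 Hz)
#' amplitude in one region: within `[onset, offset]` seconds of each matching
#' event the high-gamma component of the signal is scaled by
#' `1 + magnitude` (increase) or `1 - magnitude` (suppress).
#'
#' @param region region label.
#' @param condition `"encoding"`, `"recall"` or `"rest"`.
#' @param direction `"increase"`, `"suppress"` or `"none"`.
#' @param magnitude fractional change of the high-gamma envelope (>= 0).
#' @param onset,offset response window in seconds relative to the event
#'   anchor (`onset < offset`; negative values address pre-anchor windows,
#'   e.g. the pre-vocal recall period).
#' @return a `gamma_response_spec`.
#' @export
gamma_response_spec <- function(region, condition = "encoding",
                                direction = c("suppress", "increase", "none"),
                                magnitude = 0.3, onset = 0, offset = 1.6) {
  direction <- match.arg(direction)
  if (magnitude < 0) abort("`magnitude` must be >= 0.")
  if (onset >= offset) abort("`onset` must be before `offset`.")
  structure(
    list(
      region = region, condition = condition, direction = direction,
      magnitude = magnitude, onset = onset, offset = offset
    ),
    class = "gamma_response_spec"
  )
}

#' Synthetic session configuration
#'
#' Defines one simulated multi-electrode recording: region-labelled contact
#' groups, a task-specific trial structure (word-list encoding, pre-vocal
#' recall windows, a pre-task rest span matched to the task epochs),
#' 1/f-like broadband background, directed band-limited couplings between
#' regions, and task-locked high-gamma responses.
#'
#' Contacts within a probe carry a deterministic spatial falloff of the
#' region's coupled component (gains 1, 0.5, 0.25, ...), so bipolar
#' derivations retain a defined fraction of it rather than cancelling a
#' perfectly common field.
#'
#' @param task one of `"VFR"`, `"CATVFR"`, `"PALVCR"`, `"WMSM"`.
#' @param n_trials number of encoding events (word presentations / maze
#'   items), >= 1.
#' @param fs sampling rate, Hz.
#' @param regions region labels; one contact group per region.
#' @param contacts_per_region contacts per probe group (>= 1; 2 gives one
#'   bipolar channel per region).
#' @param couplings list of [coupling_spec()].
#' @param gamma_responses list of [gamma_response_spec()].
#' @param noise_alpha exponent of the 1/f^alpha background.
#' @param noise_amp background standard deviation (a.u.).
#' @param coupling_amp standard deviation of each coupled component at unit
#'   gain (a.u.).
#' @param rest_factor factor applied to coupling strengths within the rest
#'   span (task-vs-rest contrasts assume weaker coupling at rest).
#' @param recall_p probability that an encoding item is later recalled.
#' @param subject_id subject label.
#' @param n_subjects number of subjects for [make_study()].
#' @param seed integer seed; identical config (incl. seed) reproduces the
#'   session bit for bit.
#' @return a `session_config`.
#' @export
session_config <- function(task = "VFR", n_trials = 12L, fs = 500,
                           regions = c("AI", "PCC/Pr", "mPFC", "dPPC", "MFG"),
                           contacts_per_region = 2L,
                           couplings = list(),
                           gamma_responses = list(),
                           noise_alpha = 1, noise_amp = 1,
                           coupling_amp = 2, rest_factor = 0.5,
                           recall_p = 0.4, subject_id = "S01",
                           n_subjects = 1L, seed = 1L) {
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  if (fs <= 0) abort("`fs` must be positive.")
  for (cp in couplings) {
    if (cp$band[2] * 2 >= fs) {
      abort(sprintf(
        "coupling band %g-%g Hz is not below Nyquist at fs = %g.",
        cp$band[1], cp$band[2], fs
      ))
    }
  }
  structure(
    list(
      task = task, n_trials = as.integer(n_trials), fs = fs,
      regions = regions, contacts_per_region = as.integer(contacts_per_region),
      couplings = couplings, gamma_responses = gamma_responses,
      noise_alpha = noise_alpha, noise_amp = noise_amp,
      coupling_amp = coupling_amp, rest_factor = rest_factor,
      recall_p = recall_p, subject_id = subject_id,
      n_subjects = as.integer(n_subjects), seed = as.integer(seed)
    ),
    class = "session_config"
  )
}

# --- event timeline ---------------------------------------------------------

task_isi_range <- function(task) {
  switch(task,
    VFR    = c(0.8, 1.2),
    CATVFR = c(0.75, 1.0),
    PALVCR = c(1.75, 2.0),
    WMSM   = c(0.5, 1.0),
    abort(sprintf("unknown task '%s'.", task))
  )
}

build_events <- function(config) {
  lens <- task_epoch_lengths(config$task)
  isi <- task_isi_range(config$task)
  n <- config$n_trials

  rest_onset <- 1
  rest_dur <- n * lens$encoding + 1     # >= total task epoch duration
  enc_start <- rest_onset + rest_dur + 2
  gaps <- runif(n, isi[1], isi[2])
  enc_onsets <- enc_start + cumsum(c(0, (lens$encoding + gaps)[-n]))
  enc_end <- enc_onsets[n] + lens$encoding

  recall_start <- enc_end + 5           # post-encoding delay
  rec_gaps <- runif(n, 0.4, 0.8)
  if (lens$recall_pre) {
    first <- recall_start + lens$recall + 0.5
    rec_onsets <- first + cumsum(c(0, (lens$recall + rec_gaps)[-n]))
    rec_end <- rec_onsets[n] + 0.5
  } else {
    rec_onsets <- recall_start + cumsum(c(0, (lens$recall + rec_gaps)[-n]))
    rec_end <- rec_onsets[n] + lens$recall + 0.5
  }
  recalled_enc <- stats::rbinom(n, 1, config$recall_p)

  events <- bind_rows(
    tibble(
      onset_s = rest_onset, duration_s = rest_dur, trial_type = "rest",
      task = config$task, subject_id = config$subject_id, recalled = NA_real_
    ),
    tibble(
      onset_s = enc_onsets, duration_s = lens$encoding, trial_type = "encoding",
      task = config$task, subject_id = config$subject_id,
      recalled = as.numeric(recalled_enc)
    ),
    tibble(
      onset_s = rec_onsets, duration_s = lens$recall,
      trial_type = "recall_vocal_onset",
      task = config$task, subject_id = config$subject_id, recalled = 1
    )
  )
  list(events = events, total_s = ceiling(rec_end + 2),
       rest_span = c(rest_onset, rest_onset + rest_dur))
}

# --- session synthesis ------------------------------------------------------

#' Simulate a recording session
#'
#' Generates one synthetic multichannel session: per-channel 1/f^alpha
#' background, region-shared band-limited components implementing the
#' configured directed couplings (delayed-copy mixtures, scaled by
#' `rest_factor` inside the rest span), and task-locked high-gamma responses.
#' The events table follows the task template: a pre-task rest span at least
#' as long as the summed task epochs, `n_trials` encoding events with
#' task-specific durations and inter-stimulus intervals, and `n_trials`
#' recall (vocal-onset) events.
#'
#' @param config a [session_config()].
#' @param subject subject index (used by [make_study()] to decorrelate
#'   subjects); affects the seed and the subject label.
#' @return a `rec_session`.
#' @export
make_session <- function(config, subject = 1L) {
  stopifnot(inherits(config, "session_config"))
  local_rng(config$seed + 7919L * (as.integer(subject) - 1L))
  tl <- build_events(config)
  fs <- config$fs
  n <- tl$total_s * fs

  regions <- config$regions
  k <- config$contacts_per_region
  channels <- tibble(
    name = unlist(lapply(regions, function(r) paste0(gsub("[^A-Za-z]", "", r), seq_len(k)))),
    group = rep(regions, each = k),
    region = rep(regions, each = k)
  )
  nch <- nrow(channels)
  gain <- rep(0.5^(seq_len(k) - 1), times = length(regions))   # falloff along probe

  sig <- matrix(0, nch, n)
  for (i in seq_len(nch)) {
    sig[i, ] <- config$noise_amp * oneover_f_noise(n, config$noise_alpha)
  }

  # rest-span mask for coupling attenuation
  rest_idx <- (floor(tl$rest_span[1] * fs) + 1L):floor(tl$rest_span[2] * fs)
  for (cp in config$couplings) {
    u <- bandlimited_noise(n, fs, cp$band)
    s_t <- rep(cp$strength, n)
    s_t[rest_idx] <- cp$strength * config$rest_factor
    src <- which(channels$region == cp$source_region)
    tgt <- which(channels$region == cp$target_region)
    u_lag <- circ_shift(u, cp$lag)
    for (i in src) {
      sig[i, ] <- sig[i, ] + config$coupling_amp * gain[i] * u
    }
    for (i in tgt) {
      v <- bandlimited_noise(n, fs, cp$band)
      comp <- s_t * u_lag + (1 - s_t) * v
      sig[i, ] <- sig[i, ] + config$coupling_amp * gain[i] * comp
    }
  }

  session <- new_session(sig, fs, channels, tl$events)
  for (gr in config$gamma_responses) {
    idx <- which(channels$region == gr$region)
    for (i in idx) {
      session$signal[i, ] <- add_task_locked_gamma(
        session$signal[i, ], session$events, gr, fs
      )
    }
  }
  session
}

#' Simulate a multi-subject study
#'
#' @param config a [session_config()] with `n_subjects` set.
#' @return list of `rec_session`, one per subject, with subject labels
#'   `"S01"`, `"S02"`, ...
#' @export
make_study <- function(config) {
  lapply(seq_len(config$n_subjects), function(i) {
    cfg <- config
    cfg$subject_id <- sprintf("S%02d", i)
    s <- make_session(cfg, subject = i)
    s
  })
}

#' Ground-truth coupling graph
#'
#' @param config a [session_config()].
#' @return tibble with one row per directed edge: `source`, `target`,
#'   `strength`, `lag`.
#' @export
ground_truth <- function(config) {
  if (!length(config$couplings)) {
    return(tibble(
      source = character(), target = character(),
      strength = numeric(), lag = integer()
    ))
  }
  bind_rows(lapply(config$couplings, function(cp) {
    tibble(
      source = cp$source_region, target = cp$target_region,
      strength = cp$strength, lag = cp$lag
    )
  }))
}

#' Coupled band-limited signal pair
#'
#' Minimal driver/target pair with known directed dependence: `x` is
#' band-limited Gaussian noise; `y` mixes an independent band-limited noise
#' with a `lag`-sample delayed copy of `x` at weight `strength`. White
#' measurement noise of SD `noise_sd` is added to both channels, keeping the
#' two series exchangeable in distribution at `strength = 0` (so the
#' uncoupled PTE asymmetry is sign-symmetric rather than biased by unequal
#' phase jitter).
#'
#' @param n_samples length of the pair.
#' @param fs sampling rate, Hz.
#' @param band driver band `c(low, high)`, Hz.
#' @param strength mixing weight in `[0, 1]`.
#' @param lag delay in samples (< `n_samples`).
#' @param seed integer seed.
#' @param noise_sd white measurement-noise SD added to both channels (0 for
#'   the exact identity `y(t) = x(t - lag)` at `strength = 1`).
#' @return list with numeric vectors `x` and `y`.
#' @export
coupled_phase_pair <- function(n_samples, fs = 500, band = c(8, 12),
                               strength = 0.6, lag = 25L, seed = 1L,
                               noise_sd = 0.1) {
  if (!(strength >= 0 && strength <= 1)) abort("`strength` must be in [0, 1].")
  if (lag >= n_samples) abort("`lag` must be smaller than `n_samples`.")
  local_rng(seed)
  x <- bandlimited_noise(n_samples, fs, band)
  v <- bandlimited_noise(n_samples, fs, band)
  y <- (1 - strength) * v + strength * circ_shift(x, lag)
  if (noise_sd > 0) {
    y <- y + rnorm(n_samples, sd = noise_sd)
    x <- x + rnorm(n_samples, sd = noise_sd)
  }
  list(x = x, y = y)
}

#' Impose a task-locked high-gamma response on a signal
#'
#' Extracts the 80-160 Hz component of `signal` (zero-phase Butterworth) and
#' scales its amplitude by `1 + magnitude` (increase) or `1 - magnitude`
#' (suppress) within `[onset, offset]` seconds of every event matching the
#' spec's condition; the signal is unchanged elsewhere. Events whose response
#' window would exceed the recording are skipped with a warning.
#'
#' @param signal numeric vector (one channel).
#' @param events events table (`onset_s`, `trial_type`, ...).
#' @param spec a [gamma_response_spec()].
#' @param fs sampling rate, Hz.
#' @return modified signal vector.
#' @export
add_task_locked_gamma <- function(signal, events, spec, fs) {
  if (spec$direction == "none" || spec$magnitude == 0) return(signal)
  type <- switch(spec$condition,
    encoding = "encoding", recall = "recall_vocal_onset", rest = "rest",
    abort(sprintf("unknown condition '%s'.", spec$condition))
  )
  ev <- events[events$trial_type == type, ]
  if (!nrow(ev)) return(signal)
  hg <- bandpass_vec(signal, 80, 160, fs)
  factor <- if (spec$direction == "increase") 1 + spec$magnitude else 1 - spec$magnitude
  n <- length(signal)
  skipped <- 0L
  for (on in ev$onset_s) {
    i0 <- floor((on + spec$onset) * fs) + 1L
    i1 <- floor((on + spec$offset) * fs)
    if (i0 < 1L || i1 > n) { skipped <- skipped + 1L; next }
    idx <- i0:i1
    signal[idx] <- signal[idx] + (factor - 1) * hg[idx]
  }
  if (skipped > 0L) {
    warn(sprintf("add_task_locked_gamma: %d event window(s) exceeded the recording and were skipped.", skipped))
  }
  signal
}
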