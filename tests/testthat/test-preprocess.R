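# helpers to build small sessions in code
toy_session <- function(signal, fs, regions = NULL, groups = NULL) {
  nch <- nrow(signal)
  ch <- tibble::tibble(
    name = paste0("c", seq_len(nch)),
    group = groups %||% rep("g1", nch),
    region = regions %||% rep("AI", nch)
  )
  ev <- tibble::tibble(
    onset_s = 0, duration_s = 0, trial_type = "rest",
    task = "VFR", subject_id = "S01", recalled = NA_real_
  )
  new_session(signal, fs, ch, ev)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("resampling preserves passband content and rejects aliases", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  s <- toy_session(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 400 * t)), fs)

  same <- resample_session(toy_session(rbind(sin(2 * pi * 10 * t)), 500), 500)
  expect_identical(same$fs, 500)
  expect_identical(same$signal[1, ], sin(2 * pi * 10 * t))

  r <- resample_session(s, 500)
  expect_identical(r$fs, 500)
  n <- ncol(r$signal)
  idx <- 100:(n - 100)
  ref <- sin(2 * pi * 10 * (seq_len(n) - 1) / 500)
  expect_lt(max(abs(r$signal[1, idx] - ref[idx])), 0.01)
  # 400 Hz lies above the new Nyquist: anti-alias filter must kill it
  expect_lt(sqrt(mean(r$signal[2, idx]^2)) / sqrt(mean(s$signal[2, ]^2)), 0.1)

  expect_error(resample_session(s, 2000), "upsampling")
})

test_that("bipolar montage emits adjacent differences and cancels common mode", {
  fs <- 100
  n <- 1000
  withr::local_seed(1)
  base <- matrix(rnorm(4 * n), 4, n)
  s <- toy_session(base, fs, groups = c("g1", "g1", "g1", "g2"))
  b <- bipolar_montage(s)
  expect_identical(nrow(b$signal), 2L)       # (3-1) + 0, single-contact g2 dropped
  expect_identical(b$channels$name, c("c1-c2", "c2-c3"))
  expect_identical(b$channels$region, c("AI", "AI"))
  expect_equal(b$signal[1, ], base[1, ] - base[2, ], ignore_attr = TRUE)
  expect_equal(b$signal[2, ], base[2, ] - base[3, ], ignore_attr = TRUE)

  # adding a common-mode signal to every contact changes nothing
  cm <- sin(2 * pi * 7 * (seq_len(n) - 1) / fs)
  s2 <- s; s2$signal <- s$signal + rep(cm, each = 4)
  b2 <- bipolar_montage(s2)
  expect_equal(b2$signal, b$signal, tolerance = 1e-12)

  # linearity: bipolar(a * X) = a * bipolar(X)
  s3 <- s; s3$signal <- 3.7 * s$signal
  expect_equal(bipolar_montage(s3)$signal, 3.7 * b$signal, tolerance = 1e-12)

  s4 <- s; s4$channels$group <- NULL
  expect_error(bipolar_montage(s4), "group")
})

test_that("line-noise filters notch 60 Hz and pass 10 Hz", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  s <- toy_session(rbind(sin(2 * pi * 60 * t), sin(2 * pi * 10 * t)), fs)
  out <- remove_line_noise(s)
  i <- (2 * fs):(8 * fs)   # steady-state region
  expect_lt(sqrt(mean(out$signal[1, i]^2)) / sqrt(mean(s$signal[1, i]^2)), 0.01)
  expect_equal(
    sqrt(mean(out$signal[2, i]^2)) / sqrt(mean(s$signal[2, i]^2)), 1,
    tolerance = 0.01
  )
})

test_that("z-normalization yields zero mean and unit sd per channel", {
  withr::local_seed(2)
  s <- toy_session(matrix(5 + 3 * rnorm(2000), 2, 1000), 100)
  z <- zscore_channels(s)
  expect_lt(max(abs(rowMeans(z$signal))), 1e-10)
  expect_equal(apply(z$signal, 1, sd), c(1, 1), tolerance = 1e-10, ignore_attr = TRUE)
  # idempotent
  z2 <- zscore_channels(z)
  expect_equal(z2$signal, z$signal, tolerance = 1e-10)
  s$signal[1, ] <- 2
  expect_error(zscore_channels(s), "c1")
})

test_that("band-pass filter is zero-phase with the specified band behaviour", {
  fs <- 500
  # impulse response symmetric about the impulse -> zero net phase
  imp <- numeric(1001); imp[501] <- 1
  s <- toy_session(rbind(imp), fs)
  h <- bandpass_filter(s, "broadband")$signal[1, ]
  asym <- max(abs(h[501 + 1:400] - h[501 - 1:400])) / max(abs(h))
  expect_lt(asym, 0.01)

  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  i <- (2 * fs):(8 * fs)
  pass <- bandpass_filter(toy_session(rbind(sin(2 * pi * 10 * t)), fs), "broadband")
  expect_equal(sqrt(mean(pass$signal[1, i]^2)) / sqrt(0.5), 1, tolerance = 0.02)
  stop <- bandpass_filter(toy_session(rbind(sin(2 * pi * 120 * t)), fs), "broadband")
  expect_lt(sqrt(mean(stop$signal[1, i]^2)) / sqrt(0.5), 0.05)

  expect_error(bandpass_filter(s, c(0.5, 300)), "Nyquist")
  # zero-phase property: cross-correlation with the input peaks at lag 0
  x <- sin(2 * pi * 10 * t)
  y <- bandpass_filter(toy_session(rbind(x), fs), "broadband")$signal[1, ]
  cc <- stats::ccf(x[i], y[i], lag.max = 20, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("epoching follows the window conventions and drops boundary trials", {
  fs <- 500
  n <- 40 * fs
  sig <- rbind(seq_len(n) - 1)  # channel value == 0-based sample index
  ch <- tibble::tibble(name = "c1", group = "g1", region = "AI")
  ev <- tibble::tibble(
    onset_s = c(1, 10, 25, 30, 0.5),
    duration_s = c(20, 1.6, 1.6, 1.6, 1.6),
    trial_type = c("rest", "encoding", "encoding", "recall_vocal_onset",
                   "recall_vocal_onset"),
    task = "VFR", subject_id = "S01", recalled = c(NA, 1, 0, 1, 1)
  )
  s <- new_session(sig, fs, ch, ev)

  # encoding event at 10.0 s covers samples 5000..5799 (half-open, 0-based)
  enc <- epoch_session(s, "encoding", pad_pre_s = 0.25)
  expect_identical(enc$n_dropped, 0L)
  expect_identical(dim(enc$data), c(2L, 1L, 925L))
  expect_identical(enc$data[1, 1, 0.25 * fs + 1], 5000)
  expect_identical(enc$data[1, 1, 925], 5799)

  # recall epoch is the 1.6 s preceding the vocal onset: [28.4, 30.0) s;
  # the vocal onset at 0.5 s has no full pre-window and is dropped
  expect_warning(rec <- epoch_session(s, "recall"), "dropped")
  expect_identical(rec$n_dropped, 1L)
  expect_identical(dim(rec$data)[3], 800L)
  expect_identical(rec$data[1, 1, 1], 14200)
  expect_identical(rec$data[1, 1, 800], 14999)

  # rest epochs are matched in count and length to the encoding epochs
  rest <- epoch_session(s, "rest", match_to = "encoding")
  expect_identical(dim(rest$data)[1], 2L)   # 2 encoding events in the table
  expect_identical(dim(rest$data)[3], 800L)

  expect_error(epoch_session(s, "encoding", task = "WMSM"), "no encoding")
})

test_that("epoch counts are conserved: produced + dropped = matching events", {
  s <- make_session(session_config(n_trials = 6, seed = 12))
  ep <- epoch_session(s, "encoding")
  expect_identical(dim(ep$data)[1] + ep$n_dropped, 6L)
})

test_that("AR spectral radius recovers known dynamics", {
  withr::local_seed(4)
  n <- 1e4
  ar1 <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  expect_equal(ar_spectral_radius(ar1, 1), 0.9, tolerance = 0.02)
  wn <- rnorm(n)
  expect_lt(ar_spectral_radius(wn, 1), 0.2)
  rw <- cumsum(rnorm(n))
  expect_equal(ar_spectral_radius(rw, 1), 1, tolerance = 0.01)
  expect_error(ar_spectral_radius(c(rw[1:100], NA), 1), "finite")
  expect_error(ar_spectral_radius(rnorm(50), 10), "short")
})
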