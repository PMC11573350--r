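test_that("instantaneous phase and amplitude match analytic expectations", {
  fs <- 500
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  a <- instantaneous_phase(cos(2 * pi * 10 * t))
  i <- 100:900
  expect_equal(mean(a$amplitude[i]), 1, tolerance = 0.01)
  slope <- mean(diff(signal::unwrap(a$phase[i]))) * fs / (2 * pi)
  expect_equal(slope, 10, tolerance = 0.1)

  a3 <- instantaneous_phase(3 * cos(2 * pi * 10 * t))
  expect_equal(mean(a3$amplitude[i]), 3, tolerance = 0.03)

  # linear chirp 5 -> 15 Hz over 2 s: instantaneous frequency tracks the sweep
  f0 <- 5; k <- 5   # f(t) = 5 + 5 t
  chirp <- cos(2 * pi * (f0 * t + k * t^2 / 2))
  ac <- instantaneous_phase(chirp)
  inst_f <- diff(signal::unwrap(ac$phase)) * fs / (2 * pi)
  truth <- f0 + k * t[-length(t)]
  expect_lt(max(abs(inst_f[i] - truth[i])), 0.5)

  expect_error(instantaneous_phase(rep(1, 100)), "constant")
  expect_error(instantaneous_phase(c(1, 2, NA, 4)), "finite")
})

test_that("default delay reproduces brute-force sign-change counting", {
  fs <- 500
  m <- 1000
  t <- (seq_len(m) - 1) / fs
  phi <- instantaneous_phase(cos(2 * pi * 10 * t))$phase
  # ~2 sign changes per cycle per channel: one zero-crossing, one pi wrap
  mpm <- sign_changes_bruteforce(phi) * 2
  expect_equal(mpm, 80, tolerance = 2)
  expect_identical(default_delay(phi, phi), as.integer(round(2 * m / mpm)))
  expect_identical(default_delay(phi, phi), 25L)

  # iid uniform phases flip sign w.p. 1/2 per channel per step -> tau ~ 2
  withr::local_seed(5)
  u1 <- runif(1e4, -pi, pi); u2 <- runif(1e4, -pi, pi)
  expect_lte(abs(default_delay(u1, u2) - 2), 1)

  expect_warning(tau <- default_delay(rep(0.5, 100), rep(1.2, 100)), "sign")
  expect_identical(tau, 1L)
})

test_that("default bin count follows the Scott bin-width interpretation", {
  withr::local_seed(6)
  u <- runif(1000, -pi, pi)
  # arithmetic oracle: h = 3.49 * STD * M^(-1/3), bins = ceil(2 pi / h)
  std <- mean(c(sd(u), sd(u)))
  h <- 3.49 * std * 1000^(-1 / 3)
  expect_identical(default_bins(u, u), as.integer(ceiling(2 * pi / h)))
  expect_identical(default_bins(u, u), 10L)
  # the as-printed reading is degenerate and clamps to the 2-bin floor
  expect_identical(default_bins(u, u, mode = "as_printed"), 2L)
  # quadrupling M shrinks the width by 4^(1/3), growing the bin count
  u4 <- runif(4000, -pi, pi)
  expect_equal(
    default_bins(u4, u4) / default_bins(u, u), 4^(1 / 3),
    tolerance = 0.15
  )
  expect_error(default_bins(rep(1, 10), rep(1, 10)), "variance")
})

test_that("histogram PTE equals the brute-force triple-loop estimator", {
  withr::local_seed(7)
  for (rep in 1:10) {
    m <- sample(50:200, 1)
    nb <- sample(2:8, 1)
    tau <- sample(1:5, 1)
    px <- runif(m, -pi, pi)
    py <- runif(m, -pi, pi)
    expect_equal(pte(px, py, tau, nb), pte_bruteforce(px, py, tau, nb),
                 tolerance = 1e-12)
  }
})

test_that("PTE is non-negative and detects a noiseless directed copy", {
  withr::local_seed(8)
  # non-negativity over random instances
  vals <- replicate(50, {
    m <- sample(100:400, 1)
    pte(runif(m, -pi, pi), runif(m, -pi, pi),
        tau = sample(1:10, 1), n_bins = sample(2:8, 1))
  })
  expect_true(all(vals >= -1e-12))

  # y a delayed copy of x with matching tau: forward PTE dominates
  hits <- sum(replicate(40, {
    p <- coupled_phase_pair(1500, strength = 1, lag = 10,
                            seed = sample.int(1e6, 1), noise_sd = 0)
    phx <- instantaneous_phase(p$x)$phase
    phy <- instantaneous_phase(p$y)$phase
    pte(phx, phy, tau = 10, n_bins = 8) > pte(phy, phx, tau = 10, n_bins = 8)
  }))
  expect_gte(hits, 38)

  expect_error(pte(runif(10), runif(10), tau = 10), "smaller")
})

test_that("shuffling both phase series leaves the PTE asymmetry sign-symmetric", {
  withr::local_seed(9)
  diffs <- replicate(200, {
    p <- coupled_phase_pair(800, strength = 0.8, lag = 10, seed = sample.int(1e6, 1))
    phx <- sample(instantaneous_phase(p$x)$phase)
    phy <- sample(instantaneous_phase(p$y)$phase)
    pte(phx, phy, 5, 6) - pte(phy, phx, 5, 6)
  })
  bt <- stats::binom.test(sum(diffs > 0), length(diffs), 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("PLV obeys its closed-form identities and invariances", {
  withr::local_seed(10)
  phi <- runif(1000, -pi, pi)
  expect_equal(plv(phi, phi), 1, tolerance = 1e-12)
  expect_equal(plv(phi, phi + 1.3), 1, tolerance = 1e-12)
  # common rotation of both series leaves PLV unchanged
  psi <- runif(1000, -pi, pi)
  expect_equal(plv(phi, psi), plv(phi + 0.7, psi + 0.7), tolerance = 1e-12)
  v <- replicate(50, plv(runif(500, -pi, pi), runif(500, -pi, pi)))
  expect_true(all(v >= 0 & v <= 1))
  expect_error(plv(numeric(0), numeric(0)), "non-empty")
})

test_that("epoch-level PTE: empty pairs, trial duplication invariance", {
  s <- make_session(session_config(
    n_trials = 3, seed = 21,
    couplings = list(coupling_spec("AI", "PCC/Pr", 0.8, 25))
  ))
  pre <- preprocess_session(s)
  ep <- epoch_session(pre, "encoding")

  empty <- pte_epochs(ep, tibble::tibble(chan_a = character(), chan_b = character()))
  expect_identical(nrow(empty), 0L)

  pairs <- region_pairs(ep, "AI", "PCC/Pr")
  r1 <- pte_epochs(ep, pairs)
  expect_true(all(c("AI", "PCC/Pr") %in% r1$source_region))
  expect_true(all(r1$pte_mean >= 0))

  # duplicating every trial leaves the trial means unchanged
  ep2 <- ep
  ep2$data <- ep$data[rep(1:3, 2), , , drop = FALSE]
  ep2$trials <- dplyr::bind_rows(ep$trials, ep$trials)
  r2 <- pte_epochs(ep2, pairs)
  expect_equal(r2$pte_mean, r1$pte_mean, tolerance = 1e-12)
  expect_identical(r2$n_trials, 2L * r1$n_trials)
})

test_that("net outflow matches its definition and conserves under sums", {
  res <- tibble::tibble(
    source_region = c("A", "B"), target_region = c("B", "A"),
    pte_mean = c(0.6, 0.4)
  )
  no <- net_outflow(res)
  expect_equal(no$net[no$node == "A"], 0.2, tolerance = 1e-12)
  expect_equal(no$net[no$node == "B"], -0.2, tolerance = 1e-12)

  # closed random system: sum aggregation is exactly conservative
  withr::local_seed(11)
  nodes <- c("A", "B", "C", "D")
  g <- expand.grid(source_region = nodes, target_region = nodes,
                   stringsAsFactors = FALSE)
  g <- g[g$source_region != g$target_region, ]
  g$pte_mean <- runif(nrow(g))
  ns <- net_outflow(tibble::as_tibble(g), aggregate = "sum")
  expect_lt(abs(sum(ns$net)), 1e-12)

  expect_warning(net_outflow(res, nodes = c("A", "B", "Z")), "no pairs")
})
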