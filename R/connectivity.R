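# Analytic signal via the FFT half-spectrum construction: zero out negative
# frequencies, double positive ones, keep DC (and Nyquist for even n).
analytic_vec <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous amplitude and phase
#'
#' Computes the analytic signal z(t) = x(t) + i x~(t), where x~ is the
#' Hilbert transform of x, and returns the instantaneous amplitude |z(t)|
#' and wrapped phase arg z(t) in `[-pi, pi)`. The first and last few samples
#' carry edge distortion; treat the epoch interior as reliable.
#'
#' @param x finite numeric vector, length >= 4.
#' @return an `analytic_signal`: list with `amplitude` and `phase`.
#' @export
instantaneous_phase <- function(x) {
  if (length(x) < 4L) abort("signal must have length >= 4.")
  if (!all(is.finite(x))) abort("signal must be finite.")
  if (sd(x) == 0) abort("constant signal: phase is undefined.")
  z <- analytic_vec(x)
  ph <- Arg(z)
  ph[ph >= pi] <- ph[ph >= pi] - 2 * pi
  structure(list(amplitude = Mod(z), phase = ph), class = "analytic_signal")
}

#' Data-driven PTE delay
#'
#' The analysis delay tau is set to `round(2 * M / Mpm)` where M is the
#' series length and Mpm counts sign changes of the instantaneous phase
#' between consecutive samples, summed over the two channels of the pair
#' (each oscillatory cycle contributes two sign changes per channel: one
#' zero-crossing and one +-pi wrap). Degenerate inputs with no sign change
#' fall back to tau = 1 with a warning.
#'
#' @param phi_x,phi_y phase series of equal length (radians).
#' @return integer delay in samples, >= 1.
#' @export
default_delay <- function(phi_x, phi_y) {
  if (length(phi_x) != length(phi_y)) abort("phase series must have equal length.")
  m <- length(phi_x)
  count_changes <- function(p) {
    s <- p >= 0
    sum(s[-1] != s[-length(s)])
  }
  mpm <- count_changes(phi_x) + count_changes(phi_y)
  if (mpm == 0L) {
    warn("no phase sign changes; falling back to tau = 1.")
    return(1L)
  }
  max(1L, as.integer(round(2 * m / mpm)))
}

#' Data-driven PTE histogram bin count
#'
#' Based on the Scott bin-width rule h = 3.49 * STD * M^(-1/3), with STD the
#' mean of the two phase-series standard deviations: the default `"scott"`
#' mode treats the expression as a bin width on the `[-pi, pi)` circle and
#' returns `ceiling(2*pi / h)` bins; the `"as_printed"` mode returns the
#' expression itself rounded to a bin count (degenerate for realistic M,
#' where it clamps to the 2-bin floor).
#'
#' @param phi_x,phi_y phase series of equal length.
#' @param mode `"scott"` (default) or `"as_printed"`.
#' @return integer bin count, >= 2.
#' @export
default_bins <- function(phi_x, phi_y, mode = c("scott", "as_printed")) {
  mode <- match.arg(mode)
  if (length(phi_x) != length(phi_y)) abort("phase series must have equal length.")
  m <- length(phi_x)
  if (m < 2L) abort("phase series must have length >= 2.")
  std <- mean(c(sd(phi_x), sd(phi_y)))
  if (std == 0) abort("zero-variance phase series.")
  expr <- 3.49 * std * m^(-1 / 3)
  if (mode == "scott") {
    max(2L, as.integer(ceiling(2 * pi / expr)))
  } else {
    max(2L, as.integer(round(expr)))
  }
}

# Map phases in [-pi, pi) to bin indices 1..n_bins (equal-width bins on the
# circle; the pi edge folds into the last bin).
phase_bins <- function(phi, n_bins) {
  idx <- floor((phi + pi) / (2 * pi / n_bins)) + 1L
  pmin(pmax(idx, 1L), n_bins)
}

#' Phase transfer entropy
#'
#' Directed information flow from driver phase `phi_x` to target phase
#' `phi_y`: the plug-in conditional mutual information
#' I(phi_y(t + tau); phi_x(t) | phi_y(t)), estimated from a joint histogram
#' of the triplet (phi_y(t+tau), phi_y(t), phi_x(t)) over the M - tau valid
#' samples, with `n_bins` equal-width bins per axis spanning `[-pi, pi)`.
#' All conditionals are derived from the same joint table, so the estimate
#' is non-negative up to floating-point tolerance; empty cells contribute
#' zero. Reported in nats.
#'
#' @param phi_x driver phase series (radians).
#' @param phi_y target phase series, same length.
#' @param tau delay in samples (`>= 1`, `< M`); default via [default_delay()].
#' @param n_bins histogram bins per axis; default via [default_bins()].
#' @return PTE in nats (non-negative scalar).
#' @export
pte <- function(phi_x, phi_y, tau = NULL, n_bins = NULL) {
  if (length(phi_x) != length(phi_y)) abort("phase series must have equal length.")
  m <- length(phi_x)
  tau <- tau %||% default_delay(phi_x, phi_y)
  n_bins <- n_bins %||% default_bins(phi_x, phi_y)
  tau <- as.integer(tau); n_bins <- as.integer(n_bins)
  if (tau < 1L) abort("`tau` must be >= 1.")
  if (tau >= m) abort("`tau` must be smaller than the series length.")

  yf <- phase_bins(phi_y[(1L + tau):m], n_bins)
  yp <- phase_bins(phi_y[1L:(m - tau)], n_bins)
  xp <- phase_bins(phi_x[1L:(m - tau)], n_bins)
  nv <- m - tau

  # joint counts over the (yf, yp, xp) cube and its marginals
  code <- (yf - 1L) * n_bins * n_bins + (yp - 1L) * n_bins + xp
  c_fpx <- tabulate(code, nbins = n_bins^3)
  cube <- array(c_fpx, dim = c(n_bins, n_bins, n_bins))  # [xp, yp, yf] order
  # note: tabulate code maps xp fastest -> dim order (xp, yp, yf)
  c_px  <- apply(cube, c(1, 2), sum)                     # (xp, yp)
  c_fp  <- apply(cube, c(2, 3), sum)                     # (yp, yf)
  c_p   <- apply(cube, 2, sum)                           # (yp)

  nz <- which(cube > 0, arr.ind = TRUE)
  p_joint <- cube[nz] / nv
  terms <- p_joint * log(
    (cube[nz] / c_px[nz[, c(1, 2), drop = FALSE]]) /
      (c_fp[nz[, c(2, 3), drop = FALSE]] / c_p[nz[, 2]])
  )
  sum(terms)
}

#' Phase-locking value
#'
#' Modulus of the time-averaged unit phasor of the phase difference:
#' `|mean(exp(i * (phi_x - phi_y)))|`, in `[0, 1]`. 1 indicates perfect
#' (possibly lagged by a constant phase) locking, values near 0 indicate
#' independent phases.
#'
#' @param phi_x,phi_y phase series of equal, positive length.
#' @return PLV scalar in `[0, 1]`.
#' @export
plv <- function(phi_x, phi_y) {
  if (length(phi_x) != length(phi_y)) abort("phase series must have equal length.")
  if (!length(phi_x)) abort("phase series must be non-empty.")
  Mod(mean(exp(1i * (phi_x - phi_y))))
}

# --- epoch-level drivers ----------------------------------------------------

#' Channel pairs between two region sets
#'
#' Convenience builder of the undirected channel pairs linking `from` regions
#' to `to` regions in an epoch set or session. Pairs are deduplicated (each
#' unordered pair appears once, even when the region sets overlap);
#' [pte_epochs()] computes both directions of every pair.
#'
#' @param x an `epoch_set` or `rec_session`.
#' @param from,to character vectors of region labels.
#' @return tibble with columns `chan_a`, `chan_b`.
#' @export
region_pairs <- function(x, from, to) {
  ch <- x$channels
  a <- ch$name[ch$region %in% from]
  b <- ch$name[ch$region %in% to]
  out <- tidyr::expand_grid(chan_a = a, chan_b = b) |>
    filter(.data$chan_a != .data$chan_b) |>
    mutate(
      .lo = pmin(.data$chan_a, .data$chan_b),
      .hi = pmax(.data$chan_a, .data$chan_b)
    ) |>
    dplyr::distinct(.data$.lo, .data$.hi, .keep_all = TRUE) |>
    select("chan_a", "chan_b")
  out
}

#' Per-trial PTE over an epoch set
#'
#' For every trial and every channel pair, extracts instantaneous phases,
#' derives the delay and bin count from that trial's phases via
#' [default_delay()] / [default_bins()], and computes PTE in both directions.
#' Trials shorter than `4 * tau` are skipped with a warning. Epochs are
#' expected to be band-filtered already (broadband 0.5-80 Hz in the standard
#' pipeline).
#'
#' @param epochs an `epoch_set`.
#' @param pairs tibble of undirected channel pairs (`chan_a`, `chan_b`),
#'   e.g. from [region_pairs()]; both directions are computed for each row.
#' @return a `pte_result` tibble: one row per ordered pair with columns
#'   `subject`, `task`, `condition`, `source_channel`, `target_channel`,
#'   `source_region`, `target_region`, `n_trials`, `pte_mean`, `tau_median`,
#'   `bins_median`; per-trial values in `attr(, "trials")` (also via
#'   [tidy()]).
#' @export
pte_epochs <- function(epochs, pairs) {
  pairs <- as_tibble(pairs)
  empty <- tibble(
    subject = character(), task = character(), condition = character(),
    source_channel = character(), target_channel = character(),
    source_region = character(), target_region = character(),
    n_trials = integer(), pte_mean = numeric(),
    tau_median = numeric(), bins_median = numeric()
  )
  if (!nrow(pairs)) {
    return(structure(empty, trials = empty, class = c("pte_result", class(empty))))
  }
  ch_names <- epochs$channels$name
  region_of <- setNames(epochs$channels$region, ch_names)
  miss <- setdiff(unique(c(pairs$chan_a, pairs$chan_b)), ch_names)
  if (length(miss)) abort(paste0("unknown channels: ", paste(miss, collapse = ", ")))

  n_tr <- dim(epochs$data)[1]
  m <- dim(epochs$data)[3]
  used <- unique(c(pairs$chan_a, pairs$chan_b))
  rows <- vector("list", n_tr * nrow(pairs) * 2L)
  r <- 0L
  n_skipped <- 0L
  for (tr in seq_len(n_tr)) {
    phases <- lapply(setNames(used, used), function(cn) {
      instantaneous_phase(epochs$data[tr, match(cn, ch_names), ])$phase
    })
    for (p in seq_len(nrow(pairs))) {
      pa <- pairs$chan_a[p]; pb <- pairs$chan_b[p]
      phx <- phases[[pa]]; phy <- phases[[pb]]
      tau <- default_delay(phx, phy)
      if (m < 4L * tau) { n_skipped <- n_skipped + 1L; next }
      nb <- default_bins(phx, phy)
      for (dir in 1:2) {
        src <- if (dir == 1L) pa else pb
        tgt <- if (dir == 1L) pb else pa
        val <- if (dir == 1L) pte(phx, phy, tau, nb) else pte(phy, phx, tau, nb)
        r <- r + 1L
        rows[[r]] <- tibble(
          trial = tr, source_channel = src, target_channel = tgt,
          pte = val, tau = tau, bins = nb
        )
      }
    }
  }
  if (n_skipped > 0L) {
    warn(sprintf("pte_epochs: %d trial x pair combination(s) skipped (trial shorter than 4 * tau).", n_skipped))
  }
  if (r == 0L) abort("no trial x pair combination was long enough for PTE.")
  trials <- bind_rows(rows[seq_len(r)]) |>
    mutate(
      subject = epochs$subject_id, task = epochs$task,
      condition = epochs$condition,
      source_region = unname(region_of[.data$source_channel]),
      target_region = unname(region_of[.data$target_channel])
    )
  res <- trials |>
    group_by(
      .data$subject, .data$task, .data$condition,
      .data$source_channel, .data$target_channel,
      .data$source_region, .data$target_region
    ) |>
    summarise(
      n_trials = dplyr::n(), pte_mean = mean(.data$pte),
      tau_median = median(.data$tau), bins_median = median(.data$bins),
      .groups = "drop"
    )
  structure(res, trials = trials, class = c("pte_result", class(res)))
}

#' Per-trial PLV over an epoch set
#'
#' Phase-locking value per trial and channel pair, averaged across trials.
#' Apply to narrowband-filtered epochs (one call per band).
#'
#' @inheritParams pte_epochs
#' @return tibble: one row per unordered pair with `plv_mean`, `n_trials`,
#'   plus per-trial values in `attr(, "trials")`.
#' @export
plv_epochs <- function(epochs, pairs) {
  pairs <- as_tibble(pairs)
  if (!nrow(pairs)) return(tibble(chan_a = character(), chan_b = character(), plv_mean = numeric()))
  ch_names <- epochs$channels$name
  region_of <- setNames(epochs$channels$region, ch_names)
  n_tr <- dim(epochs$data)[1]
  rows <- list()
  for (tr in seq_len(n_tr)) {
    used <- unique(c(pairs$chan_a, pairs$chan_b))
    phases <- lapply(setNames(used, used), function(cn) {
      instantaneous_phase(epochs$data[tr, match(cn, ch_names), ])$phase
    })
    for (p in seq_len(nrow(pairs))) {
      rows[[length(rows) + 1L]] <- tibble(
        trial = tr, chan_a = pairs$chan_a[p], chan_b = pairs$chan_b[p],
        plv = plv(phases[[pairs$chan_a[p]]], phases[[pairs$chan_b[p]]])
      )
    }
  }
  trials <- bind_rows(rows) |>
    mutate(
      subject = epochs$subject_id, task = epochs$task,
      condition = epochs$condition,
      region_a = unname(region_of[.data$chan_a]),
      region_b = unname(region_of[.data$chan_b]),
      band = if (!is.null(epochs$band)) epochs$band$name else NA_character_
    )
  res <- trials |>
    group_by(
      .data$subject, .data$task, .data$condition, .data$band,
      .data$chan_a, .data$chan_b, .data$region_a, .data$region_b
    ) |>
    summarise(n_trials = dplyr::n(), plv_mean = mean(.data$plv), .groups = "drop")
  structure(res, trials = trials, class = c("plv_result", class(res)))
}

#' Net information outflow per node
#'
#' For each node (region by default, or channel), aggregates the PTE of its
#' outgoing pairs and of its incoming pairs and reports
#' `net = outflow - inflow`. The default aggregation is the mean over pairs,
#' so nodes with many electrodes are not inflated by degree; `"sum"`
#' aggregation is exactly antisymmetric over a closed node set
#' (`sum(net) == 0`).
#'
#' @param result a `pte_result` from [pte_epochs()] (or any tibble with
#'   `source_region`/`target_region` (or channel) columns and `pte_mean`).
#' @param nodes node labels to include; default all regions present. Nodes
#'   with no pairs are excluded with a warning.
#' @param level `"region"` or `"channel"`.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return a `net_outflow` tibble: `node`, `outflow`, `inflow`, `net`,
#'   sorted by decreasing `net`.
#' @export
net_outflow <- function(result, nodes = NULL,
                        level = c("region", "channel"),
                        aggregate = c("mean", "sum")) {
  level <- match.arg(level)
  aggregate <- match.arg(aggregate)
  src_col <- if (level == "region") "source_region" else "source_channel"
  tgt_col <- if (level == "region") "target_region" else "target_channel"
  agg <- if (aggregate == "mean") mean else sum
  nodes <- nodes %||% sort(unique(c(result[[src_col]], result[[tgt_col]])))
  rows <- list()
  for (nd in nodes) {
    out_v <- result$pte_mean[result[[src_col]] == nd & result[[tgt_col]] %in% nodes]
    in_v <- result$pte_mean[result[[tgt_col]] == nd & result[[src_col]] %in% nodes]
    if (!length(out_v) && !length(in_v)) {
      warn(sprintf("node '%s' has no pairs and was excluded.", nd))
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      node = nd,
      outflow = if (length(out_v)) agg(out_v) else 0,
      inflow = if (length(in_v)) agg(in_v) else 0
    )
  }
  res <- bind_rows(rows) |>
    mutate(net = .data$outflow - .data$inflow) |>
    arrange(dplyr::desc(.data$net))
  structure(res, class = c("net_outflow", class(res)))
}
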