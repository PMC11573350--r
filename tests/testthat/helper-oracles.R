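# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# Plug-in conditional mutual information I(yf; xp | yp) by exhaustive
# triple loop over all histogram cells.
pte_bruteforce <- function(phi_x, phi_y, tau, n_bins) {
  m <- length(phi_x)
  binify <- function(p) {
    i <- floor((p + pi) / (2 * pi / n_bins)) + 1
    pmin(pmax(i, 1), n_bins)
  }
  yf <- binify(phi_y[(1 + tau):m])
  yp <- binify(phi_y[1:(m - tau)])
  xp <- binify(phi_x[1:(m - tau)])
  nv <- m - tau
  total <- 0
  for (a in 1:n_bins) {        # yf
    for (b in 1:n_bins) {      # yp
      n_b <- sum(yp == b)
      n_ab <- sum(yf == a & yp == b)
      for (c in 1:n_bins) {    # xp
        n_abc <- sum(yf == a & yp == b & xp == c)
        if (n_abc == 0) next
        n_bc <- sum(yp == b & xp == c)
        p_abc <- n_abc / nv
        total <- total + p_abc * log((n_abc / n_bc) / (n_ab / n_b))
      }
    }
  }
  total
}

# Sliding-window count by explicit enumeration.
count_windows_bruteforce <- function(n, win, step) {
  k <- 0L
  start <- 1
  while (start + win - 1 <= n) {
    k <- k + 1L
    start <- start + step
  }
  k
}

# Benjamini-Hochberg step-up rejections by direct definition.
bh_reject_bruteforce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Sign changes of a series between consecutive samples (treating 0 as +).
sign_changes_bruteforce <- function(p) {
  n <- 0
  for (i in 2:length(p)) {
    if ((p[i] >= 0) != (p[i - 1] >= 0)) n <- n + 1
  }
  n
}

# Small synthetic observation table: `n_sub` subjects x `n_pair` pairs,
# paired two-condition design with subject intercepts; `shift` is the true
# standardized condition effect.
sim_obs_table <- function(n_sub, n_pair, shift = 0, subject_sd = 0.5) {
  g <- expand.grid(
    subject = sprintf("S%02d", seq_len(n_sub)),
    pair = sprintf("p%02d", seq_len(n_pair)),
    condition = c("A", "B"),
    stringsAsFactors = FALSE
  )
  u <- stats::rnorm(n_sub, sd = subject_sd)
  names(u) <- sprintf("S%02d", seq_len(n_sub))
  g$value <- u[g$subject] + ifelse(g$condition == "B", shift, 0) +
    stats::rnorm(nrow(g))
  tibble::as_tibble(g)
}
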