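# Per-task epoch conventions: encoding window length and recall convention.
# Verbal tasks analyse the 1.6 s preceding each vocal onset at recall; the
# spatial water-maze task uses 5 s epochs anchored at the event onset.
task_epoch_lengths <- function(task) {
  switch(task,
    VFR    = list(encoding = 1.6, recall = 1.6, recall_pre = TRUE),
    CATVFR = list(encoding = 1.6, recall = 1.6, recall_pre = TRUE),
    PALVCR = list(encoding = 4.0, recall = 1.6, recall_pre = TRUE),
    WMSM   = list(encoding = 5.0, recall = 5.0, recall_pre = FALSE),
    abort(sprintf("unknown task '%s'.", task))
  )
}

new_epoch_set <- function(data, fs, window, condition, task, subject_id,
                          channels, trials, n_dropped = 0L) {
  structure(
    list(
      data = data, fs = fs, window = window, condition = condition,
      task = task, subject_id = subject_id, channels = channels,
      trials = trials, n_dropped = n_dropped
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %s/%s: %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
    x$task, x$condition, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    x$fs, x$window[1] + 0, x$window[2] + 0
  ))
  invisible(x)
}

#' Cut trial epochs from a session
#'
#' Cuts trials x channels x samples epochs around the events of one
#' condition, using half-open sample windows `[start, end)` with the onset
#' sample at `floor(onset_s * fs)`.
#'
#' * `encoding`: `[onset, onset + L)` where `L` is the task's encoding epoch
#'   length (1.6 s verbal free recall, 4 s paired associates, 5 s water maze).
#' * `recall`: the 1.6 s preceding each vocal onset (`[onset - 1.6, onset)`)
#'   for verbal tasks; `[onset, onset + 5)` for the water-maze task.
#' * `rest`: non-overlapping consecutive windows cut from the pre-task rest
#'   span, matched in length and count to the epochs of `match_to`; if the
#'   span is too short, fewer windows are returned with a warning.
#'
#' Trials that would extend outside the recording are dropped with a warning;
#' `n_dropped` on the result reports the count.
#'
#' @param session a `rec_session`.
#' @param condition `"encoding"`, `"recall"` or `"rest"`.
#' @param task task code; default taken from the events table.
#' @param pad_pre_s extra pre-anchor signal to include in each epoch, in
#'   seconds (used to carry a pre-stimulus baseline for power analysis).
#' @param match_to for `condition = "rest"`, which task condition to match in
#'   epoch length and count.
#' @return an `epoch_set`.
#' @export
epoch_session <- function(session, condition = c("encoding", "recall", "rest"),
                          task = NULL, pad_pre_s = 0, match_to = "encoding") {
  condition <- match.arg(condition)
  ev <- session$events
  task <- task %||% ev$task[ev$trial_type != "rest"][1]
  lens <- task_epoch_lengths(task)
  fs <- session$fs
  n_total <- ncol(session$signal)

  if (condition == "rest") {
    rest_ev <- ev[ev$trial_type == "rest", ]
    if (!nrow(rest_ev)) abort("no rest span in events table.")
    m_type <- if (match_to == "recall") "recall_vocal_onset" else "encoding"
    n_match <- sum(ev$trial_type == m_type & ev$task == task)
    if (!n_match) abort(sprintf("no %s events to match rest epochs to.", match_to))
    len_s <- lens[[match_to]] + pad_pre_s
    span0 <- rest_ev$onset_s[1]
    span1 <- span0 + rest_ev$duration_s[1]
    n_fit <- floor((span1 - span0) / len_s)
    n_use <- min(n_match, n_fit)
    if (n_use < n_match) {
      warn(sprintf(
        "rest span fits only %d of %d matched epochs; returning %d.",
        n_fit, n_match, n_use
      ))
    }
    if (n_use < 1L) abort("rest span shorter than one matched epoch.")
    anchors <- span0 + pad_pre_s + (seq_len(n_use) - 1L) * len_s
    window <- c(-pad_pre_s, lens[[match_to]])
    recalled <- rep(NA_real_, n_use)
  } else {
    type <- if (condition == "encoding") "encoding" else "recall_vocal_onset"
    sel <- ev[ev$trial_type == type & ev$task == task, ]
    if (!nrow(sel)) abort(sprintf("no %s events for task %s.", condition, task))
    if (condition == "recall" && lens$recall_pre) {
      window <- c(-lens$recall - pad_pre_s, 0)
    } else {
      window <- c(-pad_pre_s, lens[[condition]])
    }
    anchors <- sel$onset_s
    recalled <- as.numeric(sel$recalled)
  }

  n_samp <- round((window[2] - window[1]) * fs)
  start_samp <- floor(anchors * fs) + round(window[1] * fs)   # 0-based
  keep <- start_samp >= 0 & (start_samp + n_samp) <= n_total
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    warn(sprintf("%d trial(s) extend outside the recording and were dropped.", n_dropped))
  }
  if (!any(keep)) abort("all candidate epochs fall outside the recording.")
  start_samp <- start_samp[keep]
  anchors <- anchors[keep]
  recalled <- recalled[keep]

  nch <- nrow(session$signal)
  data <- array(0, dim = c(length(start_samp), nch, n_samp))
  for (i in seq_along(start_samp)) {
    idx <- (start_samp[i] + 1L):(start_samp[i] + n_samp)
    data[i, , ] <- session$signal[, idx]
  }
  trials <- tibble(
    trial = seq_along(anchors), anchor_s = anchors, recalled = recalled
  )
  new_epoch_set(
    data, fs, window, condition, task,
    subject_id = ev$subject_id[1], channels = session$channels,
    trials = trials, n_dropped = n_dropped
  )
}
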