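#' Write a session to an EDF file
#'
#' Minimal European Data Format (EDF, 16-bit) writer. Signals are scaled
#' per channel to the full digital range; one data record per second, the
#' last record zero-padded (the true sample count is stored in the header
#' reserved field and honoured by [read_edf()]).
#'
#' @param session a `rec_session`. `fs` must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(session, path) {
  sig <- session$signal
  fs <- session$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate.")
  nch <- nrow(sig)
  n <- ncol(sig)
  n_rec <- ceiling(n / fs)

  pad <- function(x, width) {
    x <- substr(as.character(x), 1L, width)
    formatC(x, width = width, flag = "-")
  }
  num8 <- function(x) pad(formatC(x, format = "g", digits = 7), 8L)

  # per-channel physical scaling to the full 16-bit range
  pmax <- apply(abs(sig), 1, max)
  pmax <- ifelse(pmax > 0, pmax * 1.0001, 1)
  dmin <- -32768L; dmax <- 32767L
  dig <- matrix(0L, nch, n_rec * fs)
  for (i in seq_len(nch)) {
    d <- round((sig[i, ] + pmax[i]) / (2 * pmax[i]) * (dmax - dmin) + dmin)
    dig[i, seq_len(n)] <- as.integer(pmin(pmax(d, dmin), dmax))
    if (n < n_rec * fs) dig[i, (n + 1L):(n_rec * fs)] <- 0L
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  header_bytes <- 256L + 256L * nch
  wr(pad("0", 8))
  wr(pad("X X X X", 80))
  wr(pad("Startdate X X X X", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(header_bytes, 8))
  wr(pad(sprintf("ns=%d", n), 44))       # true sample count, read back by read_edf
  wr(pad(n_rec, 8))
  wr(pad("1", 8))                         # 1 s records
  wr(pad(nch, 4))
  for (i in seq_len(nch)) wr(pad(session$channels$name[i], 16))
  for (i in seq_len(nch)) wr(pad("", 80))
  for (i in seq_len(nch)) wr(pad("uV", 8))
  for (i in seq_len(nch)) wr(num8(-pmax[i]))
  for (i in seq_len(nch)) wr(num8(pmax[i]))
  for (i in seq_len(nch)) wr(pad(dmin, 8))
  for (i in seq_len(nch)) wr(pad(dmax, 8))
  for (i in seq_len(nch)) wr(pad("", 80))
  for (i in seq_len(nch)) wr(pad(fs, 8))
  for (i in seq_len(nch)) wr(pad("", 32))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nch)) {
      writeBin(dig[i, idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads 16-bit EDF with uniform per-record sample counts (the layout written
#' by [write_edf()] and by standard clinical exporters).
#'
#' @param path EDF file path.
#' @return list with `signal` (channels x samples matrix, rows named by EDF
#'   labels), `fs`, and `labels`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") abort(sprintf("not an EDF file (version field '%s'): %s", version, path))
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1L) abort(sprintf("malformed EDF header: %s", path))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L) abort("EDF reader supports uniform sampling rates only.")
  fs <- spr[1] / rec_dur

  total <- n_rec * spr[1]
  sig <- matrix(0, nch, total)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little", signed = TRUE)
      phys <- (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
      sig[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  m <- regmatches(reserved, regexec("ns=([0-9]+)", reserved))[[1]]
  if (length(m) == 2L) {
    n_true <- as.integer(m[2])
    if (n_true <= total) sig <- sig[, seq_len(n_true), drop = FALSE]
  }
  rownames(sig) <- labels
  list(signal = sig, fs = fs, labels = labels)
}

#' Write a session to disk
#'
#' Writes `<name>.edf` (signal), `<name>_channels.tsv` (name, group, region),
#' and `<name>_events.tsv` (onset_s, duration_s, trial_type, task,
#' subject_id, recalled).
#'
#' @param session a `rec_session`.
#' @param dir output directory (created if needed).
#' @param name file stem, default `"session"`.
#' @return the directory, invisibly.
#' @export
write_session <- function(session, dir, name = "session") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edf(session, file.path(dir, paste0(name, ".edf")))
  readr::write_tsv(session$channels, file.path(dir, paste0(name, "_channels.tsv")))
  readr::write_tsv(session$events, file.path(dir, paste0(name, "_events.tsv")))
  invisible(dir)
}

#' Read a session from disk
#'
#' Counterpart of [write_session()].
#'
#' @param dir directory containing the files.
#' @param name file stem, default `"session"`.
#' @return a `rec_session`.
#' @export
read_session <- function(dir, name = "session") {
  edf_path <- file.path(dir, paste0(name, ".edf"))
  ch_path <- file.path(dir, paste0(name, "_channels.tsv"))
  ev_path <- file.path(dir, paste0(name, "_events.tsv"))
  for (p in c(edf_path, ch_path, ev_path)) {
    if (!file.exists(p)) abort(sprintf("session file not found: %s", p))
  }
  edf <- read_edf(edf_path)
  channels <- readr::read_tsv(ch_path, show_col_types = FALSE)
  events <- readr::read_tsv(ev_path, show_col_types = FALSE)
  new_session(edf$signal, edf$fs, channels, events)
}
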