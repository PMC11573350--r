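#' Pipeline configuration
#'
#' Assembles (or reads from a YAML file) the configuration driving
#' [run_pipeline()]: where sessions come from (`"simulate"` or a directory
#' written by [write_session()]), the synthetic-session block, the analysis
#' bands, statistical options and the seed.
#'
#' @param path optional YAML file; entries override the defaults below.
#' @param input `"simulate"` or a directory of sessions.
#' @param session_names file stems when `input` is a directory.
#' @param synth a [session_config()] (or list of its arguments) used when
#'   simulating.
#' @param connectivity_band band for directed-connectivity analysis
#'   (default broadband 0.5-80 Hz).
#' @param plv_bands preset band names for phase-locking analysis.
#' @param hub_regions regions entering the net-outflow hub analysis.
#' @param alpha FDR level for contrasts.
#' @param seed integer seed governing all simulation randomness.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, input = "simulate",
                            session_names = "session",
                            synth = session_config(),
                            connectivity_band = "broadband",
                            plv_bands = c("delta-theta", "alpha", "beta", "gamma", "high-gamma"),
                            hub_regions = c("AI", "PCC/Pr", "mPFC", "dPPC", "MFG"),
                            alpha = 0.05, seed = 1L) {
  cfg <- list(
    input = input, session_names = session_names, synth = synth,
    connectivity_band = connectivity_band, plv_bands = plv_bands,
    hub_regions = hub_regions, alpha = alpha, seed = as.integer(seed)
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user$synth)) {
      user$synth <- do.call(session_config, user$synth)
    }
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  if (identical(cfg$input, "simulate")) {
    if (!inherits(cfg$synth, "session_config")) {
      cfg$synth <- do.call(session_config, cfg$synth)
    }
    cfg$synth$seed <- cfg$seed
  } else if (!dir.exists(cfg$input)) {
    abort(sprintf("input directory not found: %s", cfg$input))
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate on-disk session inputs
#'
#' Checks that each named session in a directory is readable (EDF header,
#' channel and event TSV schemas) and internally consistent (channel count
#' matches the signal, event onsets within the recording). Returns findings
#' rather than failing; an empty result means all checks passed.
#'
#' @param dir directory of sessions written by [write_session()].
#' @param session_names file stems to check.
#' @return tibble of findings: `session`, `level` (`"schema"`/`"integrity"`),
#'   `message`.
#' @export
validate_inputs <- function(dir, session_names = "session") {
  findings <- list()
  note <- function(session, level, message) {
    findings[[length(findings) + 1L]] <<- tibble(
      session = session, level = level, message = message
    )
  }
  for (nm in session_names) {
    edf_path <- file.path(dir, paste0(nm, ".edf"))
    ch_path <- file.path(dir, paste0(nm, "_channels.tsv"))
    ev_path <- file.path(dir, paste0(nm, "_events.tsv"))
    for (p in c(edf_path, ch_path, ev_path)) {
      if (!file.exists(p)) note(nm, "schema", sprintf("missing file: %s", basename(p)))
    }
    if (!file.exists(edf_path) || !file.exists(ch_path) || !file.exists(ev_path)) next
    edf <- tryCatch(read_edf(edf_path), error = function(e) {
      note(nm, "schema", sprintf("unreadable EDF: %s", conditionMessage(e))); NULL
    })
    channels <- tryCatch(
      readr::read_tsv(ch_path, show_col_types = FALSE),
      error = function(e) { note(nm, "schema", "unreadable channels TSV"); NULL }
    )
    events <- tryCatch(
      readr::read_tsv(ev_path, show_col_types = FALSE),
      error = function(e) { note(nm, "schema", "unreadable events TSV"); NULL }
    )
    if (!is.null(channels)) {
      miss <- setdiff(c("name", "group", "region"), names(channels))
      if (length(miss)) note(nm, "schema", paste0("channels TSV missing column(s): ", paste(miss, collapse = ", ")))
    }
    if (!is.null(events)) {
      miss <- setdiff(
        c("onset_s", "duration_s", "trial_type", "task", "subject_id", "recalled"),
        names(events)
      )
      if (length(miss)) note(nm, "schema", paste0("events TSV missing column(s): ", paste(miss, collapse = ", ")))
    }
    if (!is.null(edf) && !is.null(channels) && !"name" %in% setdiff(c("name"), names(channels))) {
      if (nrow(channels) && nrow(channels) != nrow(edf$signal)) {
        note(nm, "integrity", sprintf(
          "channel table has %d rows but EDF has %d signals", nrow(channels), nrow(edf$signal)
        ))
      }
    }
    if (!is.null(edf) && !is.null(events) && "onset_s" %in% names(events)) {
      dur <- ncol(edf$signal) / edf$fs
      n_bad <- sum(events$onset_s < 0 | events$onset_s > dur, na.rm = TRUE)
      if (n_bad) note(nm, "integrity", sprintf("%d event onset(s) outside the recording [0, %.2f] s", n_bad, dur))
    }
  }
  if (!length(findings)) {
    return(tibble(session = character(), level = character(), message = character()))
  }
  bind_rows(findings)
}

pipeline_stage <- function(name, expr) {
  inform(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> preprocess -> high-gamma power -> directed
#' connectivity (PTE, net outflow) -> phase locking -> group statistics, and
#' writes all result CSVs, a JSON manifest (seed, package version, file
#' checksums) and a human-readable summary to `out_dir`. Re-running with an
#' identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory results: `pte`,
#'   `net_outflow`, `plv`, `power`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  sessions <- pipeline_stage("load", {
    if (identical(config$input, "simulate")) {
      make_study(config$synth)
    } else {
      lapply(config$session_names, function(nm) read_session(config$input, nm))
    }
  })

  per_session <- pipeline_stage("analyze", {
    lapply(sessions, function(s) analyze_session(s, config))
  })

  pte_all <- bind_rows(lapply(per_session, `[[`, "pte"))
  plv_all <- bind_rows(lapply(per_session, `[[`, "plv"))
  power_all <- bind_rows(lapply(per_session, `[[`, "power"))
  net_tbl <- bind_rows(lapply(per_session, function(x) {
    mutate(x$net, subject = x$subject, condition = x$condition_of_net)
  }))

  stats_tbl <- pipeline_stage("stats", {
    pipeline_stats(pte_all, config)
  })

  pipeline_stage("report", {
    readr::write_csv(pte_all, file.path(out_dir, "pte_pairs.csv"))
    readr::write_csv(net_tbl, file.path(out_dir, "net_outflow.csv"))
    if (nrow(plv_all)) readr::write_csv(plv_all, file.path(out_dir, "plv_pairs.csv"))
    readr::write_csv(power_all, file.path(out_dir, "highgamma_power.csv"))
    readr::write_csv(stats_tbl, file.path(out_dir, "stats_contrasts.csv"))
    writeLines(pipeline_summary(stats_tbl, net_tbl), file.path(out_dir, "summary.txt"))
    csvs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest <- list(
      package = "ptenet",
      version = as.character(utils::packageVersion("ptenet")),
      seed = config$seed,
      input = config$input,
      n_sessions = length(sessions),
      files = as.list(setNames(unname(tools::md5sum(csvs)), basename(csvs)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(
    pte = pte_all, net_outflow = net_tbl, plv = plv_all,
    power = power_all, stats = stats_tbl
  ))
}

# Single-session analysis: preprocessing in the canonical order, then the
# power branch on the unfiltered (z-scored) montage and the connectivity
# branch on the broadband-filtered montage.
analyze_session <- function(session, config) {
  base <- preprocess_session(session, target_fs = 500, band = NULL)
  bb <- bandpass_filter(base, config$connectivity_band)

  other <- setdiff(intersect(config$hub_regions, unique(bb$channels$region)), "AI")
  pairs <- region_pairs(bb, "AI", other)

  pte_res <- list(); plv_res <- list(); power_res <- list()
  net <- NULL
  for (cond in c("rest", "encoding", "recall")) {
    ep <- epoch_session(bb, cond, match_to = "encoding")
    res <- pte_epochs(ep, pairs)
    pte_res[[cond]] <- res
    if (cond == "encoding") {
      all_pairs <- region_pairs(bb, config$hub_regions, config$hub_regions)
      net <- net_outflow(pte_epochs(ep, all_pairs))
    }
    for (bn in config$plv_bands) {
      epb <- bandpass_filter(epoch_session(base, cond, match_to = "encoding"), bn)
      plv_res[[paste(cond, bn)]] <- plv_epochs(epb, pairs)
    }
    pad <- if (cond == "recall") 0 else 0.25
    epp <- epoch_session(base, cond, pad_pre_s = pad, match_to = "encoding")
    pw <- smooth_windows(highgamma_envelope(epp))
    # encoding: own 0.2 s pre-stimulus baseline; recall has no pre-anchor
    # signal, so the matched rest-period mean serves as its baseline
    pw <- switch(cond,
      encoding = baseline_correct(pw),
      recall = baseline_correct(pw, rest = power_res[["rest"]]),
      pw
    )
    power_res[[cond]] <- pw
  }
  list(
    pte = bind_rows(pte_res),
    plv = bind_rows(plv_res),
    power = bind_rows(power_res),
    net = net,
    subject = session$events$subject_id[1],
    condition_of_net = "encoding"
  )
}

# Direction-of-flow contrasts (AI vs each hub region, per condition) plus
# task-vs-rest contrasts, FDR-corrected together.
pipeline_stats <- function(pte_all, config) {
  regions <- setdiff(unique(c(pte_all$source_region, pte_all$target_region)), "AI")
  rows <- list()
  multi_subject <- length(unique(pte_all$subject)) > 1L
  for (cond in intersect(c("encoding", "recall"), unique(pte_all$condition))) {
    sub <- filter(pte_all, .data$condition == cond)
    for (rg in regions) {
      tab <- tryCatch(direction_table(sub, "AI", rg), error = function(e) NULL)
      if (is.null(tab) || length(unique(tab$condition)) != 2L) next
      ct <- suppressWarnings(condition_contrast(tab))
      rows[[length(rows) + 1L]] <- tibble(
        contrast = sprintf("AI<->%s", rg), condition = cond,
        f = ct$f, df1 = ct$df1, df2 = ct$df2, p = ct$p, d = ct$d,
        direction = ct$direction, n_obs = ct$n
      )
    }
  }
  if (!length(rows)) {
    return(tibble(
      contrast = character(), condition = character(), f = numeric(),
      df1 = numeric(), df2 = numeric(), p = numeric(), d = numeric(),
      direction = character(), n_obs = integer(), p_fdr = numeric(),
      significant = logical()
    ))
  }
  out <- bind_rows(rows)
  adj <- fdr_bh(out$p, config$alpha)
  out$p_fdr <- adj$p_adj
  out$significant <- adj$reject
  out
}

pipeline_summary <- function(stats_tbl, net_tbl) {
  lines <- c("Directed information flow summary", "=================================", "")
  if (nrow(stats_tbl)) {
    for (i in seq_len(nrow(stats_tbl))) {
      r <- stats_tbl[i, ]
      lines <- c(lines, sprintf(
        "%-14s %-9s higher: %-16s F(%g, %.1f) = %8.3f  p = %.3g  p_fdr = %.3g  d = %.3f%s",
        r$contrast, r$condition, r$direction, r$df1, r$df2, r$f, r$p, r$p_fdr, r$d,
        if (r$significant) "  *" else ""
      ))
    }
  }
  lines <- c(lines, "", "Net outflow ranking (encoding, mean over sessions)", "")
  if (nrow(net_tbl)) {
    rk <- net_tbl |>
      group_by(.data$node) |>
      summarise(net = mean(.data$net), .groups = "drop") |>
      arrange(dplyr::desc(.data$net))
    for (i in seq_len(nrow(rk))) {
      lines <- c(lines, sprintf("  %d. %-10s net = %+.4f", i, rk$node[i], rk$net[i]))
    }
  }
  lines
}
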