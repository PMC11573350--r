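#' Plot directed PTE by direction
#'
#' Violin/point display of trial-averaged PTE for each ordered region pair,
#' mirroring the direction-of-flow comparisons of the analysis (one violin
#' per direction).
#'
#' @param object a `pte_result`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pte_result <- function(object, ...) {
  df <- object |>
    mutate(direction = paste0(.data$source_region, " → ", .data$target_region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction, y = .data$pte_mean)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "point", size = 2.5, colour = "white") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "PTE (nats)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot net-outflow ranking
#'
#' @param object a `net_outflow`.
#' @param ... unused.
#' @return a ggplot bar chart of net = outflow - inflow per node.
#' @exportS3Method ggplot2::autoplot
autoplot.net_outflow <- function(object, ...) {
  df <- mutate(object, node = stats::reorder(.data$node, .data$net))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$net)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "net outflow (PTE out - PTE in, nats)") +
    ggplot2::theme_minimal()
}

#' Plot a high-gamma power time course
#'
#' Trial-averaged envelope per region over window centers, with a ribbon of
#' +-1 SEM across trials and channels.
#'
#' @param object a `power_ts`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.power_ts <- function(object, ...) {
  df <- object |>
    group_by(.data$region, .data$window_center_s) |>
    summarise(
      m = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ylab <- if (identical(attr(object, "baseline"), "none")) {
    "high-gamma amplitude (% of mean)"
  } else {
    "high-gamma amplitude (% of mean, baseline-corrected)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_center_s, y = .data$m, colour = .data$region)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se, fill = .data$region),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time from event (s)", y = ylab) +
    ggplot2::theme_minimal()
}
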