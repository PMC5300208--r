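#' Plot a per-frame shape series
#'
#' Time traces of each metric in the series, one facet per metric with free
#' y scales — the standard way to eyeball end-to-end-distance or ellipsoid
#' fluctuations over a production run.
#'
#' @param object A `gag_shape_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gag_shape_series
#' @export
autoplot.gag_shape_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ps, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#2166ac") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot residue-level hydrogen-bond occupancies
#'
#' @param object A `gag_occupancy` table.
#' @param ... Unused.
#' @return A ggplot object (occupancy percent by residue).
#' @method autoplot gag_occupancy
#' @export
autoplot.gag_occupancy <- function(object, ...) {
  df <- as_tibble(object)
  df$residue <- factor(df$residue, levels = df$residue[order(df$residue_id)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$occupancy)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "H-bond occupancy (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a mimicry report as a leg/score panel
#'
#' @param object A `gag_mimicry_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gag_mimicry_report
#' @export
autoplot.gag_mimicry_report <- function(object, ...) {
  df <- tidy(object)
  df$leg <- factor(df$leg, levels = c("free_state", "binding_site", "bound_state"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$leg, y = .data$score,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(pass = "#1a9850", fail = "#d73027",
                                          inconclusive = "#fdae61",
                                          not_evaluated = "grey70")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = paste(object$candidate, "vs", object$reference),
                  x = NULL, y = "leg score") +
    ggplot2::theme_minimal()
}

#' Box-plot comparison of metric distributions across molecules
#'
#' Rebuilds the classic compiled box plot from distribution summaries: one
#' box (q1, median, q3 with min-max whiskers) per molecule, faceted by
#' metric.
#'
#' @param summaries Named list of `gag_summary` tables, one per molecule.
#' @param metrics Optional metric subset to show.
#' @return A ggplot object.
#' @export
plot_summary_comparison <- function(summaries, metrics = NULL) {
  df <- bind_rows(lapply(names(summaries), function(nm) {
    s <- as_tibble(summaries[[nm]]); s$molecule <- nm; s
  }))
  if (!is.null(metrics)) df <- df[df$metric %in% metrics, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molecule)) +
    ggplot2::geom_boxplot(ggplot2::aes(ymin = .data$min, lower = .data$q1,
                                       middle = .data$median, upper = .data$q3,
                                       ymax = .data$max),
                          stat = "identity", fill = "#d1e5f0") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
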