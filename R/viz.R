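# the five named colors used for the most-used apps, then greys for "other"
TIMELINE_PALETTE <- c("black", "red", "green3", "gold", "blue")

new_phonelog_plot <- function(plot, geometry, path = NULL,
                              width = 8, height = 4.5, dpi = 150) {
  if (!is.null(path)) {
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = dpi)
    readr::write_csv(geometry, paste0(path, ".geometry.csv"), na = "")
  }
  structure(list(plot = plot, geometry = geometry, path = path),
    class = "phonelog_plot"
  )
}

#' @export
print.phonelog_plot <- function(x, ...) {
  print(x$plot, ...)
  invisible(x)
}

#' Bar chart of total time per app in one 24-hour period
#'
#' One horizontal bar per app, length proportional to foreground time. Every
#' plot function in the package also returns (and, when `path` is given,
#' writes alongside the image) a machine-readable *geometry sidecar*: a table
#' of exactly what was drawn, so analyses and tests can assert the plotted
#' data rather than pixels.
#'
#' @param app_durations [per_app_durations()] output for a single 24-h
#'   period.
#' @param path Optional image file path (extension selects the format, e.g.
#'   `.png` or `.svg`); the sidecar is written to `<path>.geometry.csv`.
#' @param width,height,dpi Image dimensions (inches) and resolution.
#' @return A `phonelog_plot`: list with `plot` (ggplot) and `geometry`
#'   (tibble `app_id`, `duration_ms`, `duration_min`).
#' @export
plot_app_totals <- function(app_durations, path = NULL,
                            width = 8, height = 4.5, dpi = 150) {
  geometry <- tibble(
    app_id = app_durations$app_id,
    duration_ms = app_durations$duration_ms,
    duration_min = app_durations$duration_ms / MS_PER_MIN
  )
  p <- ggplot2::ggplot(
    geometry,
    ggplot2::aes(
      x = .data$duration_min,
      y = stats::reorder(.data$app_id, .data$duration_min)
    )
  ) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(
      x = "Total foreground time (minutes)", y = NULL,
      title = "Time spent per app over 24 h"
    ) +
    ggplot2::theme_minimal()
  if (nrow(geometry) == 0) {
    p <- p + ggplot2::annotate("text", x = 0, y = 1, label = "no app usage")
  }
  new_phonelog_plot(p, geometry, path, width, height, dpi)
}

#' Barcode strip of screen use across one day
#'
#' A horizontal 24-hour axis on which each session is a dark bar spanning
#' `[start, end)` and gaps are blank — periods of consistent use read as
#' solid black. Sessions are clipped to the requested day; micro-gaps are
#' drawn as-is, not bridged.
#'
#' @param sessions [sessionize()] output.
#' @param day_start_ms UNIX ms of the (local) midnight opening the 24-h
#'   period to display.
#' @param path,width,height,dpi See [plot_app_totals()]; the default shape is
#'   a wide strip.
#' @return A `phonelog_plot` whose geometry has one row per drawn bar:
#'   `start_ms`, `end_ms`, `x0_hours`, `x1_hours`.
#' @export
plot_day_barcode <- function(sessions, day_start_ms, path = NULL,
                             width = 8, height = 1.5, dpi = 150) {
  day_end <- day_start_ms + MS_PER_DAY
  s <- pmax(sessions$start_ms, day_start_ms)
  e <- pmin(sessions$end_ms, day_end)
  keep <- e > s
  geometry <- tibble(
    start_ms = s[keep], end_ms = e[keep],
    x0_hours = (s[keep] - day_start_ms) / MS_PER_HOUR,
    x1_hours = (e[keep] - day_start_ms) / MS_PER_HOUR
  )
  p <- ggplot2::ggplot(geometry) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$x0_hours, xmax = .data$x1_hours),
      ymin = 0, ymax = 1, fill = "black"
    ) +
    ggplot2::scale_x_continuous(
      limits = c(0, 24),
      breaks = seq(0, 24, by = 4)
    ) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "Hour of day", y = NULL, title = "Screen use") +
    ggplot2::theme_minimal()
  new_phonelog_plot(p, geometry, path, width, height, dpi)
}

#' Colored per-app timeline of one day
#'
#' Like the barcode, but segments are colored by app: the `k` most-used apps
#' of the day get named colors, everything else is grouped as `"other"` in
#' grey, and the legend lists the color-to-app mapping.
#'
#' @param events A validated `event_stream`.
#' @param day_start_ms UNIX ms of the midnight opening the displayed day.
#' @param k How many apps to color individually (default 5).
#' @param palette Colors for the top-`k` apps.
#' @param path,width,height,dpi See [plot_app_totals()].
#' @return A `phonelog_plot` whose geometry has one row per drawn segment:
#'   `app_id`, `group`, `color`, `start_ms`, `end_ms`, `x0_hours`,
#'   `x1_hours`.
#' @export
plot_app_timeline <- function(events, day_start_ms, k = 5,
                              palette = TIMELINE_PALETTE, path = NULL,
                              width = 8, height = 2.5, dpi = 150) {
  day_end <- day_start_ms + MS_PER_DAY
  ivs <- app_intervals(events, span = c(day_start_ms, day_end))
  totals <- per_app_durations(events, span = c(day_start_ms, day_end))
  k <- min(k, nrow(totals))
  top <- totals$app_id[seq_len(k)]
  palette <- rep_len(palette, max(k, 1))

  group <- ifelse(ivs$app_id %in% top, ivs$app_id, "other")
  color <- c(stats::setNames(palette[seq_len(k)], top), other = "grey70")
  geometry <- tibble(
    app_id = ivs$app_id,
    group = group,
    color = unname(color[group]),
    start_ms = ivs$start_ms, end_ms = ivs$end_ms,
    x0_hours = (ivs$start_ms - day_start_ms) / MS_PER_HOUR,
    x1_hours = (ivs$end_ms - day_start_ms) / MS_PER_HOUR
  )
  lev <- c(top, if (any(group == "other")) "other")
  geometry$group <- factor(geometry$group, levels = lev)
  p <- ggplot2::ggplot(geometry) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$x0_hours, xmax = .data$x1_hours,
        fill = .data$group
      ),
      ymin = 0, ymax = 1
    ) +
    ggplot2::scale_fill_manual(values = color, name = "app") +
    ggplot2::scale_x_continuous(
      limits = c(0, 24),
      breaks = seq(0, 24, by = 4)
    ) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "Hour of day", y = NULL, title = "App use") +
    ggplot2::theme_minimal()
  new_phonelog_plot(p, geometry, path, width, height, dpi)
}
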