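#' Plot a reactivity profile
#'
#' Per-nucleotide reactivity along the template, colored by read-out
#' section; an optional baseline is drawn as a dashed line and hotspot
#' calls as shaded spans.
#'
#' @param object A `reactivity_profile`.
#' @param baseline Optional [degradation_baseline()].
#' @param hotspots Optional [find_hotspots()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reactivity_profile
#' @export
autoplot.reactivity_profile <- function(object, baseline = NULL,
                                        hotspots = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$reactivity)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$section), width = 1,
                      na.rm = TRUE) +
    ggplot2::labs(x = "position (nt)", y = "reactivity (a.u.)",
                  title = attr(object, "treatment")) +
    ggplot2::theme_minimal()
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(hotspots),
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red",
      inherit.aes = FALSE)
  }
  if (!is.null(baseline)) {
    bl <- tibble(position = df$position,
                 y = baseline_at(baseline, df$position))
    p <- p + ggplot2::geom_line(data = bl,
                                ggplot2::aes(x = .data$position, y = .data$y),
                                linetype = "dashed", inherit.aes = FALSE)
  }
  p
}

#' Plot an electropherogram
#'
#' Signal against size (or migration time), with the main-peak window
#' shaded when given.
#'
#' @param object An [electropherogram()].
#' @param window Optional c(lo, hi) main-peak window in nt.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot electropherogram
#' @export
autoplot.electropherogram <- function(object, window = NULL, ...) {
  df <- as_tibble(object)
  axis <- names(df)[1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[axis]],
                                        y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (axis == "size_nt") "size (nt)" else "migration time",
                  y = "fluorescence (a.u.)",
                  title = attr(object, "sample_name")) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  }
  p
}

#' Plot hotspot calls along the construct
#'
#' @param calls A [find_hotspots()] table.
#' @param construct Optional [mrna_construct()] whose elements are drawn as
#'   a track.
#' @return A ggplot.
#' @export
plot_hotspots <- function(calls, construct = NULL) {
  df <- as_tibble(calls)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = 1, yend = 1),
                          linewidth = 4, color = "red") +
    ggplot2::labs(x = "position (nt)", y = NULL,
                  title = "degradation hotspot calls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(construct)) {
    p <- p + ggplot2::geom_segment(
      data = construct$elements,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0,
                   color = .data$label),
      linewidth = 3)
  }
  p
}
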