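#' Plot a time-frequency coherency map
#'
#' Raster of WTC, IWTC or phase over time and (log-scaled) frequency, with
#' the cone of influence drawn as a dashed boundary; bins outside the COI are
#' blanked.
#'
#' @param object a `coherency_map`.
#' @param field `"wtc"`, `"iwtc"` or `"phase"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coherency_map <- function(object, field = c("wtc", "iwtc", "phase"),
                                   ...) {
  field <- match.arg(field)
  df <- tidy(object)
  df$value <- df[[field]]
  df$value[!df$in_coi | !df$valid] <- NA_real_
  omega0 <- if (!is.null(object$spec)) object$spec$omega0 else 6
  edge_s <- pmin(object$time - min(object$time),
                 max(object$time) - object$time)
  coi_f <- omega0 / (2 * pi * pmax(edge_s / sqrt(2), 1e-6))
  coi_df <- tibble::tibble(time = object$time,
                           freq = pmin(coi_f, max(object$freqs)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_line(data = coi_df,
                       ggplot2::aes(y = .data$freq), linetype = "dashed",
                       linewidth = 0.3, colour = "grey20") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = field) +
    ggplot2::labs(
      x = "time relative to event (s)", y = "frequency (Hz)",
      title = paste0(toupper(field), ": ", object$pair[1], " ~ ",
                     object$pair[2], " (N = ", object$n_epochs, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a network snapshot with a force-directed layout
#'
#' @param object a `network_snapshot`.
#' @param seed layout seed.
#' @param ... unused.
#' @return A ggplot object; edge width encodes weight.
#' @export
autoplot.network_snapshot <- function(object, seed = 1L, ...) {
  xy <- force_layout(object, seed = seed)
  ed <- object$edges |>
    dplyr::left_join(xy, by = c(from = "node")) |>
    dplyr::left_join(xy, by = c(to = "node"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, linewidth = .data$weight),
      colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_point(data = xy, ggplot2::aes(.data$x, .data$y),
                        size = 3) +
    ggplot2::geom_text(data = xy,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2), name = "weight") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot dynamic centrality series
#'
#' One line per node plus the across-node mean (dashed).
#'
#' @param object a `dynamic_centrality`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dynamic_centrality <- function(object, ...) {
  df <- tidy(object)
  mean_df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$value,
                                   colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = mean_df,
                       mapping = ggplot2::aes(x = .data$window,
                                              y = .data$mean_value),
                       colour = "black", linetype = "dashed",
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "window", y = object$measure,
                  title = paste("dynamic", object$measure,
                                "(w =", object$w, "s)")) +
    ggplot2::theme_minimal()
}

#' Plot characteristic-centrality contributions
#'
#' @param object a `characteristic_centrality`.
#' @param ... unused.
#' @return A ggplot object: sorted PC1 contributions per measure.
#' @export
autoplot.characteristic_centrality <- function(object, ...) {
  df <- dplyr::filter(object$contributions, .data$component == "PC1")
  df$measure <- factor(df$measure, levels = rev(object$ranking))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contribution,
                                   y = .data$measure)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "contribution to PC1 (%)", y = NULL,
      title = paste0("characteristic centrality (PC1: ",
                     round(100 * object$variance_fraction[1], 1),
                     "% of variance)")) +
    ggplot2::theme_minimal()
}
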