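#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Long-format view of a coherency map
#'
#' @param x a `coherency_map`.
#' @param ... unused.
#' @return Tibble with `time`, `freq`, `scale`, `wtc`, `iwtc`, `phase`,
#'   `in_coi`, `valid` per time-frequency bin.
#' @export
tidy.coherency_map <- function(x, ...) {
  ns <- length(x$scales)
  nt <- length(x$time)
  tibble::tibble(
    time = rep(x$time, each = ns),
    freq = rep(x$freqs, nt),
    scale = rep(x$scales, nt),
    wtc = as.vector(pmin(Mod(x$rhat), 1)),
    iwtc = as.vector(Im(x$rhat)),
    phase = as.vector(Arg(x$rhat)),
    in_coi = as.vector(x$coi),
    valid = as.vector(x$valid)
  )
}

#' @export
glance.coherency_map <- function(x, ...) {
  inside <- x$coi & x$valid
  tibble::tibble(
    pair = paste(x$pair, collapse = "~"),
    n_epochs = x$n_epochs,
    n_scales = length(x$scales),
    n_times = length(x$time),
    peak_wtc = if (any(inside)) max(Mod(x$rhat)[inside]) else NA_real_,
    peak_iwtc = if (any(inside)) max(abs(Im(x$rhat))[inside]) else NA_real_
  )
}

#' @export
tidy.network_snapshot <- function(x, ...) x$edges

#' @export
glance.network_snapshot <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    gmc = if (length(x$nodes) >= 2) global_microscale_connectivity(x)
          else NA_real_,
    t_start = x$t_window[1], t_end = x$t_window[2],
    f_low = x$f_window[1], f_high = x$f_window[2],
    significant_only = x$significant_only
  )
}

#' @export
tidy.dynamic_centrality <- function(x, ...) {
  tibble::as_tibble(as.table(x$series), .name_repair = "minimal") |>
    stats::setNames(c("node", "window", "value")) |>
    dplyr::mutate(window = as.integer(sub("^w", "", .data$window)),
                  measure = x$measure, .before = "value")
}

#' @export
glance.dynamic_centrality <- function(x, ...) {
  tibble::tibble(window = seq_along(x$mean_series),
                 mean_value = as.numeric(x$mean_series),
                 measure = x$measure, w = x$w)
}

#' @export
tidy.characteristic_centrality <- function(x, ...) x$contributions

#' @export
glance.characteristic_centrality <- function(x, ...) {
  tibble::tibble(component = names(x$variance_fraction),
                 variance_fraction = as.numeric(x$variance_fraction))
}

#' @export
tidy.pca_modules <- function(x, ...) {
  tibble::as_tibble(as.table(x$loadings), .name_repair = "minimal") |>
    stats::setNames(c("pair", "component", "loading"))
}

#' @export
glance.pca_modules <- function(x, ...) {
  tibble::tibble(component = names(x$variance_fraction),
                 variance_fraction = as.numeric(x$variance_fraction))
}

#' @export
tidy.effect_size <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$d,
                 mean_a = x$mean_a, mean_b = x$mean_b,
                 sd_a = x$sd_a, sd_b = x$sd_b, n_a = x$n_a, n_b = x$n_b)
}

#' @export
glance.effect_size <- tidy.effect_size
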