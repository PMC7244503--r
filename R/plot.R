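#' Plot a free-energy profile
#'
#' Free energy per macrostate against the number of invader-target base
#' pairs. When the system carries a mismatch, a dotted vertical line marks
#' the coordinate of mismatch enclosure (`h + x`).
#'
#' @param object a [displacement_profile()]
#' @param ... unused
#' @return a ggplot
#' @importFrom ggplot2 autoplot
#' @method autoplot free_energy_profile
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  sys <- attr(object, "system")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$G_kBT)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "invader-target base pairs, n",
                  y = expression(G ~ (k[B] * T))) +
    ggplot2::theme_minimal()
  if (!is.null(sys$mismatch_position)) {
    p <- p + ggplot2::geom_vline(
      xintercept = sys$toehold_length + sys$mismatch_position,
      linetype = "dotted"
    )
  }
  p
}

#' Plot a fluorescence trace
#'
#' @param object a [tmsd_trace()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot tmsd_trace
#' @export
autoplot.tmsd_trace <- function(object, ...) {
  sig_cols <- setdiff(names(object), c("time_s", "noiseless"))
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[c("time_s", sig_cols)],
                              -"time_s", names_to = "channel",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 60, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "signal (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a conditional-probability decomposition
#'
#' @param object a [conditional_probabilities()] result
#' @param ... unused
#' @return a ggplot
#' @method autoplot tmsd_decomposition
#' @export
autoplot.tmsd_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"x",
                              names_to = "quantity", values_to = "p")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$p,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "reference base pair x", y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot relative displacement rate against mismatch position
#'
#' @param rates tibble with columns `position` and `ratio` (e.g. from
#'   looping [relative_rate()] over a mismatch series)
#' @return a ggplot
#' @export
plot_relative_rates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$position, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mismatch position", y = expression(k / k[0])) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
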