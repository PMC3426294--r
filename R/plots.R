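#' Plot mean trajectories with standard-deviation bands
#'
#' One panel per state: the mean trajectory (dotted, as prevalence
#' figures conventionally draw the expectation) inside the
#' mean-plus/minus-one-standard-deviation ribbon.
#'
#' @param object A [chaos_moments()] tibble.
#' @param states States to show; defaults to all present.
#' @param percent Scale the y axis to percentage points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chaos_moments <- function(object, states = NULL, percent = TRUE, ...) {
  dat <- object
  if (!is.null(states)) dat <- dplyr::filter(dat, .data$state %in% states)
  scale <- if (percent) 100 else 1
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = scale * .data$band_low, ymax = scale * .data$band_high),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_line(ggplot2::aes(y = scale * .data$mean), linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$state), scales = "free_y") +
    ggplot2::labs(
      x = "time (weeks)",
      y = if (percent) "prevalence (%)" else "proportion",
      title = "Mean trajectory with one-standard-deviation band"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.chaos_moments
#' @export
plot_prevalence_bands <- function(object, states = NULL, percent = TRUE, ...) {
  autoplot.chaos_moments(object, states = states, percent = percent, ...)
}

#' Plot first-order Sobol indices over time
#'
#' One panel per state; one line per random parameter (plus the pooled
#' interaction contribution), each in `[0, 1]`.
#'
#' @param object A [chaos_sobol()] tibble.
#' @param states States to show; defaults to all present.
#' @param include_interactions Show the pooled cross-term series.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chaos_sobol <- function(object, states = NULL,
                                 include_interactions = TRUE, ...) {
  dat <- object
  if (!is.null(states)) dat <- dplyr::filter(dat, .data$state %in% states)
  if (!include_interactions) {
    dat <- dplyr::filter(dat, .data$parameter != "interactions")
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$index,
                                    colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$state)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (weeks)", y = "first-order Sobol index",
                  colour = "parameter",
                  title = "Variance-based sensitivity over time") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.chaos_sobol
#' @export
plot_sobol_indices <- function(object, states = NULL,
                               include_interactions = TRUE, ...) {
  autoplot.chaos_sobol(object, states = states,
                       include_interactions = include_interactions, ...)
}
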