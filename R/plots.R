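#' Plot the MU pool property distributions
#'
#' Four-panel view of the pool: recruitment thresholds, normalized twitch
#' forces, normalized tetanic forces and innervation ratios against the
#' MU index, coloured by fibre type.
#'
#' @param object A [mu_pool()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mu_pool
#' @export
autoplot.mu_pool <- function(object, ...) {
  long <- object |>
    dplyr::select("mu", "type", "T_th", "f_tw_bar", "f0_bar", "IR") |>
    tidyr::pivot_longer(cols = c("T_th", "f_tw_bar", "f0_bar", "IR"),
                        names_to = "property", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, y = .data$value,
                                     colour = .data$type)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = "MU index (threshold-ranked)", y = NULL,
                  colour = "MU type") +
    ggplot2::theme_minimal()
}

#' Plot the five neuromechanical states of one MU
#'
#' Each state is normalized to its own maximum so the cascade can be read
#' on one scale: MN potential `e`, fibre potential `u`, free calcium `c`,
#' calcium-troponin `P` and active state `a`.
#'
#' @param object An `ne_trajectory` from [simulate_ne()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ne_trajectory
#' @export
autoplot.ne_trajectory <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(cols = c("e", "u", "c", "P", "a"),
                        names_to = "state", values_to = "value") |>
    dplyr::group_by(.data$state) |>
    dplyr::mutate(value = .data$value / max(abs(.data$value), 1e-300)) |>
    dplyr::ungroup() |>
    dplyr::mutate(state = factor(.data$state, c("e", "u", "c", "P", "a")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$state)) +
    ggplot2::labs(x = "time (s)", y = "normalized state") +
    ggplot2::theme_minimal()
}

#' Plot a whole-muscle simulation
#'
#' Whole-muscle force in Newtons with the per-MU dispersed forces behind
#' it (scaled by `F0M`).
#'
#' @param object A `muscle_sim` from [simulate_muscle()].
#' @param show_mu Draw the individual MU forces.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot muscle_sim
#' @export
autoplot.muscle_sim <- function(object, show_mu = TRUE, ...) {
  p <- ggplot2::ggplot()
  if (show_mu) {
    p <- p + ggplot2::geom_line(
      data = object$mu_forces,
      ggplot2::aes(x = .data$time, y = .data$f * object$settings$F0M,
                   group = .data$mu),
      colour = "grey70", linewidth = 0.3)
  }
  p + ggplot2::geom_line(
    data = object$muscle,
    ggplot2::aes(x = .data$time, y = .data$F_M),
    colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "time (s)", y = "force (N)") +
    ggplot2::theme_minimal()
}

#' Plot a validation report
#'
#' Overlays the predicted and reference traces and annotates the headline
#' metrics.
#'
#' @param object A `validation_report` from [trace_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(object$pred, trace = "predicted"),
    dplyr::mutate(object$ref, trace = "reference"))
  lab <- sprintf("nRMSE = %.1f%%  r2 = %.3f", object$nRMSE, object$r2)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::annotate("text", x = -Inf, y = Inf, label = lab,
                      hjust = -0.1, vjust = 1.5) +
    ggplot2::labs(x = "time (s)", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}
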