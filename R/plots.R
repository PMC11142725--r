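#' Plot final concentration profiles of a trajectory
#'
#' Draws the steady-state spatial profiles of the active Rho-GTPases and the
#' bound polarity complexes along the apical-basal axis (basal at x = 0),
#' the standard summary view of a polarization run.
#'
#' @param object a `polar_trajectory`.
#' @param species fields to draw (default: the active GTPases and bound
#'   complexes).
#' @param time_s which snapshot to draw (default: the final time).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.polar_trajectory <- function(object,
                                      species = c("R_a", "rho_a", "C_a",
                                                  "P_C", "S_C"),
                                      time_s = NULL, ...) {
  df <- tidy.polar_trajectory(object, species = species)
  tt <- time_s %||% max(df$time_s)
  df <- dplyr::filter(df, abs(.data$time_s - tt) < 1e-9)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$conc_uM,
                                   colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "position along apical-basal axis (um, basal at 0)",
                  y = "concentration (uM)",
                  colour = NULL,
                  title = sprintf("Concentration profiles at t = %g s", tt)) +
    ggplot2::theme_minimal()
}

#' Plot normalized K-S distances of an MPSA
#'
#' Bar chart of each parameter's K-S distance per output, normalized to the
#' per-output maximum, with the dummy-derived significance threshold as a
#' horizontal line. Parameters above the line are influential.
#'
#' @param object a `polar_mpsa`.
#' @param ... unused.
#' @return A ggplot object faceted by output.
#' @export
autoplot.polar_mpsa <- function(object, ...) {
  df <- tidy.polar_mpsa(object) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rownames(object$ks)))
  thr <- tibble::tibble(
    output = names(object$threshold),
    threshold_normalized = object$threshold /
      apply(object$ks, 2, max)[names(object$threshold)]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter,
                                   y = .data$ks_normalized,
                                   fill = .data$influential)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold_normalized),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~output) +
    ggplot2::labs(x = NULL, y = "K-S distance (normalized per output)",
                  fill = "influential") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot an integrin dose sweep
#'
#' Apical-basal concentration differences of the six outputs as a function of
#' the integrin amplitude, showing the all-or-nothing dose threshold of
#' polarization.
#'
#' @param object a `polar_sweep`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.polar_sweep <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$amplitude_uM,
                               y = .data$difference_uM,
                               colour = .data$output)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$threshold_uM, linetype = 2) +
    ggplot2::labs(x = "integrin amplitude (uM)",
                  y = "apical-basal difference (uM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
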