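#' Plot a visual predictive check
#'
#' Observed percentiles (lines with points) overlaid on the 90% confidence
#' bands of the corresponding simulated percentiles.
#'
#' @param object A `vpc_result` from [vpc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vpc_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$sim_lower, ymax = .data$sim_upper,
                   group = .data$percentile),
      alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$sim_median, group = .data$percentile),
      colour = "steelblue") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$observed, group = .data$percentile),
      colour = "firebrick", linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "firebrick", size = 1) +
    ggplot2::labs(x = "Time (h)", y = "Observation",
                  title = "Visual predictive check",
                  subtitle = "red: observed percentiles; blue: simulated with 90% CI") +
    ggplot2::theme_minimal()
}

#' Goodness-of-fit panels for a population model fit
#'
#' DV vs PRED, DV vs IPRED, CWRES vs PRED and CWRES vs time.
#'
#' @param object A `pop_model_fit`.
#' @param ... Unused.
#' @return A ggplot object (facetted panels).
#' @export
autoplot.pop_model_fit <- function(object, ...) {
  d <- cwres(object)
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "DV vs PRED", x = d$PRED, y = d$DV),
    tibble::tibble(panel = "DV vs IPRED", x = d$IPRED, y = d$DV),
    tibble::tibble(panel = "CWRES vs PRED", x = d$PRED, y = d$CWRES),
    tibble::tibble(panel = "CWRES vs time", x = d$TIME, y = d$CWRES))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(formula = y ~ x, method = "loess", se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, title = "Goodness of fit")
}

#' Concentration-inhibition curve of a pooled Emax fit
#'
#' @param object An `emax_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emax_fit <- function(object, ...) {
  grid <- tibble::tibble(
    conc = exp(seq(log(max(min(object$data$conc[object$data$conc > 0]),
                            1e-3)),
                   log(max(object$data$conc)), length.out = 200)))
  grid$inhibition <- predict_emax(object$params, grid$conc)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conc, y = .data$inhibition)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "steelblue",
                       linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (ng/mL)", y = "DPP-4 inhibition (%)",
                  title = "Pooled Emax concentration-effect model") +
    ggplot2::theme_minimal()
}

#' Mean effect-time profiles by arm
#'
#' Group-mean DPP-4 inhibition over time, one line per arm, for a quick
#' look at the simulated (or observed) inhibition time course.
#'
#' @param ds A [study_dataset()].
#' @return A ggplot object.
#' @export
plot_inhibition_time <- function(ds) {
  act <- tibble::as_tibble(ds) %>%
    dplyr::filter(.data$EVID == 0L, .data$DVID == "dpp4_activity")
  base <- act %>%
    dplyr::group_by(.data$ID) %>%
    dplyr::summarise(base = .data$DV[which.min(.data$TIME)],
                     .groups = "drop")
  d <- act %>%
    dplyr::left_join(base, by = "ID") %>%
    dplyr::mutate(inhibition = (1 - .data$DV / .data$base) * 100) %>%
    dplyr::group_by(.data$ARM, .data$TIME) %>%
    dplyr::summarise(inhibition = mean(.data$inhibition),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$TIME, y = .data$inhibition,
                                  colour = .data$ARM)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Mean DPP-4 inhibition (%)") +
    ggplot2::theme_minimal()
}
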