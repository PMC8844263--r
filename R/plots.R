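#' Plot organ time--activity curves of a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param organs Organs to show (default: the six highest-uptake curves).
#' @return A ggplot.
#' @export
plot_cohort_tacs <- function(cohort,
                             organs = c("muscle", "liver", "kidneys",
                                        "heart_content", "cortical_bone",
                                        "spleen")) {
  df <- dplyr::filter(cohort$tacs, .data$organ %in% organs)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min,
                                   100 * .data$fraction_ia,
                                   colour = .data$organ,
                                   group = interaction(.data$subject_id,
                                                       .data$organ))) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time post-injection (min)",
                  y = "% injected activity (decay-corrected)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname fit_washout
#' @param object A `washout_fit`.
#' @param ntac The curve the fit was computed from.
#' @export
autoplot.washout_fit <- function(object, ntac, ...) {
  grid <- tibble::tibble(
    time_min = seq(object$t_start_min, max(ntac$time_min), length.out = 100))
  grid$value <- object$A0 *
    exp(-object$k_bio * (grid$time_min - object$t_start_min) / 60)
  ggplot2::ggplot(ntac, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Time post-injection (min)",
                  y = "Activity per MBq injected",
                  title = object$organ) +
    ggplot2::theme_minimal()
}

#' @rdname build_dose_report
#' @param object A `dose_report`.
#' @export
autoplot.dose_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(organ = stats::reorder(.data$organ,
                                         .data$mean_mgy_per_mbq))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_mgy_per_mbq, .data$organ)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      xmin = pmax(0, .data$mean_mgy_per_mbq - .data$sd_mgy_per_mbq),
      xmax = .data$mean_mgy_per_mbq + .data$sd_mgy_per_mbq),
      width = 0.3) +
    ggplot2::labs(x = "Absorbed dose (mGy/MBq)", y = NULL) +
    ggplot2::theme_minimal()
}
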