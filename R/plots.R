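#' Plot venous saturation versus altitude under both heart-rate hypotheses
#'
#' Scatter of per-study myocardial venous O2 saturation against altitude:
#' open squares for the observed maximal heart rate, filled triangles for
#' a fixed sea-level heart rate, with a dashed line at the viability
#' floor and a dotted line at zero.
#'
#' @param rows A scenario tibble from [run_scenarios()].
#' @param params Model parameters (used for the floor annotation).
#' @return A ggplot object.
#' @export
plot_venous_saturation <- function(rows, params = model_parameters()) {
  long <- tidyr::pivot_longer(
    rows,
    cols = c("sv_actual_hr_pct", "sv_fixed_hr_pct"),
    names_to = "hypothesis", values_to = "sv_pct"
  )
  long$hypothesis <- ifelse(long$hypothesis == "sv_actual_hr_pct",
                            "observed maximal HR", "fixed sea-level HR")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$altitude_m, y = .data$sv_pct,
                                     shape = .data$hypothesis)) +
    ggplot2::geom_hline(yintercept = params$sv_min_pct, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c("observed maximal HR" = 0,
                                           "fixed sea-level HR" = 17)) +
    ggplot2::labs(x = "Altitude (m)",
                  y = expression(Myocardial~venous~SO[2]~("%")),
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot venous O2 pressure versus altitude under both heart-rate hypotheses
#'
#' Same layout as [plot_venous_saturation()] but for the venous partial
#' pressure obtained through the dissociation transform. Rows whose
#' saturation is non-positive have no defined pressure and are absent.
#'
#' @inheritParams plot_venous_saturation
#' @return A ggplot object.
#' @export
plot_venous_pressure <- function(rows, params = model_parameters()) {
  long <- tidyr::pivot_longer(
    rows,
    cols = c("pv_actual_hr_mmHg", "pv_fixed_hr_mmHg"),
    names_to = "hypothesis", values_to = "pv_mmHg"
  )
  long$hypothesis <- ifelse(long$hypothesis == "pv_actual_hr_mmHg",
                            "observed maximal HR", "fixed sea-level HR")
  long <- dplyr::filter(long, !is.na(.data$pv_mmHg))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$altitude_m, y = .data$pv_mmHg,
                                     shape = .data$hypothesis)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c("observed maximal HR" = 0,
                                           "fixed sea-level HR" = 17)) +
    ggplot2::labs(x = "Altitude (m)",
                  y = expression(Myocardial~venous~PO[2]~(mmHg)),
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the maximal-altitude curve against coronary-reserve increase
#'
#' @param sweep A tibble from [reserve_sweep()].
#' @return A ggplot object.
#' @export
plot_reserve_curve <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$delta_q_pct,
                                      y = .data$max_altitude_m)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Increase in coronary reserve (%)",
                  y = "Maximal tolerable altitude (m)") +
    ggplot2::theme_minimal()
}
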