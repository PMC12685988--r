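#' Cohort stress quartile band plot
#'
#' Median stress with IQR and min-max bands against strain, on a
#' logarithmic stress axis (the cohort spans roughly two orders of
#' magnitude at low strain).
#'
#' @param qtable Output of [stress_quartile_table()].
#' @return A ggplot object.
#' @export
plot_quartile_band <- function(qtable) {
  ggplot2::ggplot(qtable, ggplot2::aes(x = .data$strain)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                         fill = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Strain", y = "Stress (MPa, log scale)",
                  title = "Cohort stress quartiles by strain") +
    ggplot2::theme_minimal()
}

#' CS and CE distribution boxplots
#'
#' @param profiles Stiffness profiles (rows from [stiffness_profile()]).
#' @return A ggplot object, one panel per parameter family.
#' @export
plot_stiffness_box <- function(profiles) {
  pars <- grep("^C[SE][0-9]+$", names(profiles), value = TRUE)
  long <- tidyr::pivot_longer(profiles[c("nodule_id", pars)], all_of(pars),
                              names_to = "parameter", values_to = "value")
  long$family <- ifelse(grepl("^CS", long$parameter),
                        "Compression Strength (MPa)",
                        "Compression Energy (J/cm^3)")
  long$parameter <- factor(long$parameter, levels = pars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~family, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Stiffness parameter distributions") +
    ggplot2::theme_minimal()
}

#' Stiffness versus CT density scatter plots
#'
#' @param profiles Stiffness profiles keyed by `nodule_id`.
#' @param records Nodule table with `ct_hu`.
#' @param parameters Parameters to plot.
#' @return A ggplot object with one panel per parameter.
#' @export
plot_ct_scatter <- function(profiles, records,
                            parameters = c("CS10", "CS20", "CE10", "CE20")) {
  parameters <- intersect(parameters, names(profiles))
  joined <- left_join(profiles, records[c("nodule_id", "ct_hu")],
                      by = "nodule_id")
  long <- tidyr::pivot_longer(joined[c("nodule_id", "ct_hu", parameters)],
                              all_of(parameters),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long[!is.na(long$value) & !is.na(long$ct_hu), ],
                  ggplot2::aes(x = .data$ct_hu, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Mean CT number (HU)", y = "Value",
                  title = "Stiffness vs CT density") +
    ggplot2::theme_minimal()
}

#' Plot a stress-strain curve
#'
#' @param object A `crush_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crush_curve
#' @export
autoplot.crush_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$strain, y = .data$stress_mpa)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Strain", y = "Stress (MPa)",
                  title = attr(object, "nodule_id")) +
    ggplot2::theme_minimal()
}

#' Plot a raw load-displacement recording
#'
#' @param object A `crush_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crush_recording
#' @export
autoplot.crush_recording <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$displacement_mm,
                                       y = .data$load_N)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Displacement (mm)", y = "Load (N)",
                  title = attr(object, "nodule_id")) +
    ggplot2::theme_minimal()
}
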