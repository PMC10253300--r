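#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.dose_factor <- function(x) factor(signif(x, 4), levels = signif(sort(unique(x)), 4))

#' Delta heatmap of a synergy result
#'
#' Per-cell difference between the reference surface and the observed
#' viability, on the conventional diverging scale: blue = synergy (observed
#' below the model), red = antagonism. Significant cells (p < alpha) are
#' starred.
#'
#' @param object A [score_synergy()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.synergy_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  lim <- max(abs(df$delta), 1)
  ggplot2::ggplot(df, ggplot2::aes(.dose_factor(.data$conc_col),
                                   .dose_factor(.data$conc_row),
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant, "*", "")),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-lim, lim),
                                  name = "Δ viability\n(model - obs)") +
    ggplot2::labs(
      x = "column-drug concentration", y = "row-drug concentration",
      title = sprintf("%s model, %s fits: mean score %.2f (%s)",
                      toupper(attr(object, "model")), attr(object, "regime"),
                      attr(object, "mean_score"), attr(object, "classification"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Expected-viability heatmap of a reference surface
#'
#' @param object A [reference_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.reference_surface <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.dose_factor(.data$conc_col),
                                   .dose_factor(.data$conc_row),
                                   fill = .data$expected)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "expected\n% viability") +
    ggplot2::labs(x = "column-drug concentration",
                  y = "row-drug concentration",
                  title = sprintf("%s reference surface (%s fits)",
                                  toupper(attr(object, "model")),
                                  attr(object, "regime"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Concentration-response curve with data
#'
#' Observed replicate means \eqn{\pm} SD with the fitted 4PL overlaid on a
#' log-dose axis.
#'
#' @param object A [fit_hill()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hill_fit <- function(object, ...) {
  plot_fit_curves(list(object))
}

#' Overlay fitted curves from both regimes on the same data
#'
#' The side-by-side view that makes regime bias visible: points are replicate
#' means with SD error bars, lines are the fitted curves per regime.
#'
#' @param fits A list of [fit_hill()] objects on the same data (typically one
#'   per regime).
#' @return A ggplot object.
#' @export
plot_fit_curves <- function(fits) {
  stopifnot(length(fits) >= 1, all(purrr::map_lgl(fits, inherits, "hill_fit")))
  data <- fits[[1]]$data
  pts <- data |>
    dplyr::summarise(mean = mean(.data$viability),
                     sd = stats::sd(.data$viability), .by = "dose")
  grid <- exp(seq(log(min(data$dose)), log(max(data$dose)), length.out = 200))
  curves <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(regime = f$regime, dose = grid,
                   viability = predict(f, grid))
  })
  ggplot2::ggplot(pts, ggplot2::aes(.data$dose, .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$dose, .data$viability,
                                    colour = .data$regime)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "% viability", colour = "regime") +
    ggplot2::theme_minimal()
}

#' Dot panel of matrix scores per model, regime and convention
#'
#' One dot per analysed combination of reference model, fitting regime and
#' scoring convention, on the diverging blue (synergy) / red (antagonism)
#' scale.
#'
#' @param report The `report` tibble of a [run_full_analysis()] result (or a
#'   row-bound collection of them with an extra `dataset` column).
#' @param value `"normalized_score"` (default) or `"raw_score"`.
#' @return A ggplot object.
#' @export
plot_score_panel <- function(report, value = "normalized_score") {
  stopifnot(value %in% names(report))
  ggplot2::ggplot(report,
                  ggplot2::aes(interaction(.data$regime, .data$convention),
                               .data[[value]],
                               colour = .data[[value]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~model) +
    ggplot2::scale_colour_gradient2(low = "#b2182b", mid = "grey70",
                                    high = "#2166ac", guide = "none") +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
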