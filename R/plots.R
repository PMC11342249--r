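# ggplot2 displays for the main result types.

#' Plot the pair-distance distribution with band cutoffs
#'
#' Histogram of inter-centroid distances over all region pairs, with the Q1
#' and Q3 cutoffs that separate short, medium and long-range connections.
#'
#' @param object A `distance_bands` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.distance_bands <- function(object, ...) {
  q <- band_cutoffs(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$distance, fill = .data$band)) +
    ggplot2::geom_histogram(bins = 30, colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = q, linetype = "dashed") +
    ggplot2::labs(x = "inter-centroid distance (mm)", y = "region pairs",
                  fill = "band",
                  title = sprintf("Distance bands: Q1 = %.1f mm, Q3 = %.1f mm",
                                  q["q1"], q["q3"])) +
    ggplot2::theme_minimal()
}

#' Plot per-region lesion-symptom mapping results
#'
#' One point per tested region: one-tailed -log10 p against the damage-slope
#' t statistic, FDR-significant regions highlighted.
#'
#' @param object An `lsm_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lsm_result <- function(object, ...) {
  tab <- dplyr::filter(object$table, !.data$excluded)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$t, y = -log10(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$region), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "damage slope t", y = "-log10 one-tailed p",
                  colour = sprintf("FDR q <= %g", object$q_level),
                  title = sprintf("ROI lesion-symptom mapping: %s", object$measure)) +
    ggplot2::theme_minimal()
}

#' Scatterplots of residualized behaviour against the fibre ratio
#'
#' One panel per measure: standardized covariate-model residuals against the
#' long:short fibre ratio, with the least-squares line and the association
#' r / corrected p annotated, mirroring the usual presentation of
#' additional-variance results.
#'
#' @param fits Named list of `covariate_fit` objects.
#' @param profiles Tibble with `subject_id`, `long_short_ratio`.
#' @param associations Optional `association_result` for panel annotation.
#' @return A ggplot.
#' @export
plot_associations <- function(fits, profiles, associations = NULL) {
  pts <- dplyr::bind_rows(purrr::imap(fits, function(fit, nm) {
    dplyr::inner_join(fit$residuals,
                      dplyr::select(profiles, "subject_id", "long_short_ratio"),
                      by = "subject_id") |>
      dplyr::mutate(measure = nm)
  }))
  if (!is.null(associations)) {
    lab <- dplyr::mutate(
      associations,
      label = sprintf("r = %.3f, p[FDR] = %.3g", .data$r, .data$p_fdr))
    pts <- dplyr::left_join(pts, lab[c("measure", "label")], by = "measure") |>
      dplyr::mutate(measure = paste0(.data$measure, "\n", .data$label))
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$long_short_ratio,
                                    y = .data$std_resid)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "proportion of long-range fibres (long:short ratio)",
                  y = "standardized residual") +
    ggplot2::theme_minimal()
}

#' Bar chart of additional variance explained per measure
#'
#' @param associations An `association_result`.
#' @return A ggplot of delta R-squared by measure.
#' @export
plot_delta_r2 <- function(associations) {
  ggplot2::ggplot(associations,
                  ggplot2::aes(x = .data$measure, y = .data$delta_r_squared,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(Delta * R^2),
                  fill = "FDR significant",
                  title = "Additional variance explained by the long-range fibre proportion") +
    ggplot2::theme_minimal()
}
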