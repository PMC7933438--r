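#' Plot methods
#'
#' `autoplot()` methods for the main result types: curvature histograms as
#' frequency polygons with the mean marked, group comparisons as bar plots
#' with s.e.m. error bars, and zone densities as per-zone bars.
#'
#' @param object result object.
#' @param ... unused.
#' @return a ggplot.
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_step
#'   geom_vline labs theme_minimal
#' @export
#' @rdname autoplot_lvmorph
autoplot.curvature_histogram <- function(object, ...) {
  mids <- (object$breaks[-1] + object$breaks[-length(object$breaks)]) / 2
  df <- data.frame(curvature = mids, freq = object$freq)
  ggplot(df, aes(x = .data$curvature, y = .data$freq)) +
    geom_step() +
    geom_vline(xintercept = object$mean_mm, linetype = "dashed") +
    labs(x = "mean curvature (1/mm)", y = "area-weighted frequency",
         title = sprintf("apical curvature (mean %.3f 1/mm)",
                         object$mean_mm)) +
    theme_minimal()
}

#' @export
#' @rdname autoplot_lvmorph
autoplot.group_comparison <- function(object, ...) {
  s <- object$summary
  ggplot(s, aes(x = .data$group, y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.2) +
    labs(x = NULL, y = object$endpoint,
         title = sprintf("ANOVA p = %.3g", object$anova_p)) +
    theme_minimal()
}

#' @param densities a [zone_vascular_density()] tibble.
#' @export
#' @rdname autoplot_lvmorph
plot_zone_density <- function(densities, ...) {
  d <- densities[densities$zone != "whole_wall", ]
  d$zone <- factor(d$zone, levels = c("infarct", "border", "remote"))
  ggplot(d, aes(x = .data$zone, y = .data$density_pct)) +
    geom_col(fill = "grey70") +
    labs(x = NULL, y = "vascular density (% of tissue volume)") +
    theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
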