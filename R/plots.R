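#' Plot a PCoA ordination
#'
#' Scatter of samples on the first two principal coordinates, optionally
#' colored by a grouping variable, with percent variation explained on the
#' axis labels.
#'
#' @param object A `pcoa_ordination`.
#' @param groups Optional named vector (by sample id) or vector in sample
#'   order used for point color.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_ordination <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  lab <- function(i) sprintf("PCo%d (%.1f%%)", i, object$pct_explained[i])
  p <- if (is.null(groups)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$PCo1, .data$PCo2))
  } else {
    if (!is.null(names(groups))) groups <- groups[df$sample_id]
    df$group <- as.character(groups)
    ggplot2::ggplot(df, ggplot2::aes(.data$PCo1, .data$PCo2,
                                     color = .data$group))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1), y = lab(2), color = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplot of per-sample cohesion by group
#'
#' @param coh Cohesion tibble from [cohesion()] (optionally with extra
#'   cohesion tables row-bound together).
#' @param groups Named group label vector (by sample id).
#' @param which Cohesion component to plot.
#' @return A ggplot object.
#' @export
plot_cohesion <- function(coh, groups,
                          which = c("total_cohesion", "positive_cohesion",
                                    "negative_cohesion")) {
  which <- match.arg(which)
  coh$group <- as.character(groups[coh$sample_id])
  ggplot2::ggplot(coh, ggplot2::aes(.data$group, .data[[which]],
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = gsub("_", " ", which)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the environmental driver table
#'
#' Tile plot of Spearman correlations between environmental variables and
#' responses, annotated with significance stars.
#'
#' @param object A `driver_table` from [driver_correlations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.driver_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$response, .data$variable,
                                       fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of direct/indirect/total effects from a PLS-PM fit
#'
#' @param object A `plspm_fit`.
#' @param to Endogenous latent whose incoming effects are shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plspm_fit <- function(object, to = NULL, ...) {
  eff <- object$effects
  to <- to %||% utils::tail(object$model$latents, 1)
  eff <- eff[eff$to == to & (eff$direct != 0 | eff$indirect != 0), ]
  long <- tidyr::pivot_longer(eff, c("direct", "indirect", "total"),
                              names_to = "effect", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$from, .data$value,
                                     fill = .data$effect)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = paste("effect on", to), fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
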