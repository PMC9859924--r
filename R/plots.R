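#' Plot a per-cycle metric across strategies
#'
#' Line plot of one per-cycle statistic from a [run_grid()] result (or any
#' tibble shaped like its `cycles` element), averaged over runs, colored by
#' strategy and faceted by framework and parental population size.
#'
#' @param cycles The `cycles` tibble of a [run_grid()] result.
#' @param metric Column to plot, e.g. `"fixed_favorable"`,
#'   `"adjusted_fitness"`, `"hamming"`, `"relative_variance"`.
#' @param trait Optional trait filter.
#' @return A ggplot object.
#' @export
plot_cycle_metric <- function(cycles, metric = "fixed_favorable",
                              trait = NULL) {
  if (!metric %in% names(cycles)) {
    abort(paste0("no column '", metric, "' in cycles table"))
  }
  if (!is.null(trait)) cycles <- cycles[cycles$trait == trait, ]
  summ <- cycles |>
    dplyr::group_by(
      .data$trait, .data$framework, .data$strategy,
      .data$parents, .data$cycle
    ) |>
    dplyr::summarise(
      value = mean(.data[[metric]], na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(
    .data$cycle, .data$value,
    colour = .data$strategy
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$parents),
      cols = ggplot2::vars(.data$framework)
    ) +
    ggplot2::labs(x = "cycle", y = metric) +
    ggplot2::theme_minimal()
}

#' @method autoplot breeding_sim
#' @export
autoplot.breeding_sim <- function(object, metric = "adjusted_fitness", ...) {
  rec <- object$records
  ggplot2::ggplot(rec, ggplot2::aes(.data$cycle, .data[[metric]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = paste(
        object$arch$trait, object$program$name,
        object$program$framework
      ),
      x = "cycle", y = metric
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot beansim_pca
#' @export
autoplot.beansim_pca <- function(object, colour = "strategy", ...) {
  sc <- object$scores
  lo <- object$loadings
  scale_f <- max(abs(c(sc$PC1, sc$PC2))) * 0.8
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  if (colour %in% names(sc)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data[[colour]]),
      alpha = 0.6
    )
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6)
  }
  p +
    ggplot2::geom_segment(
      data = lo,
      ggplot2::aes(
        x = 0, y = 0, xend = .data$PC1 * scale_f,
        yend = .data$PC2 * scale_f
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = lo,
      ggplot2::aes(
        x = .data$PC1 * scale_f * 1.1, y = .data$PC2 * scale_f * 1.1,
        label = .data$statistic
      ),
      size = 3, colour = "grey20"
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance$proportion[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance$proportion[2])
    ) +
    ggplot2::theme_minimal()
}
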