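#' @name sitenet-plots
#' @title ggplot2 views of pipeline results
#'
#' @description `autoplot()` methods: the DiD-vs-k curve used to choose the
#' number of clusters, the cluster-profile heatmap (cluster centers in the
#' scaled covariate space), the allocation bar chart, the subsample ARI
#' distribution, and a map of a synthetic city.
NULL

#' @rdname sitenet-plots
#' @param object Result object.
#' @param ... Unused.
#' @method autoplot did_curve
#' @export
autoplot.did_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("did_predictions", "did_covariates"),
                              names_to = "characteristics", values_to = "did") %>%
    mutate(characteristics = dplyr::recode(.data$characteristics,
                                           did_predictions = "predicted concentration",
                                           did_covariates = "selected covariates"))
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$did,
                                     colour = .data$characteristics)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "number of clusters (k)",
                  y = "decrease in overall deviation (%)", colour = NULL) +
    ggplot2::ylim(0, 100) + ggplot2::theme_minimal()
}

#' @rdname sitenet-plots
#' @method autoplot cluster_solution
#' @export
autoplot.cluster_solution <- function(object, ...) {
  prof <- as_tibble(object$centers) %>%
    mutate(cluster = factor(seq_len(object$K))) %>%
    tidyr::pivot_longer(-"cluster", names_to = "variable", values_to = "mean")
  ggplot2::ggplot(prof, ggplot2::aes(.data$variable, .data$cluster,
                                     fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = "cluster", fill = "scaled mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname sitenet-plots
#' @method autoplot allocation
#' @export
autoplot.allocation <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(factor(.data$cluster), .data$new_sites)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = "cluster", y = "new monitoring sites") +
    ggplot2::theme_minimal()
}

#' @rdname sitenet-plots
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(.data$ari)) +
    ggplot2::geom_histogram(bins = 30, fill = "#4393c3") +
    ggplot2::geom_vline(xintercept = c(0.65, 0.80, 0.90), linetype = "dashed") +
    ggplot2::labs(x = "adjusted Rand index vs. full-data clustering",
                  y = "replicates") +
    ggplot2::theme_minimal()
}

#' @rdname sitenet-plots
#' @method autoplot synthetic_city
#' @export
autoplot.synthetic_city <- function(object, ...) {
  p <- ggplot2::ggplot(object$locations,
                       ggplot2::aes(.data$x, .data$y, colour = .data$role)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "role") +
    ggplot2::theme_minimal()
  if (!is.null(object$sources$lines) && nrow(object$sources$lines)) {
    p <- p + ggplot2::geom_segment(
      data = object$sources$lines,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2),
      inherit.aes = FALSE, linewidth = 0.4, colour = "grey30")
  }
  if (!is.null(object$sources$points) && nrow(object$sources$points)) {
    p <- p + ggplot2::geom_point(
      data = object$sources$points,
      ggplot2::aes(.data$x, .data$y, shape = .data$kind),
      inherit.aes = FALSE, size = 1.5, colour = "grey20")
  }
  p
}
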