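#' @importFrom ggplot2 autoplot ggplot aes
NULL

#' Plot the pooled delta-PCC distribution with its fitted cutoff
#'
#' Histogram of all defined delta-PCC entries with the fitted normal
#' density and the symmetric significance cutoffs overlaid — the standard
#' diagnostic for a pooled-normal cutoff fit.
#'
#' @param object An `mln_delta`.
#' @param cutoff Optional `mln_cutoff` (pooled_normal) to overlay.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mln_delta
#' @export
autoplot.mln_delta <- function(object, cutoff = NULL, bins = 80, ...) {
  d <- tibble(delta = as.numeric(object$delta))
  d <- d[is.finite(d$delta), , drop = FALSE]
  p <- ggplot(d, aes(x = .data$delta)) +
    ggplot2::geom_histogram(aes(y = ggplot2::after_stat(.data$density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::labs(x = expression(Delta * "PCC"), y = "Density",
                  title = sprintf("Delta-PCC distribution (%s samples)", object$group))
  if (!is.null(cutoff) && cutoff$method == "pooled_normal") {
    p <- p +
      ggplot2::stat_function(fun = stats::dnorm,
                             args = list(mean = cutoff$fitted_mean, sd = cutoff$fitted_sd),
                             colour = "red") +
      ggplot2::geom_vline(xintercept = cutoff$fitted_mean + c(-1, 1) * cutoff$cutoff_abs,
                          linetype = "dashed")
  }
  p
}

#' @rdname autoplot.mln_delta
#' @export
plot_delta_distribution <- function(object, cutoff = NULL, bins = 80) {
  autoplot.mln_delta(object, cutoff = cutoff, bins = bins)
}

#' ROC curve of a cross-validated evaluation
#'
#' @param object An `mln_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mln_eval
#' @export
autoplot.mln_eval <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Pooled out-of-fold ROC (AUC = %.4f)", object$auc))
}

#' @rdname autoplot.mln_eval
#' @export
plot_roc <- function(object) autoplot.mln_eval(object)

#' Volcano plot of the differential-expression baseline
#'
#' @param object An `mln_de`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mln_de
#' @export
autoplot.mln_de <- function(object, ...) {
  ggplot(object, aes(x = .data$log2_fc, y = -log10(.data$p_adjusted),
                     colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "blue", down = "red", not_de = "darkgreen")) +
    ggplot2::labs(x = "log2 fold change (tumor / non-tumor)",
                  y = "-log10 adjusted p", colour = NULL)
}

#' @rdname autoplot.mln_de
#' @export
plot_volcano <- function(object) autoplot.mln_de(object)

#' Tile view of the cross-cohort score matrix
#'
#' @param object An `mln_crosscancer`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mln_crosscancer
#' @export
autoplot.mln_crosscancer <- function(object, ...) {
  long <- object$matrix %>%
    dplyr::mutate(edge = edge_key(.data$mirna, .data$lncrna)) %>%
    tidyr::pivot_longer(dplyr::all_of(object$cohorts),
                        names_to = "cohort", values_to = "score")
  ggplot(long, aes(x = .data$cohort, y = .data$edge, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Significance\nscore") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}
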