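#' Plot a pooled ROC curve
#'
#' @param object A `metprior_validation` from [loocv()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metprior_validation <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("LOOCV ROC (%s), AUC = %.3f",
                                  object$ablation, object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the top-ranked candidate metabolites
#'
#' @param object A `metprior_ranking` from [prioritize()].
#' @param n Number of top candidates to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metprior_ranking <- function(object, n = 20L, ...) {
  d <- utils::head(tidy(object), n)
  d$metabolite <- factor(d$metabolite, levels = rev(d$metabolite))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$metabolite)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Steady-state probability", y = NULL,
                  title = sprintf("Top %d candidate metabolites", nrow(d))) +
    ggplot2::theme_minimal()
}

#' Plot per-class AUCs
#'
#' @param object A `metprior_classwise` from [classwise_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metprior_classwise <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$auc, y = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "AUC", y = NULL, title = "Per-class LOOCV AUC") +
    ggplot2::theme_minimal()
}

#' Plot a noise-robustness sweep
#'
#' @param sweep The tibble returned by [noise_sweep()].
#' @return A ggplot of AUC against the noise proportion.
#' @export
plot_noise_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$sigma, y = .data$auc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = expression(sigma ~ "(noise proportion)"), y = "LOOCV AUC") +
    ggplot2::theme_minimal()
}
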