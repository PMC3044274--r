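#' Plot a target-decoy ROC curve
#'
#' @param object A `psm_roc` object from [roc_and_auc()].
#' @param ... Unused.
#' @return A ggplot: FPR against TPR with the chance diagonal and the AUC in
#'   the subtitle.
#' @method autoplot psm_roc
#' @export
autoplot.psm_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.7, color = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate (decoy)",
      y = "True positive rate (target)",
      title = "Target-decoy ROC",
      subtitle = sprintf("AUC = %.4f  (%d targets, %d decoys)",
                         object$auc, object$n_target, object$n_decoy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot initial vs regularized score change
#'
#' @param object A `psm_rerank` object from [rerank_psms()].
#' @param ... Unused.
#' @return A ggplot of regularized against initial score; points below the
#'   identity line were pulled down by their graph neighborhood, points
#'   above were pulled up.
#' @method autoplot psm_rerank
#' @export
autoplot.psm_rerank <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$initial_score,
                               y = .data$regularized_score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.5, color = "#2166ac") +
    ggplot2::labs(
      x = "Initial score", y = "Regularized score",
      title = sprintf("Score regularization (lambda = %g)",
                      object$result$lambda)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a regularization-parameter sweep
#'
#' @param sweep A tibble from [lambda_sweep()].
#' @return A ggplot of AUC against lambda; the dashed line marks the AUC of
#'   the initial scores (reached in the limit lambda -> 1).
#' @export
plot_lambda_sweep <- function(sweep) {
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data$lambda, y = .data$auc)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_point(color = "#2166ac") +
    ggplot2::labs(x = "Regularization parameter lambda", y = "AUC",
                  title = "Sensitivity to the regularization parameter") +
    ggplot2::theme_minimal()
  auc0 <- attr(sweep, "auc_initial")
  if (!is.null(auc0)) {
    p <- p + ggplot2::geom_hline(yintercept = auc0, linetype = "dashed",
                                 color = "grey40")
  }
  p
}

#' Plot min-max-normalized score distributions before and after re-ranking
#'
#' @param fit A `psm_rerank` object.
#' @param is_target Logical vector labeling each PSM (see [label_psms()]).
#' @return A two-panel ggplot of the normalized initial and regularized
#'   score densities for targets and decoys. Regularization typically
#'   shrinks each group towards its mean, reducing the overlap.
#' @export
plot_score_distributions <- function(fit, is_target) {
  stopifnot(inherits(fit, "psm_rerank"),
            length(is_target) == nrow(fit$psms))
  df <- dplyr::bind_rows(
    tibble(score = minmax_normalize(fit$psms$score),
           class = ifelse(is_target, "target", "decoy"),
           stage = "initial"),
    tibble(score = minmax_normalize(fit$psms$regularized_score),
           class = ifelse(is_target, "target", "decoy"),
           stage = "regularized")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.4, color = NA) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::scale_fill_manual(values = c(target = "#2166ac", decoy = "#b2182b")) +
    ggplot2::labs(x = "Min-max normalized score", y = "Density",
                  title = "Score distributions before and after re-ranking") +
    ggplot2::theme_minimal()
}
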