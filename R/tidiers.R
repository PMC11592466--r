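#' Tidy a pipeline run
#'
#' @param x A `wmcm_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The 9-row metrics tibble (one row per classification system).
#' @export
tidy.wmcm_run <- function(x, ...) x$metrics

#' @rdname tidy.wmcm_run
#' @return For `glance()`: a one-row tibble with split sizes, the best
#'   system and its accuracy/AUC, and the seed.
#' @export
glance.wmcm_run <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$accuracy), ]
  tibble::tibble(
    n_train = nrow(x$split$train),
    n_test = nrow(x$split$test),
    n_rejected = sum(!x$rejection_log$kept),
    best_system = best$system,
    best_accuracy = best$accuracy,
    best_auc = best$auc,
    seed = x$config$seed
  )
}

#' Tidy a fitted base-learner panel
#'
#' @param x A `wmcm_ensemble` from [train_base_learners()].
#' @param weights Optional weights from [derive_weights()]; when given,
#'   their values and cross-validated accuracies are included.
#' @param ... Unused.
#' @return One row per learner: `learner`, and with `weights` supplied
#'   also `cv_accuracy` and `weight`.
#' @export
tidy.wmcm_ensemble <- function(x, weights = NULL, ...) {
  out <- tibble::tibble(learner = names(x$fits))
  if (!is.null(weights)) {
    out$cv_accuracy <- as.numeric(attr(weights, "cv_accuracy")[out$learner])
    out$weight <- as.numeric(weights[out$learner])
  }
  out
}

#' @rdname tidy.wmcm_ensemble
#' @export
glance.wmcm_ensemble <- function(x, ...) {
  tibble::tibble(n_learners = length(x$fits),
                 n_train = x$n_train,
                 n_features = length(x$columns),
                 seed = x$seed)
}

#' Plot ROC curves of a pipeline run
#'
#' @param object A `wmcm_run`.
#' @param systems Which systems to draw (default: the three ensembles).
#' @param ... Unused.
#' @return A ggplot: one ROC step curve per system with AUC in the
#'   legend, plus the chance diagonal.
#' @export
autoplot.wmcm_run <- function(object,
                              systems = c("weighted_averaging",
                                          "soft_voting", "hard_voting"),
                              ...) {
  roc <- dplyr::filter(object$roc, .data$system %in% systems)
  aucs <- dplyr::filter(object$metrics, .data$system %in% systems)
  lab <- stats::setNames(sprintf("%s (AUC %.3f)", aucs$system, aucs$auc),
                         aucs$system)
  roc$system <- lab[roc$system]
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr,
                                    colour = .data$system)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of the evaluation metrics across systems
#'
#' @param run A `wmcm_run`.
#' @param metrics Which metric columns to show.
#' @return A ggplot with one panel per metric.
#' @export
plot_metrics <- function(run, metrics = c("accuracy", "sensitivity",
                                          "specificity", "f_value")) {
  long <- tidyr::pivot_longer(run$metrics, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$system, .data$value,
                                     fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
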