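# broom-style accessors and plots for the fitted objects.

#' @export
tidy.mkl_solution <- function(x, ...) {
  tibble::tibble(
    kernel = x$problem$kernel_names %||% as.character(seq_along(x$beta)),
    weight = unname(x$beta))
}

#' @export
glance.mkl_solution <- function(x, ...) {
  tibble::tibble(objective = x$objective, lambda = x$problem$lambda,
                 n_kernels = x$problem$m, n_samples = x$problem$N)
}

#' @export
tidy.dbp_eval <- function(x, ...) {
  tibble::tibble(metric = names(x$metrics), value = as.numeric(x$metrics))
}

#' @export
glance.dbp_eval <- function(x, ...) {
  tibble::tibble(x$metrics, n = nrow(x$decisions), strategy = x$strategy,
                 seed = x$seed)
}

#' @export
tidy.dbp_model <- function(x, ...) {
  tibble::tibble(kernel = names(x$beta), weight = unname(x$beta))
}

#' @export
glance.dbp_model <- function(x, ...) {
  tibble::tibble(n_train = length(x$train_ids),
                 n_support = length(x$svm$support),
                 C = x$svm$C, lambda = x$config$lambda,
                 strategy = x$config$strategy)
}

#' ROC curve of an evaluation report
#'
#' @param object a `dbp_eval`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dbp_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = object$name,
      subtitle = sprintf("AUC = %.3f", object$metrics$AUC)) +
    ggplot2::theme_minimal()
}

#' Kernel-weight bar chart of a solved MKL problem
#'
#' @param object an `mkl_solution`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mkl_solution <- function(object, ...) {
  df <- tidy(object)
  df$kernel <- factor(df$kernel, levels = df$kernel)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kernel, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1 / nrow(df), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "kernel weight",
                  subtitle = sprintf("lambda = %g", object$problem$lambda)) +
    ggplot2::theme_minimal()
}
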