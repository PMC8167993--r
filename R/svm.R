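# Binary SVM on a precomputed kernel.
#
# The decision function is f(x) = sign(sum_i y_i alpha_i K(x, x_i) + b),
# with alpha solving the usual box-constrained dual
#   max  sum_i alpha_i - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij
#   s.t. 0 <= alpha_i <= C,  sum_i alpha_i y_i = 0.
# The dual is solved exactly with quadprog's dual active-set method, which
# is deterministic and, at the problem sizes this package targets (a few
# thousand samples at most), fast; the bias b comes from the KKT
# conditions at free support vectors, with the standard bound-interval
# midpoint fallback when no multiplier is strictly inside the box.

#' Train a binary SVM on a precomputed kernel
#'
#' @param K_train square symmetric PSD kernel matrix.
#' @param y labels in \{+1, -1\}, both classes present.
#' @param C box constraint (default 2, the tuned value for the combined
#'   kernel).
#' @return Object of class `dbp_svm` with `alpha_y` (the full-length
#'   vector of `y_i alpha_i`), `b`, `C`, support indices and training
#'   ids.
#' @export
train_svm <- function(K_train, y, C = 2) {
  if (nrow(K_train) != ncol(K_train)) stop("training kernel must be square")
  check_labels(y, nrow(K_train))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (C <= 0) stop("C must be positive")
  n <- length(y)
  K_sym <- (K_train + t(K_train)) / 2
  ev_min <- min(eigen(K_sym, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(1, max(abs(K_sym)))) {
    stop("kernel is not positive semidefinite (min eigenvalue ", ev_min,
         "); check the kernel construction")
  }
  Q <- tcrossprod(y) * K_sym
  # small relative ridge keeps the dual strictly concave when the kernel
  # is singular (duplicated samples, linear kernels, ...)
  ridge <- 1e-8 * max(1, mean(diag(Q)))
  sol <- tryCatch(
    quadprog::solve.QP(
      Dmat = Q + ridge * diag(n),
      dvec = rep(1, n),
      Amat = cbind(y, diag(n), -diag(n)),
      bvec = c(0, rep(0, n), rep(-C, n)),
      meq = 1L),
    error = function(e) stop("SVM dual QP failed: ", conditionMessage(e)))
  alpha <- pmin(pmax(sol$solution, 0), C)
  f_no_b <- drop(K_sym %*% (alpha * y))
  tol_sv <- 1e-7 * C
  free <- which(alpha > tol_sv & alpha < C - tol_sv)
  if (length(free) > 0L) {
    b <- mean(y[free] - f_no_b[free])
  } else {
    # every multiplier at a bound: the KKT conditions
    #   alpha_i = 0 -> y_i (g_i + b) >= 1,  alpha_i = C -> y_i (g_i + b) <= 1
    # leave an interval for b; take its midpoint (LIBSVM's convention)
    at_zero <- alpha <= tol_sv
    at_C <- alpha >= C - tol_sv
    b_lo <- suppressWarnings(max(c(
      (1 - f_no_b)[at_zero & y > 0], (-1 - f_no_b)[at_C & y < 0])))
    b_hi <- suppressWarnings(min(c(
      (1 - f_no_b)[at_C & y > 0], (-1 - f_no_b)[at_zero & y < 0])))
    b <- if (is.finite(b_lo) && is.finite(b_hi)) (b_lo + b_hi) / 2
         else if (is.finite(b_lo)) b_lo
         else if (is.finite(b_hi)) b_hi
         else 0
  }
  support <- which(alpha > tol_sv)
  structure(list(alpha_y = alpha * y,
                 b = b,
                 C = C,
                 support = support,
                 train_ids = rownames(K_train),
                 y = y),
            class = "dbp_svm")
}

#' @export
print.dbp_svm <- function(x, ...) {
  cat("<dbp_svm> N =", length(x$alpha_y), " support vectors =",
      length(x$support), " C =", x$C, "\n")
  invisible(x)
}

#' Decision values and labels for new samples
#'
#' `f(x) = sum_i y_i alpha_i K(x, x_i) + b`; the hard label is the sign of
#' the decision value, with `sign(0)` mapped to +1.
#'
#' @param object a trained `dbp_svm`.
#' @param K_test_train rectangular kernel, test rows by training columns
#'   (columns aligned to the training sample order).
#' @param ... unused.
#' @return Tibble with `id`, `decision` and `pred`.
#' @export
predict.dbp_svm <- function(object, K_test_train, ...) {
  if (ncol(K_test_train) != length(object$alpha_y)) {
    stop("kernel columns (", ncol(K_test_train),
         ") do not match the ", length(object$alpha_y), " training samples")
  }
  if (!is.null(object$train_ids) && !is.null(colnames(K_test_train)) &&
      !identical(colnames(K_test_train), object$train_ids)) {
    stop("kernel columns are not aligned to the training sample order")
  }
  dec <- unname(drop(K_test_train %*% object$alpha_y)) + object$b
  tibble::tibble(
    id = rownames(K_test_train) %||% as.character(seq_along(dec)),
    decision = dec,
    pred = ifelse(dec >= 0, 1L, -1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid search for the SVM cost parameter
#'
#' Stratified k-fold cross-validation accuracy over a grid of `C` values
#' on one precomputed kernel; ties are broken toward the smaller `C`.
#'
#' @param K square kernel matrix.
#' @param y labels.
#' @param C_grid candidate values (default `2^(-5:5)`).
#' @param folds fold count (default 5).
#' @param seed fold-assignment seed.
#' @return List with `best_C` and a tibble `table` of per-C accuracies.
#' @export
grid_search_C <- function(K, y, C_grid = 2^(-5:5), folds = 5L, seed = 1L) {
  if (length(C_grid) == 0L) stop("empty C grid")
  check_labels(y, nrow(K))
  fold_id <- stratified_folds(y, folds, seed)
  acc <- vapply(C_grid, function(C) {
    correct <- 0L
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      model <- train_svm(K[tr, tr, drop = FALSE], y[tr], C = C)
      pr <- predict(model, K[!tr, tr, drop = FALSE])
      correct <- correct + sum(pr$pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- which(acc == max(acc))
  best <- best[which.min(C_grid[best])]
  list(best_C = C_grid[best],
       table = tibble::tibble(C = C_grid, accuracy = acc))
}
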