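# Feature scaling and kernel construction.

#' Tuned RBF bandwidths per feature type
#'
#' The per-kernel bandwidths selected by grid search on the curated
#' benchmark (2^0 for GE, 2^-5 for MCD, 2^-1 for NMBAC, 2^-4 for PSSM-AB,
#' 2^-5 for PSSM-DWT, 2^-5 for PsePSSM). These are shipped defaults tuned
#' on that benchmark, not universal constants.
#'
#' @return Named numeric vector over the six feature types.
#' @export
default_gammas <- function() {
  c("GE" = 2^0, "MCD" = 2^-5, "NMBAC" = 2^-1,
    "PSSM-AB" = 2^-4, "PSSM-DWT" = 2^-5, "PsePSSM" = 2^-5)
}

#' Fit / apply a per-dimension min-max scaler
#'
#' Kernel bandwidth grids assume unit-scaled features, so each dimension is
#' mapped to \[0, 1\] by the training minimum and range; constant training
#' dimensions map to 0 and out-of-range test values are clipped to the
#' boundary (the scaler never sees test data).
#'
#' @param train numeric training feature matrix.
#' @return For `fit_scaler`, a list with `min` and `range`; for
#'   `apply_scaler`, the scaled matrix.
#' @export
fit_scaler <- function(train) {
  if (nrow(train) == 0L) stop("cannot fit a scaler on an empty matrix")
  mins <- apply(train, 2L, min)
  maxs <- apply(train, 2L, max)
  structure(list(min = mins, range = maxs - mins, d = ncol(train)),
            class = "dbp_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted scaler.
#' @param X matrix to transform (train or test geometry).
#' @export
apply_scaler <- function(scaler, X) {
  if (ncol(X) != scaler$d) {
    stop("scaler fitted on ", scaler$d, " dimensions, got ", ncol(X))
  }
  rng <- ifelse(scaler$range == 0, 1, scaler$range)
  out <- sweep(sweep(X, 2L, scaler$min, `-`), 2L, rng, `/`)
  out[, scaler$range == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Radial basis function kernel
#'
#' `K[i, j] = exp(-gamma * ||x_i - x_j||^2)` between the rows of two
#' feature matrices (square when both are the training matrix, rectangular
#' for test-versus-train geometry).
#'
#' @param X_rows,X_cols numeric matrices with equal column count.
#' @param gamma positive bandwidth.
#' @return Kernel matrix with the input rownames as dimnames and
#'   attributes `gamma` and `kernel`.
#' @export
rbf_kernel <- function(X_rows, X_cols = X_rows, gamma) {
  if (gamma <= 0) stop("gamma must be positive")
  if (ncol(X_rows) != ncol(X_cols)) stop("feature dimension mismatch")
  rr <- rowSums(X_rows^2)
  cc <- rowSums(X_cols^2)
  d2 <- outer(rr, cc, `+`) - 2 * tcrossprod(X_rows, X_cols)
  d2[d2 < 0] <- 0                                 # numerical guard
  K <- exp(-gamma * d2)
  if (identical(dim(X_rows), dim(X_cols)) &&
      identical(unname(X_rows), unname(X_cols))) {
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  dimnames(K) <- list(rownames(X_rows), rownames(X_cols))
  attr(K, "gamma") <- gamma
  attr(K, "kernel") <- "rbf"
  K
}

# alternative kernel functions behind the same interface; RBF is the
# shipped default, the others exist for head-to-head comparisons
linear_kernel <- function(X_rows, X_cols = X_rows, gamma = NULL) {
  K <- tcrossprod(X_rows, X_cols)
  attr(K, "kernel") <- "linear"
  K
}

polynomial_kernel <- function(X_rows, X_cols = X_rows, gamma,
                              degree = 3, coef0 = 0) {
  K <- (gamma * tcrossprod(X_rows, X_cols) + coef0)^degree
  attr(K, "kernel") <- "polynomial"
  K
}

sigmoid_kernel <- function(X_rows, X_cols = X_rows, gamma, coef0 = 0) {
  K <- tanh(gamma * tcrossprod(X_rows, X_cols) + coef0)
  attr(K, "kernel") <- "sigmoid"
  K
}

kernel_builder <- function(name) {
  switch(name,
         rbf = rbf_kernel,
         linear = linear_kernel,
         polynomial = polynomial_kernel,
         sigmoid = sigmoid_kernel,
         stop("unknown kernel function '", name, "'"))
}

#' Build the ordered kernel set from feature matrices
#'
#' One kernel per feature type, in the fixed order GE, MCD, NMBAC,
#' PSSM-AB, PSSM-DWT, PsePSSM (or the sequence-only prefix), using the
#' per-feature bandwidths. Rectangular geometry is obtained by passing
#' `features_cols` (e.g. scaled test features against scaled train
#' features).
#'
#' @param features named list of (scaled) feature matrices, identical
#'   sample ordering.
#' @param gammas named bandwidth vector covering every feature present.
#' @param features_cols optional second feature list for rectangular
#'   kernels; defaults to `features`.
#' @param kernel_fun kernel family name (default `"rbf"`).
#' @return Named list of kernel matrices, class `dbp_kernel_set`.
#' @export
build_kernel_set <- function(features, gammas = default_gammas(),
                             features_cols = features, kernel_fun = "rbf") {
  wanted <- intersect(FEATURE_ORDER, names(features))
  if (!setequal(names(features), wanted)) {
    stop("unknown feature names: ",
         paste(setdiff(names(features), FEATURE_ORDER), collapse = ", "))
  }
  missing_g <- setdiff(wanted, names(gammas))
  if (length(missing_g) > 0L) {
    stop("no bandwidth for: ", paste(missing_g, collapse = ", "))
  }
  ids <- lapply(features, rownames)
  if (length(unique(ids)) != 1L) stop("feature sample orderings differ")
  build <- kernel_builder(kernel_fun)
  ks <- lapply(wanted, function(nm) {
    K <- build(features[[nm]], features_cols[[nm]], gamma = gammas[[nm]])
    attr(K, "feature") <- nm
    K
  })
  names(ks) <- wanted
  structure(ks, class = "dbp_kernel_set")
}
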