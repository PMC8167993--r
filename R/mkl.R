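# Centered-kernel-alignment multiple kernel learning.
#
# Kernel weights beta on the probability simplex are chosen to align the
# combined centered kernel with the ideal (label) kernel y y^T, with a
# graph-Laplacian penalty that pulls the weights of mutually similar
# kernels together:
#
#   min_beta  beta' (M + lambda L) beta - 2 beta' a
#   s.t.      beta >= 0,  sum(beta) = 1
#
# where a_i = <U K_i U, y y'>_F, M_ef = <U K_e U, U K_f U>_F, U the
# centering matrix, W the kernel-kernel cosine similarities, D = diag(W 1)
# and L = D - W.

#' Center a kernel matrix
#'
#' Applies the centering projection `U K U` with
#' `U = I - (1/N) 11'`, implemented by row/column mean subtraction (the
#' projection matrix is never materialized). Centered kernels have zero
#' row and column sums; centering is idempotent.
#'
#' @param K square kernel matrix.
#' @return Centered matrix of the same shape.
#' @export
center_kernel <- function(K) {
  if (nrow(K) != ncol(K)) stop("center_kernel requires a square matrix")
  rm_ <- rowMeans(K)
  cm_ <- colMeans(K)
  K - outer(rm_, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm_) + mean(K)
}

#' Kernel alignment (cosine similarity of Gram matrices)
#'
#' `<P, Q>_F / (||P||_F ||Q||_F)`, the Frobenius cosine between two square
#' matrices of equal shape.
#'
#' @param P,Q square matrices of equal shape, neither all-zero.
#' @return Scalar in \[-1, 1\].
#' @export
kernel_alignment <- function(P, Q) {
  if (!all(dim(P) == dim(Q))) stop("alignment requires equal shapes")
  np <- sqrt(sum(P^2))
  nq <- sqrt(sum(Q^2))
  if (np == 0 || nq == 0) stop("alignment undefined for a zero matrix")
  sum(P * Q) / (np * nq)
}

#' Centered alignment between a kernel and the label kernel
#'
#' Alignment of the centered kernel `U K U` with the ideal kernel
#' `y y'` (kept uncentered, as the criterion is written; for balanced
#' labels the two conventions coincide). The Frobenius products are
#' evaluated as quadratic forms in `y`, so `y y'` is never materialized.
#'
#' @param K square kernel matrix.
#' @param y labels in \{+1, -1\}.
#' @return Scalar alignment value.
#' @export
centered_alignment <- function(K, y) {
  check_labels(y, nrow(K))
  Kc <- center_kernel(K)
  nk <- sqrt(sum(Kc^2))
  if (nk == 0) stop("kernel centers to zero; alignment undefined")
  # ||y y'||_F = y'y = N for sign labels
  drop(crossprod(y, Kc %*% y)) / (nk * length(y))
}

check_labels <- function(y, n = NULL) {
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (!is.null(n) && length(y) != n) stop("label length does not match kernel")
  invisible(y)
}

#' Assemble the MKL-CKA quadratic program
#'
#' Computes the alignment vector `a`, the centered Gram-of-Grams matrix
#' `M`, the kernel-kernel cosine similarity `W` (on the raw kernels by
#' default), its degree matrix `D` and Laplacian `L = D - W`.
#'
#' @param kernels list of square training kernels (a `dbp_kernel_set` or
#'   plain list), identical sample ordering.
#' @param y labels in \{+1, -1\}.
#' @param lambda nonnegative smoothing strength (default 0.8, the tuned
#'   value).
#' @param centered_w compute `W` from centered kernels instead of raw
#'   ones.
#' @return List of class `mkl_problem`.
#' @export
build_mkl_problem <- function(kernels, y, lambda = 0.8, centered_w = FALSE) {
  m <- length(kernels)
  if (m < 1L) stop("need at least one kernel")
  N <- nrow(kernels[[1]])
  for (K in kernels) {
    if (nrow(K) != N || ncol(K) != N) stop("kernels must be square, same N")
  }
  check_labels(y, N)
  if (lambda < 0) stop("lambda must be nonnegative")
  centered <- lapply(kernels, center_kernel)
  a <- vapply(centered, function(Kc) drop(crossprod(y, Kc %*% y)), numeric(1))
  M <- matrix(0, m, m)
  for (e in seq_len(m)) {
    for (f in e:m) {
      M[e, f] <- M[f, e] <- sum(centered[[e]] * centered[[f]])
    }
  }
  Wsrc <- if (centered_w) centered else kernels
  W <- matrix(0, m, m)
  for (e in seq_len(m)) {
    for (f in e:m) {
      W[e, f] <- W[f, e] <- kernel_alignment(Wsrc[[e]], Wsrc[[f]])
    }
  }
  D <- diag(rowSums(W), m)
  structure(list(a = a, M = M, W = W, D = D, L = D - W,
                 lambda = lambda, N = N, m = m,
                 kernel_names = names(kernels)),
            class = "mkl_problem")
}

mkl_objective <- function(problem, beta) {
  H <- problem$M + problem$lambda * problem$L
  drop(crossprod(beta, H %*% beta)) - 2 * sum(beta * problem$a)
}

#' Solve for the kernel weights
#'
#' Minimizes `beta' (M + lambda L) beta - 2 beta' a` over the probability
#' simplex with [quadprog::solve.QP()]. Both `M` and `L` are positive
#' semidefinite, so the program is convex; a relative ridge of 1e-10 on
#' the diagonal keeps the factorization of singular cases (e.g. identical
#' kernels) well posed. Tiny negative weights from floating point are
#' clipped and the vector renormalized; the reported objective is
#' evaluated on the unridged problem. The relative ridge is small enough
#' to leave the objective untouched at oracle tolerances while making
#' exactly symmetric singular problems come back numerically uniform.
#'
#' @param problem an `mkl_problem`.
#' @return List of class `mkl_solution` with `beta`, `objective` and the
#'   problem.
#' @export
solve_kernel_weights <- function(problem) {
  m <- problem$m
  H <- problem$M + problem$lambda * problem$L
  H <- (H + t(H)) / 2
  ridge <- 1e-8 * max(1, mean(diag(H)))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = 2 * (H + ridge * diag(m)),
                       dvec = 2 * problem$a,
                       Amat = cbind(rep(1, m), diag(m)),
                       bvec = c(1, rep(0, m)),
                       meq = 1L),
    error = function(e) stop("QP solver failed: ", conditionMessage(e)))
  beta <- sol$solution
  if (any(beta < -1e-9)) {
    stop("solver returned infeasible weights (min ", min(beta), ")")
  }
  beta <- pmax(beta, 0)
  beta <- beta / sum(beta)
  names(beta) <- problem$kernel_names
  structure(list(beta = beta,
                 objective = mkl_objective(problem, beta),
                 problem = problem),
            class = "mkl_solution")
}

#' @export
print.mkl_solution <- function(x, ...) {
  cat("<mkl_solution> lambda =", x$problem$lambda,
      " objective =", signif(x$objective, 6), "\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Uniform (mean-weighted) kernel weights
#'
#' The mean-weighted comparator: every kernel gets weight 1/m.
#'
#' @param kernels kernel list (only its length and names are used).
#' @return Named weight vector.
#' @export
mean_weights <- function(kernels) {
  m <- length(kernels)
  stats::setNames(rep(1 / m, m), names(kernels))
}

#' Convex combination of a kernel set
#'
#' `K* = sum_i beta_i K_i`; works for square training sets and for
#' rectangular test-by-train sets alike.
#'
#' @param kernels list of kernel matrices sharing one geometry.
#' @param beta simplex weight vector (checked to tolerance 1e-6).
#' @return Combined kernel matrix.
#' @export
combine_kernels <- function(kernels, beta) {
  if (length(kernels) != length(beta)) stop("beta length mismatch")
  if (any(beta < -1e-9) || abs(sum(beta) - 1) > 1e-6) {
    stop("beta must lie on the probability simplex")
  }
  out <- beta[[1]] * kernels[[1]]
  if (length(kernels) > 1L) {
    for (i in seq.int(2L, length(kernels))) {
      out <- out + beta[[i]] * kernels[[i]]
    }
  }
  attr(out, "beta") <- beta
  out
}

#' Kernel weights for a configured strategy
#'
#' Dispatches between the alignment solver (`"cka"`), the uniform
#' comparator (`"mean"`) and a one-hot single-kernel run
#' (`"single:<feature>"`).
#'
#' @param kernels square training kernel set.
#' @param y labels.
#' @param config a [dbp_config()].
#' @return Named weight vector on the simplex.
#' @export
kernel_weights <- function(kernels, y, config = dbp_config()) {
  strategy <- config$strategy
  if (strategy == "cka") {
    solve_kernel_weights(
      build_mkl_problem(kernels, y, lambda = config$lambda,
                        centered_w = config$centered_w))$beta
  } else if (strategy == "mean") {
    mean_weights(kernels)
  } else if (startsWith(strategy, "single:")) {
    nm <- sub("^single:", "", strategy)
    if (!nm %in% names(kernels)) stop("unknown kernel '", nm, "'")
    stats::setNames(as.numeric(names(kernels) == nm), names(kernels))
  } else {
    stop("unknown strategy '", strategy, "'")
  }
}
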