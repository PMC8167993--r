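# Centered-kernel-alignment algebra and the simplex QP.

test_that("kernel centering zeroes margins, is idempotent, and kills constants", {
  set.seed(60)
  for (i in 1:10) {
    K <- rand_kernel(12)
    Kc <- center_kernel(K)
    expect_lt(max(abs(rowSums(Kc))), 1e-8)
    expect_lt(max(abs(colSums(Kc))), 1e-8)
    expect_lt(max(abs(center_kernel(Kc) - Kc)), 1e-10)
  }
  ones <- matrix(1, 6, 6)
  expect_lt(max(abs(center_kernel(ones))), 1e-12)
  expect_error(center_kernel(matrix(1, 2, 3)), "square")
})

test_that("alignment is a cosine: self-alignment 1, scale invariant, bounded", {
  set.seed(61)
  P <- matrix(rnorm(16), 4)
  Q <- matrix(rnorm(16), 4)
  expect_equal(kernel_alignment(P, P), 1, tolerance = 1e-12)
  expect_equal(kernel_alignment(3.7 * P, Q), kernel_alignment(P, Q),
               tolerance = 1e-12)
  expect_lte(abs(kernel_alignment(P, Q)), 1 + 1e-12)
  # closed form: <I2, ones> / (sqrt(2) * 2) = 1/sqrt(2)
  expect_equal(kernel_alignment(diag(2), matrix(1, 2, 2)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(kernel_alignment(matrix(0, 3, 3), P[1:3, 1:3]), "zero")
})

test_that("centered alignment matches a dense centering-matrix oracle", {
  set.seed(62)
  y <- balanced_labels(8)
  for (i in 1:10) {
    K <- rand_kernel(8)
    expect_equal(centered_alignment(K, y), dense_centered_alignment(K, y),
                 tolerance = 1e-10)
  }
  # the label kernel itself aligns perfectly when labels are balanced
  yy <- tcrossprod(y)
  expect_equal(centered_alignment(yy, y), 1, tolerance = 1e-10)
  # an all-ones kernel centers to zero: alignment undefined
  expect_error(centered_alignment(matrix(1, 8, 8), y), "zero")
})

test_that("problem assembly reproduces dense-matrix quantities", {
  set.seed(63)
  n <- 4L
  ks <- list(A = rand_kernel(n), B = rand_kernel(n))
  y <- balanced_labels(n)
  pb <- build_mkl_problem(ks, y, lambda = 0.8)
  U <- dense_centering(n)
  cA <- U %*% ks$A %*% U
  cB <- U %*% ks$B %*% U
  yy <- tcrossprod(y)
  expect_equal(pb$a, c(A = sum(cA * yy), B = sum(cB * yy)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pb$M,
               matrix(c(sum(cA * cA), sum(cA * cB),
                        sum(cB * cA), sum(cB * cB)), 2, 2),
               tolerance = 1e-10)
  expect_equal(pb$W[1, 2], kernel_alignment(ks$A, ks$B), tolerance = 1e-12)
  expect_equal(diag(pb$W), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(rowSums(pb$L)), c(0, 0), tolerance = 1e-12)
  # M is a Gram matrix under the Frobenius inner product: PSD
  expect_gte(min(eigen(pb$M, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("identical kernels make the problem fully symmetric", {
  set.seed(64)
  K <- rand_kernel(10)
  ks <- list(k1 = K, k2 = K, k3 = K)
  y <- balanced_labels(10)
  pb <- build_mkl_problem(ks, y, lambda = 0.8)
  expect_true(all(abs(pb$M - pb$M[1, 1]) < 1e-8))
  expect_true(all(abs(pb$W - 1) < 1e-10))
  expect_equal(unname(rowSums(pb$L)), rep(0, 3), tolerance = 1e-10)
})

test_that("identical kernels receive uniform weight at any smoothing strength", {
  set.seed(65)
  K <- rand_kernel(10)
  ks <- list(k1 = K, k2 = K, k3 = K)
  y <- balanced_labels(10)
  for (lambda in c(0, 0.8, 100)) {
    sol <- solve_kernel_weights(build_mkl_problem(ks, y, lambda = lambda))
    expect_equal(unname(sol$beta), rep(1 / 3, 3), tolerance = 1e-6)
  }
})

test_that("weights are simplex-feasible and the QP is never beaten by an exhaustive grid", {
  grid <- simplex_grid3(0.02)
  for (s in 1:20) {
    set.seed(s)
    ks <- lapply(1:3, function(i) rand_kernel(30))
    names(ks) <- paste0("k", 1:3)
    y <- balanced_labels(30)
    pb <- build_mkl_problem(ks, y, lambda = 0.8)
    sol <- solve_kernel_weights(pb)
    expect_true(all(sol$beta >= 0))
    expect_equal(sum(sol$beta), 1, tolerance = 1e-8)
    H <- pb$M + pb$lambda * pb$L
    grid_objs <- rowSums((grid %*% H) * grid) - 2 * drop(grid %*% pb$a)
    expect_lte(sol$objective, min(grid_objs) + 1e-3)
    # the coarse grid may trail the continuous optimum only by its
    # discretization error
    expect_lte(min(grid_objs) - sol$objective, 0.01)
  }
})

test_that("Laplacian smoothing drives weights toward uniform monotonically", {
  for (s in 1:5) {
    set.seed(100 + s)
    ks <- lapply(1:4, function(i) rand_kernel(20))
    names(ks) <- paste0("k", 1:4)
    y <- balanced_labels(20)
    vars <- sapply(c(0, 0.8, 10, 100, 1e6), function(lambda) {
      sol <- solve_kernel_weights(build_mkl_problem(ks, y, lambda = lambda))
      var(sol$beta)
    })
    expect_true(all(diff(vars) <= 1e-10))
    sol_inf <- solve_kernel_weights(build_mkl_problem(ks, y, lambda = 1e6))
    expect_lt(max(abs(sol_inf$beta - 1 / 4)), 0.01)
  }
})

test_that("a label-informative kernel outweighs pure-noise kernels", {
  sig <- make_fixture_dataset(30, 30, c(60, 90), 0.8, seed = 7)
  noise1 <- make_fixture_dataset(30, 30, c(60, 90), 0.0, seed = 8)
  noise2 <- make_fixture_dataset(30, 30, c(60, 90), 0.0, seed = 9)
  y <- sig$records$label
  cfg <- dbp_config(sequence_only = TRUE)
  mk <- function(ds) {
    X <- extract_features(ds, cfg)$GE
    rownames(X) <- sig$records$id
    Xs <- apply_scaler(fit_scaler(X), X)
    # median-heuristic bandwidth keeps the kernel informative regardless
    # of the descriptor's dimensionality
    rbf_kernel(Xs, gamma = 1 / stats::median(dist(Xs)^2))
  }
  ks <- list(informative = mk(sig), noise_a = mk(noise1),
             noise_b = mk(noise2))
  sol <- solve_kernel_weights(build_mkl_problem(ks, y, lambda = 0.8))
  expect_gt(sol$beta[["informative"]],
            max(sol$beta[["noise_a"]], sol$beta[["noise_b"]]))
})

test_that("kernel combination honors the simplex and degenerate weights", {
  set.seed(66)
  ks <- lapply(1:3, function(i) rand_kernel(8))
  names(ks) <- paste0("k", 1:3)
  expect_equal(combine_kernels(ks, c(0, 1, 0)), ks$k2, ignore_attr = TRUE)
  K <- combine_kernels(ks, rep(1 / 3, 3))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  same <- list(a = ks$k1, b = ks$k1)
  expect_equal(combine_kernels(same, c(0.5, 0.5)), ks$k1,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(combine_kernels(ks, c(0.5, 0.5)), "mismatch")
  expect_error(combine_kernels(ks, c(0.7, 0.2, 0.2)), "simplex")
})

test_that("weighting strategies dispatch correctly", {
  set.seed(67)
  ks <- lapply(1:3, function(i) rand_kernel(10))
  names(ks) <- c("GE", "MCD", "NMBAC")
  y <- balanced_labels(10)
  expect_equal(unname(kernel_weights(ks, y, dbp_config(strategy = "mean"))),
               rep(1 / 3, 3))
  one_hot <- kernel_weights(ks, y, dbp_config(strategy = "single:MCD"))
  expect_equal(unname(one_hot), c(0, 1, 0))
  expect_error(kernel_weights(ks, y, dbp_config(strategy = "single:XX")),
               "unknown kernel")
  beta <- kernel_weights(ks, y, dbp_config(strategy = "cka"))
  expect_equal(sum(beta), 1, tolerance = 1e-8)
})

test_that("tidy and glance expose weights and objective", {
  set.seed(68)
  ks <- lapply(1:3, function(i) rand_kernel(10))
  names(ks) <- c("GE", "MCD", "NMBAC")
  sol <- solve_kernel_weights(
    build_mkl_problem(ks, balanced_labels(10), lambda = 0.8))
  td <- tidy(sol)
  expect_equal(td$kernel, c("GE", "MCD", "NMBAC"))
  expect_equal(sum(td$weight), 1, tolerance = 1e-8)
  gl <- glance(sol)
  expect_equal(gl$lambda, 0.8)
  expect_equal(gl$n_kernels, 3L)
})
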