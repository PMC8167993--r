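# Shared fixture builders. All randomness is driven by an explicit
# set.seed() in the calling test.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(L) paste(sample(AA20, L, replace = TRUE), collapse = "")

rand_pssm <- function(L) {
  m <- matrix(sample(-10:10, L * 20L, replace = TRUE), nrow = L)
  colnames(m) <- AA20
  m
}

# random strictly-PSD kernel from random features
rand_kernel <- function(n, d = 5L, gamma = 0.5) {
  X <- matrix(runif(n * d), nrow = n)
  rownames(X) <- sprintf("s%03d", seq_len(n))
  rbf_kernel(X, gamma = gamma)
}

balanced_labels <- function(n) rep(c(1L, -1L), length.out = n)

# matrix values only, all attributes dropped
bare <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# every beta on the m = 3 probability simplex with the given step
simplex_grid3 <- function(step = 0.02) {
  k <- round(1 / step)
  out <- list()
  for (i in 0:k) {
    for (j in 0:(k - i)) {
      out[[length(out) + 1L]] <- c(i, j, k - i - j) / k
    }
  }
  do.call(rbind, out)
}

# independent dense-matrix evaluation of the alignment quantities, used
# as the oracle against the quadratic-form implementation
dense_centering <- function(n) diag(n) - matrix(1 / n, n, n)

dense_centered_alignment <- function(K, y) {
  U <- dense_centering(nrow(K))
  Kc <- U %*% K %*% U
  yy <- tcrossprod(y)
  sum(Kc * yy) / (sqrt(sum(Kc^2)) * sqrt(sum(yy^2)))
}
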