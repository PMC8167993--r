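# PSSM-derived descriptors: PsePSSM, average blocks, wavelet statistics.

#' Column-standardize a PSSM profile
#'
#' Each of the 20 columns is centered and scaled over the L positions with
#' the population (divide-by-L) standard deviation; constant columns map
#' to all zeros.
#'
#' @param profile `L x 20` numeric matrix (alphabetical column order).
#' @return Matrix of the same shape.
#' @export
normalize_pssm <- function(profile) {
  if (nrow(profile) < 2L) stop("profile must have at least 2 positions")
  out <- apply(profile, 2L, function(v) {
    s <- pop_sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  colnames(out) <- colnames(profile)
  out
}

#' Pseudo-PSSM descriptor (PsePSSM)
#'
#' Operates on the column-standardized profile: the first 20 entries are
#' the column means; then for each lag t = 1..`lag_max` the 20 mean squared
#' differences `(1/(L-t)) * sum_i (m[i,j] - m[i+t,j])^2`, emitted in
#' lag-major blocks of 20.
#'
#' @param profile `L x 20` PSSM matrix (raw; standardized internally).
#' @param lag_max maximum lag (default 10, the tuned value).
#' @return Numeric vector of length `20 + 20 * lag_max` (220 at default).
#' @export
encode_psepssm <- function(profile, lag_max = 10L) {
  L <- nrow(profile)
  if (L <= lag_max) {
    stop("profile length ", L, " must exceed lag_max = ", lag_max)
  }
  m <- normalize_pssm(profile)
  out <- colMeans(m)
  for (t in seq_len(lag_max)) {
    d <- m[seq_len(L - t), , drop = FALSE] -
      m[seq.int(t + 1L, L), , drop = FALSE]
    out <- c(out, colSums(d^2) / (L - t))
  }
  unname(out)
}

#' PSSM average-blocks descriptor (PSSM-AB)
#'
#' Rows are partitioned into `n_blocks` contiguous blocks (leading blocks
#' absorb the remainder) and each block contributes its 20 column means,
#' block-major.
#'
#' @param profile `L x 20` PSSM matrix.
#' @param n_blocks number of blocks (default 20, giving 400 values).
#' @return Numeric vector of length `20 * n_blocks`.
#' @export
encode_pssm_ab <- function(profile, n_blocks = 20L) {
  L <- nrow(profile)
  if (L < n_blocks) {
    stop("profile length ", L, " is shorter than n_blocks = ", n_blocks)
  }
  blocks <- partition_indices(L, n_blocks)
  unlist(lapply(blocks, function(idx) {
    colMeans(profile[idx, , drop = FALSE])
  }), use.names = FALSE)
}

#' PSSM wavelet-statistics descriptor (PSSM-DWT)
#'
#' Each of the 20 profile columns undergoes a `levels`-deep discrete
#' wavelet decomposition ([dwt_multilevel()]); the approximation
#' coefficients at every level contribute their maximum, minimum, mean and
#' standard deviation. Ordering is column-major, level inner, statistic
#' innermost: for column j, (max, min, mean, sd) at level 1, then level 2,
#' etc. Default d = 20 x 4 x 4 = 320.
#'
#' @param profile `L x 20` PSSM matrix.
#' @param wavelet wavelet name (default `"db4"`).
#' @param levels decomposition depth (default 4).
#' @return Numeric vector of length `20 * levels * 4`.
#' @export
encode_pssm_dwt <- function(profile, wavelet = "db4", levels = 4L) {
  unlist(lapply(seq_len(ncol(profile)), function(j) {
    dec <- dwt_multilevel(profile[, j], wavelet = wavelet, levels = levels)
    unlist(lapply(dec$approx, function(a) {
      c(max(a), min(a), mean(a), pop_sd(a))
    }))
  }), use.names = FALSE)
}
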