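# One-dimensional discrete wavelet transform (pyramid algorithm) with
# half-point symmetric boundary extension. Orthonormal Daubechies filters;
# output matches the conventional symmetric-mode decimated DWT.

DB_FILTERS <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
)

wavelet_filter <- function(wavelet) {
  f <- DB_FILTERS[[wavelet]]
  if (is.null(f)) {
    stop("unsupported wavelet '", wavelet, "'; available: ",
         paste(names(DB_FILTERS), collapse = ", "))
  }
  f
}

# single decimated analysis step; returns approximation and detail
dwt_step <- function(x, lo) {
  n <- length(x)
  flen <- length(lo)
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1L)   # quadrature mirror filter
  pad <- c(rev(x[seq_len(flen - 1L)]), x,
           rev(x[seq.int(n - flen + 2L, n)]))
  out_len <- (n + flen - 1L) %/% 2L
  idx <- seq.int(flen + 1L, by = 2L, length.out = out_len)
  ca <- stats::convolve(pad, rev(lo), type = "open")[idx]
  cd <- stats::convolve(pad, rev(hi), type = "open")[idx]
  list(approx = ca, detail = cd)
}

#' Multi-level discrete wavelet decomposition
#'
#' Decimated DWT with half-point symmetric boundary extension, iterated on
#' the approximation band.
#'
#' @param x numeric signal.
#' @param wavelet filter name (`"db4"` default; also `"db1"`, `"db2"`).
#' @param levels decomposition depth.
#' @return List with `approx` and `detail`, each a list of `levels`
#'   coefficient vectors (level 1 first).
#' @export
dwt_multilevel <- function(x, wavelet = "db4", levels = 4L) {
  lo <- wavelet_filter(wavelet)
  min_len <- length(lo)
  approx <- detail <- vector("list", levels)
  a <- as.numeric(x)
  for (lev in seq_len(levels)) {
    if (length(a) < min_len) {
      stop("signal too short for ", levels, "-level '", wavelet,
           "' decomposition; need length >= ",
           min_len * 2L^(levels - 1L), " at the top level")
    }
    st <- dwt_step(a, lo)
    approx[[lev]] <- st$approx
    detail[[lev]] <- st$detail
    a <- st$approx
  }
  list(approx = approx, detail = detail)
}
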