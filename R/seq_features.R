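# Profile-free sequence descriptors: GE, MCD, NMBAC.

# 6-class physicochemical grouping used by the global-encoding descriptor
GE_CLASSES <- list(c("A", "V", "L", "I", "M", "C"),
                   c("F", "W", "Y", "H"),
                   c("S", "T", "N", "Q"),
                   c("K", "R"),
                   c("D", "E"),
                   c("G", "P"))

# 7-class grouping used by the multi-scale CTD descriptor
MCD_CLASSES <- list(c("A", "G", "V"),
                    c("I", "L", "F", "P"),
                    c("Y", "M", "T", "S"),
                    c("H", "N", "Q", "W"),
                    c("R", "K"),
                    c("D", "E"),
                    c("C"))

class_map <- function(classes) {
  m <- integer(0)
  for (k in seq_along(classes)) m[classes[[k]]] <- k
  m
}

seq_chars <- function(x) {
  if (is.list(x) || is.data.frame(x)) x <- x$sequence
  strsplit(x, "")[[1]]
}

# split 1..L into k contiguous chunks, leading chunks absorb the remainder
partition_indices <- function(L, k) {
  base <- L %/% k
  extra <- L %% k
  lens <- base + (seq_len(k) <= extra)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  lapply(seq_len(k), function(i) seq.int(starts[i], ends[i]))
}

# composition + unordered-pair transition frequencies for a class-index
# vector over n_classes classes
comp_trans <- function(cl, n_classes) {
  len <- length(cl)
  comp <- tabulate(cl, nbins = n_classes) / len
  pairs <- which(upper.tri(matrix(0, n_classes, n_classes)), arr.ind = TRUE)
  trans <- numeric(nrow(pairs))
  if (len > 1L) {
    a <- cl[-len]; b <- cl[-1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- lo != hi
    if (any(keep)) {
      idx <- (hi[keep] - 1L) * n_classes + lo[keep]
      key <- (pairs[, 2L] - 1L) * n_classes + pairs[, 1L]
      counts <- table(factor(idx, levels = key))
      trans <- as.numeric(counts) / (len - 1L)
    }
  }
  c(comp, trans)
}

# distribution descriptor: for each class, the relative positions of its
# 1st, 25%, 50%, 75% and last occurrence (0s when the class is absent)
distribution_desc <- function(cl, n_classes) {
  len <- length(cl)
  out <- numeric(5L * n_classes)
  for (k in seq_len(n_classes)) {
    pos <- which(cl == k)
    if (length(pos) > 0L) {
      n_k <- length(pos)
      picks <- c(1L, ceiling(0.25 * n_k), ceiling(0.5 * n_k),
                 ceiling(0.75 * n_k), n_k)
      out[(k - 1L) * 5L + 1:5] <- pos[picks] / len
    }
  }
  out
}

#' Global-encoding descriptor (GE)
#'
#' Residues are mapped to 6 physicochemical classes; the sequence is then
#' partitioned by successive halving into 1 + 2 + 4 + 8 = 15 segments
#' (levels 0--3, leading segments absorbing remainders), and each segment
#' contributes its 6 class-composition frequencies plus the 15
#' unordered-pair class-transition frequencies, for 15 x 21 = 315 values.
#'
#' @param record a record tibble row/list with `$sequence`, or a plain
#'   sequence string.
#' @return Numeric vector of length 315.
#' @export
encode_ge <- function(record) {
  chars <- seq_chars(record)
  if (length(chars) < 50L) stop("GE requires sequences of at least 50 residues")
  cl <- unname(class_map(GE_CLASSES)[chars])
  if (anyNA(cl)) stop("non-canonical residue in sequence")
  segs <- unlist(lapply(0:3, function(level) {
    partition_indices(length(cl), 2L^level)
  }), recursive = FALSE)
  unlist(lapply(segs, function(idx) comp_trans(cl[idx], 6L)))
}

# fixed region list for the multi-scale descriptor: the 10 contiguous runs
# of quarters plus 4 discontinuous unions
mcd_regions <- function(L) {
  q <- partition_indices(L, 4L)
  list(Q1    = q[[1]],
       Q2    = q[[2]],
       Q3    = q[[3]],
       Q4    = q[[4]],
       Q12   = c(q[[1]], q[[2]]),
       Q23   = c(q[[2]], q[[3]]),
       Q34   = c(q[[3]], q[[4]]),
       Q123  = c(q[[1]], q[[2]], q[[3]]),
       Q234  = c(q[[2]], q[[3]], q[[4]]),
       Q1234 = c(q[[1]], q[[2]], q[[3]], q[[4]]),
       Q13   = c(q[[1]], q[[3]]),
       Q24   = c(q[[2]], q[[4]]),
       Q14   = c(q[[1]], q[[4]]),
       Q124  = c(q[[1]], q[[2]], q[[4]]))
}

#' Multi-scale continuous and discontinuous descriptor (MCD)
#'
#' Residues are mapped to 7 classes and the sequence is cut into four
#' near-equal quarters. Fourteen regions -- every contiguous run of
#' quarters plus the discontinuous unions Q1+Q3, Q2+Q4, Q1+Q4 and
#' Q1+Q2+Q4 -- each contribute the standard
#' composition/transition/distribution triple (7 + 21 + 35 = 63 values),
#' for a 14 x 63 = 882-dimensional vector. Discontinuous regions are
#' treated as the concatenation of their quarters, so one artificial
#' junction pair enters their transition counts.
#'
#' @inheritParams encode_ge
#' @return Numeric vector of length 882.
#' @export
encode_mcd <- function(record) {
  chars <- seq_chars(record)
  if (length(chars) < 50L) stop("MCD requires sequences of at least 50 residues")
  cl <- unname(class_map(MCD_CLASSES)[chars])
  if (anyNA(cl)) stop("non-canonical residue in sequence")
  regions <- mcd_regions(length(cl))
  unlist(lapply(regions, function(idx) {
    sub <- cl[idx]
    c(comp_trans(sub, 7L), distribution_desc(sub, 7L))
  }), use.names = FALSE)
}

#' Normalized Moreau-Broto autocorrelation (NMBAC)
#'
#' For each of 6 standardized physicochemical properties and each lag
#' d = 1..`lg_max`, the average product of property values `d` residues
#' apart: `(1/(L-d)) * sum_i P_j(s_i) P_j(s_{i+d})`. Output is
#' property-major: all lags of property 1, then property 2, etc.
#'
#' @inheritParams encode_ge
#' @param table standardized 6 x 20 property matrix from
#'   [aa_property_table()].
#' @param lg_max maximum lag (default 30, the tuned value); sequence must
#'   be strictly longer than this.
#' @return Numeric vector of length `6 * lg_max`.
#' @export
encode_nmbac <- function(record, table = aa_property_table(), lg_max = 30L) {
  chars <- seq_chars(record)
  L <- length(chars)
  if (L <= lg_max) {
    stop("sequence length ", L, " must exceed lg_max = ", lg_max,
         "; lower lg_max")
  }
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) stop("non-canonical residue in sequence")
  out <- numeric(nrow(table) * lg_max)
  for (j in seq_len(nrow(table))) {
    p <- table[j, idx]
    for (d in seq_len(lg_max)) {
      out[(j - 1L) * lg_max + d] <-
        sum(p[seq_len(L - d)] * p[seq.int(d + 1L, L)]) / (L - d)
    }
  }
  out
}
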