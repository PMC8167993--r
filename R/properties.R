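#' Physicochemical property table for the 20 canonical residues
#'
#' Six per-residue scales used by the autocorrelation descriptor:
#' hydrophobicity (Eisenberg), hydrophilicity (Hopp--Woods), side-chain
#' volume, polarity (Grantham), polarizability, and normalized
#' solvent-accessible surface area. The raw values ship with the package;
#' [standardize_properties()] centers and scales each property over the 20
#' residues before any autocorrelation is computed.
#'
#' @param standardized logical; return the standardized table (default) or
#'   the raw values.
#' @return A 6 x 20 numeric matrix, properties in rows, residues (in
#'   alphabetical one-letter order) in columns.
#' @export
#' @examples
#' tab <- aa_property_table()
#' rowMeans(tab)  # ~0 for every property
aa_property_table <- function(standardized = TRUE) {
  path <- system.file("extdata", "aa_properties.tsv", package = "dbpmkl",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(setequal(df$residue, AA_ALPHABET))
  raw <- t(as.matrix(df[match(AA_ALPHABET, df$residue), -1, drop = FALSE]))
  colnames(raw) <- AA_ALPHABET
  if (standardized) standardize_properties(raw) else raw
}

#' Standardize residue property scales
#'
#' Each property (row) is centered to mean 0 and scaled to standard
#' deviation 1 over the 20 residues, using the population (divide-by-n)
#' convention shared by all encoders in this package.
#'
#' @param raw numeric matrix, properties in rows, one column per canonical
#'   residue (all 20 must be present).
#' @return Matrix of the same shape with standardized rows.
#' @export
standardize_properties <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 20L || !setequal(colnames(raw), AA_ALPHABET)) {
    stop("property table must have one column per canonical residue")
  }
  raw <- raw[, AA_ALPHABET, drop = FALSE]
  out <- t(apply(raw, 1L, function(v) {
    s <- pop_sd(v)
    if (s == 0) stop("zero-variance property row cannot be standardized")
    (v - mean(v)) / s
  }))
  colnames(out) <- AA_ALPHABET
  out
}

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
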