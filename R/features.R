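#' Names of the feature types computed for a run
#'
#' @param sequence_only if TRUE only the three profile-free descriptors.
#' @return Character vector in the fixed package order.
#' @export
feature_names <- function(sequence_only = FALSE) {
  if (sequence_only) FEATURE_ORDER[1:3] else FEATURE_ORDER
}

#' Encode a dataset into the per-feature sample matrices
#'
#' Runs the configured encoders over every record and stacks the vectors
#' into one `N x d` matrix per feature type, rows named by record id.
#' Encoding is strictly per-record, so feature extraction can safely
#' happen once before cross-validation: no information flows between
#' samples at this stage.
#'
#' @param dataset a `dbp_dataset`; profiles are required unless
#'   `config$sequence_only`.
#' @param config a [dbp_config()] list.
#' @return Named list of numeric matrices in the fixed feature order.
#' @export
extract_features <- function(dataset, config = dbp_config()) {
  records <- dataset$records
  wanted <- feature_names(config$sequence_only)
  if (!config$sequence_only && is.null(dataset$profiles)) {
    stop("dataset has no PSSM profiles; use a sequence-only config")
  }
  tab <- aa_property_table()
  enc_one <- function(name, i) {
    seqi <- records$sequence[i]
    prof <- if (!config$sequence_only) dataset$profiles[[records$id[i]]]
    switch(name,
      "GE"       = encode_ge(seqi),
      "MCD"      = encode_mcd(seqi),
      "NMBAC"    = encode_nmbac(seqi, tab, lg_max = config$lg_max),
      "PSSM-AB"  = encode_pssm_ab(prof, n_blocks = config$n_blocks),
      "PSSM-DWT" = encode_pssm_dwt(prof, wavelet = config$wavelet,
                                   levels = config$levels),
      "PsePSSM"  = encode_psepssm(prof, lag_max = config$lag_max),
      stop("unknown feature ", name))
  }
  out <- lapply(wanted, function(name) {
    m <- t(vapply(seq_len(nrow(records)), function(i) enc_one(name, i),
                  numeric(length(enc_one(name, 1L)))))
    rownames(m) <- records$id
    if (any(!is.finite(m))) stop("non-finite values in feature ", name)
    m
  })
  names(out) <- wanted
  out
}

#' Write / read a feature matrix as TSV
#'
#' @param X numeric matrix with sample ids as rownames.
#' @param path file path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_feature_tsv <- function(X, path) {
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  colnames(df) <- c("sample_id", sprintf("f_%04d", seq_len(ncol(X))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}
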