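#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning the tibble
#' of records the rest of the package consumes. Sequences are upper-cased;
#' record order is preserved; duplicate identifiers and empty sequences are
#' errors.
#'
#' @param path FASTA file.
#' @return A tibble with columns `id`, `sequence` and `label` (`NA` until
#'   labels are attached).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(aas))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  empty <- !nzchar(seqs) | !nzchar(ids) | is.na(ids)
  if (any(empty)) {
    stop("malformed FASTA entry (empty id or sequence) at record ",
         which(empty)[1L])
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs),
                 label = NA_integer_)
}

#' Write records to FASTA
#'
#' @param records tibble with `id` and `sequence` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Apply the benchmark dataset filters
#'
#' Drops every record shorter than `min_length` residues and every record
#' containing a character outside the 20 canonical amino acids. The
#' benchmark curation rule names only 'X'; this filter generalizes to any
#' non-canonical letter ('B', 'Z', 'U', 'O', '*', ...) because the
#' downstream property tables and class groupings are defined only for the
#' canonical 20.
#'
#' @param records tibble of protein records.
#' @param min_length minimum retained sequence length (default 50).
#' @return The retained rows, original order preserved.
#' @export
filter_records <- function(records, min_length = 50L) {
  if (nrow(records) == 0L) return(records)
  ok_len <- nchar(records$sequence) >= min_length
  ok_chr <- !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                   records$sequence)
  records[ok_len & ok_chr, , drop = FALSE]
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the `-out_ascii_pssm` dialect: a banner, a header row of residue
#' letters, then one row per position holding the position index, the query
#' residue, 20 log-odds integers and 20 weighted-percentage columns. Only
#' the 20 log-odds columns are kept; they are re-mapped from the file's own
#' header order to the package's fixed alphabetical column order.
#'
#' @param path PSSM file.
#' @return An `L x 20` numeric matrix with residue columns in alphabetical
#'   order, attributes `id` (file stem) and `sequence` (column-2 residues).
#' @export
read_pssm_ascii <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^\\s*(?:[A-Z]\\s+){19}[A-Z]", lines, perl = TRUE)
  if (length(hdr) == 0L) stop("no PSSM residue header found in ", path)
  hdr <- hdr[1L]
  hdr_letters <- strsplit(trimws(lines[hdr]), "\\s+")[[1]]
  file_order <- hdr_letters[seq_len(20L)]
  if (!setequal(file_order, AA_ALPHABET)) {
    stop("PSSM header does not list the 20 canonical residues in ", path)
  }
  rows <- list()
  seq_chars <- character()
  for (i in seq(hdr + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break                      # footer starts
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) < 2L || !grepl("^[0-9]+$", fields[1L])) break
    num <- suppressWarnings(as.numeric(fields[-(1:2)]))
    if (anyNA(num) || !(length(num) %in% c(40L, 42L))) {
      stop("PSSM row with unexpected field count at line ", i, " of ", path)
    }
    rows[[length(rows) + 1L]] <- num[seq_len(20L)]
    seq_chars <- c(seq_chars, fields[2L])
  }
  if (length(rows) == 0L) stop("PSSM file has no score rows: ", path)
  mat <- do.call(rbind, rows)
  colnames(mat) <- file_order
  mat <- mat[, AA_ALPHABET, drop = FALSE]
  attr(mat, "id") <- sub("\\.[^.]*$", "", basename(path))
  attr(mat, "sequence") <- paste(seq_chars, collapse = "")
  mat
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Inverse of [read_pssm_ascii()] up to the ignored percentage columns,
#' which are written as zeros. Columns are emitted in PSI-BLAST order.
#'
#' @param matrix `L x 20` numeric matrix, alphabetical column order.
#' @param sequence residue string of length `L` for column 2.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(matrix, sequence, path) {
  stopifnot(ncol(matrix) == 20L, nchar(sequence) == nrow(matrix))
  m <- matrix[, PSIBLAST_ORDER, drop = FALSE]
  res <- strsplit(sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ", paste(sprintf("%3s", PSIBLAST_ORDER), collapse = " "),
                      " ", paste(sprintf("%3s", PSIBLAST_ORDER), collapse = " "))),
             con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", round(m[i, ])), collapse = " "),
                      " ",
                      paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
                      "  0.00 0.00"),
               con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path TSV with columns `id` and `label` (+1 / -1).
#' @return tibble with integer labels.
#' @export
read_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label") %in% names(df)))
  if (!all(df$label %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  tibble::tibble(id = as.character(df$id), label = as.integer(df$label))
}

#' Assemble a dataset from records and optional profiles
#'
#' @param records tibble with `id`, `sequence`, `label` columns.
#' @param profiles named list of PSSM matrices keyed by record id, or NULL
#'   for sequence-only data.
#' @param name dataset label used in reports.
#' @return An object of class `dbp_dataset`.
#' @export
dbp_dataset <- function(records, profiles = NULL, name = "dataset") {
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  if (!is.null(profiles)) {
    missing <- setdiff(records$id, names(profiles))
    if (length(missing) > 0L) {
      stop("missing PSSM profiles for: ", paste(missing, collapse = ", "))
    }
    profiles <- profiles[records$id]
    len_ok <- vapply(records$id, function(i) {
      nrow(profiles[[i]]) == nchar(records$sequence[records$id == i])
    }, logical(1))
    if (!all(len_ok)) {
      stop("profile length mismatch for: ",
           paste(records$id[!len_ok], collapse = ", "))
    }
  }
  structure(list(records = records, profiles = profiles, name = name),
            class = "dbp_dataset")
}

#' @export
print.dbp_dataset <- function(x, ...) {
  lab <- x$records$label
  cat("<dbp_dataset> ", x$name, ": ", nrow(x$records), " records (",
      sum(lab == 1L, na.rm = TRUE), " positive / ",
      sum(lab == -1L, na.rm = TRUE), " negative), profiles: ",
      if (is.null(x$profiles)) "none" else length(x$profiles), "\n", sep = "")
  invisible(x)
}

#' Write a dataset as FASTA + labels TSV + one PSSM file per record
#'
#' @param dataset a `dbp_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$records, file.path(dir, "sequences.fasta"))
  write.table(dataset$records[, c("id", "label")],
              file.path(dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$profiles)) {
    pdir <- file.path(dir, "pssm")
    dir.create(pdir, showWarnings = FALSE)
    for (i in seq_len(nrow(dataset$records))) {
      id <- dataset$records$id[i]
      write_pssm_ascii(dataset$profiles[[id]], dataset$records$sequence[i],
                       file.path(pdir, paste0(id, ".pssm")))
    }
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory with `sequences.fasta`, optional `labels.tsv` and
#'   optional `pssm/` subdirectory.
#' @param name dataset label.
#' @return A `dbp_dataset`.
#' @export
read_dataset <- function(dir, name = basename(dir)) {
  records <- read_fasta(file.path(dir, "sequences.fasta"))
  lab_path <- file.path(dir, "labels.tsv")
  if (file.exists(lab_path)) {
    labs <- read_labels(lab_path)
    records$label <- labs$label[match(records$id, labs$id)]
  }
  pdir <- file.path(dir, "pssm")
  profiles <- NULL
  if (dir.exists(pdir)) {
    files <- list.files(pdir, pattern = "\\.pssm$", full.names = TRUE)
    profiles <- lapply(files, read_pssm_ascii)
    names(profiles) <- sub("\\.pssm$", "", basename(files))
  }
  dbp_dataset(records, profiles, name = name)
}
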