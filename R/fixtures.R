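#' Generate a synthetic benchmark dataset
#'
#' Emulates the shape of the curated DNA-binding benchmark sets so the full
#' pipeline can run offline: FASTA-clean sequences of at least 50 residues
#' over the canonical alphabet, one synthetic PSSM profile per record, and
#' balanced +1/-1 labels. Class signal is injected twice, controlled by one
#' knob: positives and negatives draw residues from compositions tilted in
#' opposite directions proportionally to `signal_strength`, and each
#' record's PSSM columns receive a class-conditional mean shift with
#' integer-rounded Gaussian noise clipped to the log-odds-like range
#' -10..10. At `signal_strength = 0` both classes are i.i.d. from the
#' same distribution, giving a null dataset.
#'
#' @param n_pos,n_neg number of positive / negative records (>= 1).
#' @param length_range integer pair; sequence lengths drawn uniformly from
#'   this range (minimum 50, matching [filter_records()]).
#' @param signal_strength real in \[0, 1\]; 0 = no class signal.
#' @param seed integer seed; the result is a pure function of the
#'   arguments.
#' @return A `dbp_dataset` with profiles and labels.
#' @export
#' @examples
#' d <- make_fixture_dataset(5, 5, c(60, 80), 0.8, seed = 1)
#' d
make_fixture_dataset <- function(n_pos, n_neg, length_range = c(60L, 120L),
                                 signal_strength = 0.8, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            signal_strength >= 0, signal_strength <= 1)
  if (min(length_range) < 50L) {
    stop("fixture lengths must be >= 50 to pass the dataset filters")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))

  # opposite composition tilts: half the residues up, half down
  tilt <- rep(c(0.5, -0.5), length.out = 20L)
  p_pos <- (1 + signal_strength * tilt); p_pos <- p_pos / sum(p_pos)
  p_neg <- (1 - signal_strength * tilt); p_neg <- p_neg / sum(p_neg)
  # PSSM column mean shift, same sign pattern as the composition tilt
  mu_shift <- 3 * signal_strength * tilt

  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(-1L, n_neg))
  ids <- sprintf("fx%04d", seq_len(n))
  lens <- sample(seq(min(length_range), max(length_range)), n, replace = TRUE)

  seqs <- character(n)
  profiles <- vector("list", n)
  names(profiles) <- ids
  for (i in seq_len(n)) {
    p <- if (labels[i] == 1L) p_pos else p_neg
    s <- sample(AA_ALPHABET, lens[i], replace = TRUE, prob = p)
    seqs[i] <- paste(s, collapse = "")
    mu <- if (labels[i] == 1L) mu_shift else -mu_shift
    m <- matrix(rnorm(lens[i] * 20L, sd = 2), nrow = lens[i])
    m <- sweep(m, 2L, mu, `+`)
    # a profile scores its own residue higher, as real log-odds do
    m[cbind(seq_len(lens[i]), match(s, AA_ALPHABET))] <-
      m[cbind(seq_len(lens[i]), match(s, AA_ALPHABET))] + 2
    m <- pmin(pmax(round(m), -10), 10)
    colnames(m) <- AA_ALPHABET
    attr(m, "id") <- ids[i]
    profiles[[i]] <- m
  }
  records <- tibble::tibble(id = ids, sequence = seqs, label = labels)
  dbp_dataset(records, profiles,
              name = sprintf("fixture_s%.2f_seed%d", signal_strength,
                             as.integer(seed)))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
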