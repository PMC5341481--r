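# Position-specific oligonucleotide probability tables.
#
# A table holds, for every start position n along the 147-bp window and every
# k-mer w, the fraction of ensemble sequences whose k-mer at n equals w:
# the empirical P(S_n ... S_{n+k-1}).  k-mers are indexed base-4 with the
# first base most significant, so marginalizing over the *last* base is a
# sum over consecutive blocks of 4 columns.

#' All k-mers of length k, in table column order
#'
#' Column `i` of a [position_oligo_table()] corresponds to the k-mer whose
#' base-4 code (first base most significant, A=0..T=3) is `i - 1`.
#'
#' @param k oligonucleotide length
#' @return character vector of length `4^k`
#' @export
kmer_names <- function(k) {
  stopifnot(k >= 1)
  grid <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies its first factor fastest; we want the last base
  # fastest, so reverse the column order before pasting.
  do.call(paste0, rev(grid))
}

# k-mer integer codes (0-based) at every start of every row of a code
# matrix: returns an integer matrix n_seq x (L - k + 1).
kmer_codes <- function(codes, k) {
  L <- ncol(codes)
  npos <- L - k + 1L
  ids <- matrix(0L, nrow(codes), npos)
  for (t in seq_len(k)) {
    ids <- ids + codes[, t:(t + npos - 1L), drop = FALSE] * 4L^(k - t)
  }
  ids
}

#' Construct a position-specific oligonucleotide table
#'
#' Low-level constructor; most users call [count_oligos()] or
#' [transfer_matrix_marginals()] instead.
#'
#' @param prob numeric matrix, rows = start positions (0-based position `n`
#'   is row `n + 1`), columns = the `4^k` k-mers in [kmer_names()] order;
#'   each row a probability vector
#' @param k oligonucleotide length
#' @param window_length length of the sequences the table describes
#' @param n_sequences ensemble size the probabilities were estimated from
#'   (`NA` for exact/analytic tables)
#' @param smoothed logical: has 3-bp positional smoothing been applied?
#' @return object of class `position_oligo_table`
#' @export
position_oligo_table <- function(prob, k, window_length,
                                 n_sequences = NA_real_, smoothed = FALSE) {
  k <- as.integer(k)
  window_length <- as.integer(window_length)
  stopifnot(is.matrix(prob), k >= 1L,
            nrow(prob) == window_length - k + 1L,
            ncol(prob) == 4L^k,
            all(prob >= 0))
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > 1e-9))
    stop("rows of a probability table must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  colnames(prob) <- kmer_names(k)
  rownames(prob) <- as.character(seq_len(nrow(prob)) - 1L)
  structure(
    list(prob = prob, k = k, window_length = window_length,
         n_sequences = n_sequences, smoothed = isTRUE(smoothed)),
    class = "position_oligo_table"
  )
}

#' @export
print.position_oligo_table <- function(x, ...) {
  cat("Position-specific ", x$k, "-mer table: ",
      nrow(x$prob), " positions x ", ncol(x$prob), " k-mers",
      if (x$smoothed) " (3-bp smoothed)", "\n", sep = "")
  cat("  window length: ", x$window_length,
      "; ensemble size: ", x$n_sequences, "\n", sep = "")
  invisible(x)
}

#' Count position-specific k-mers in a sequence ensemble
#'
#' At each start position the number of ensemble sequences carrying each
#' k-mer is counted and divided by the ensemble size, giving the empirical
#' position-specific k-mer probability distribution.
#'
#' @param ensemble character vector of equal-length sequences, or an integer
#'   code matrix (rows = sequences, entries 0..3)
#' @param k oligonucleotide length (1 = mono, 2 = di, 3 = tri, ...)
#' @return a [position_oligo_table()]
#' @export
count_oligos <- function(ensemble, k) {
  k <- as.integer(k)
  codes <- encode_ensemble(ensemble)
  L <- ncol(codes)
  if (k > L) stop("k (", k, ") exceeds window length (", L, ")")
  if (anyNA(codes)) stop("ensemble sequences must not contain N")
  n <- nrow(codes)
  npos <- L - k + 1L
  prob <- matrix(0, npos, 4L^k)
  ids <- kmer_codes(codes, k)
  for (p in seq_len(npos)) {
    prob[p, ] <- tabulate(ids[, p] + 1L, nbins = 4L^k) / n
  }
  position_oligo_table(prob, k = k, window_length = L, n_sequences = n)
}

#' Marginalize a k-mer table over its last base
#'
#' Summing the `(k)`-mer probabilities over the final base yields the
#' `(k-1)`-mer (prefix) distribution at the same start positions.  Deriving
#' the denominator tables of the Markov model this way (rather than
#' recounting) guarantees numerator and denominator are exactly consistent.
#'
#' @param table a [position_oligo_table()] with `k >= 2`
#' @return a `position_oligo_table` with `k - 1`, spanning the same starts
#'   (its `window_length` is reduced by one so row/position bookkeeping stays
#'   consistent: the prefix starts run 0..`window_length - k`)
#' @export
marginalize_last <- function(table) {
  stopifnot(inherits(table, "position_oligo_table"), table$k >= 2L)
  p <- table$prob
  nk <- ncol(p)
  marg <- p[, seq.int(1L, nk, by = 4L), drop = FALSE]
  for (j in 2:4) marg <- marg + p[, seq.int(j, nk, by = 4L), drop = FALSE]
  position_oligo_table(marg, k = table$k - 1L,
                       window_length = table$window_length - 1L,
                       n_sequences = table$n_sequences,
                       smoothed = table$smoothed)
}

#' Smooth a table along positions with a 3-bp running average
#'
#' Each probability is replaced by the average of its values at positions
#' `n - 1`, `n`, `n + 1`; the two boundary positions average over the
#' available two neighbours.  Rows are then renormalized to sum to one.
#' This is the positional smoothing applied by experimentally trained
#' nucleosome models whose data lack single-bp resolution.
#'
#' @param table a [position_oligo_table()] with at least 3 positions
#' @return smoothed `position_oligo_table` (flagged `smoothed = TRUE`)
#' @export
smooth_positions <- function(table) {
  stopifnot(inherits(table, "position_oligo_table"))
  p <- table$prob
  npos <- nrow(p)
  if (npos < 3L) stop("need at least 3 positions to smooth")
  zero <- matrix(0, 1L, ncol(p))
  acc <- p + rbind(zero, p[-npos, , drop = FALSE]) +
             rbind(p[-1L, , drop = FALSE], zero)
  denom <- c(2, rep(3, npos - 2L), 2)
  sm <- acc / denom
  sm <- sm / rowSums(sm)
  position_oligo_table(sm, k = table$k, window_length = table$window_length,
                       n_sequences = table$n_sequences, smoothed = TRUE)
}

#' Subsample a sequence ensemble without replacement
#'
#' @param ensemble character vector of sequences or integer code matrix
#' @param n subset size, `1 <= n <= length(ensemble)`
#' @param seed optional integer seed (caller RNG untouched)
#' @return subset of the same type as the input
#' @export
subsample <- function(ensemble, n, seed = NULL) {
  N <- if (is.matrix(ensemble)) nrow(ensemble) else length(ensemble)
  n <- as.integer(n)
  if (n < 1L || n > N)
    stop("subset size n = ", n, " must be in 1..", N)
  idx <- with_seed(seed, sample.int(N, n))
  if (is.matrix(ensemble)) ensemble[idx, , drop = FALSE] else ensemble[idx]
}

#' Write a position-specific oligonucleotide table to TSV (+ JSON sidecar)
#'
#' Long-format TSV with columns `position` (0-based), `kmer`, `probability`;
#' metadata (`k`, `window_length`, `n_sequences`, `smoothed`) goes to
#' `<path>.json`.
#'
#' @param table a [position_oligo_table()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_oligo_table <- function(table, path) {
  stopifnot(inherits(table, "position_oligo_table"))
  df <- data.frame(
    position = rep(seq_len(nrow(table$prob)) - 1L, times = ncol(table$prob)),
    kmer = rep(colnames(table$prob), each = nrow(table$prob)),
    probability = as.vector(table$prob),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(k = table$k, window_length = table$window_length,
               n_sequences = table$n_sequences, smoothed = table$smoothed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a table written by [write_oligo_table()]
#' @param path TSV path (expects `<path>.json` sidecar)
#' @return a [position_oligo_table()]
#' @export
read_oligo_table <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  km <- kmer_names(meta$k)
  npos <- meta$window_length - meta$k + 1L
  prob <- matrix(0, npos, length(km))
  prob[cbind(df$position + 1L, match(df$kmer, km))] <- df$probability
  position_oligo_table(prob, k = meta$k, window_length = meta$window_length,
                       n_sequences = meta$n_sequences %||% NA_real_,
                       smoothed = isTRUE(meta$smoothed))
}
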