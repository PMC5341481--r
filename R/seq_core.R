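# Sequence representation, FASTA I/O, window iteration and random fixtures.
#
# Sequences are plain uppercase character strings over {A,C,G,T} (plus N for
# genomic input, which is masked rather than scored).  Internally everything
# is encoded as integer codes 0..3 (A,C,G,T); ensembles are integer matrices
# with one row per sequence, which is also the native output format of the
# MMC sampler.

DNA_BASES <- c("A", "C", "G", "T")

# ASCII lookup: A,C,G,T -> 0..3, N -> -1, anything else -> NA
.dna_code_lookup <- local({
  tbl <- rep(NA_integer_, 127L)
  tbl[utf8ToInt("A")] <- 0L
  tbl[utf8ToInt("C")] <- 1L
  tbl[utf8ToInt("G")] <- 2L
  tbl[utf8ToInt("T")] <- 3L
  tbl[utf8ToInt("N")] <- -1L
  tbl
})

#' Encode a DNA string as integer codes
#'
#' Maps `A,C,G,T` to `0:3`.  With `allow_n = TRUE`, `N` becomes `NA` (masked);
#' otherwise `N` and any other character raise an error.  Input is uppercased
#' first.
#'
#' @param x a single character string over `{A,C,G,T,N}`
#' @param allow_n logical; mask `N` as `NA` instead of erroring
#' @return integer vector of codes in `0:3` (with `NA` for masked `N`)
#' @export
encode_seq <- function(x, allow_n = FALSE) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  ints <- utf8ToInt(toupper(x))
  if (any(ints > 127L)) stop("non-ASCII character in sequence")
  codes <- .dna_code_lookup[ints]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop("invalid character '", substr(toupper(x), bad, bad),
         "' at position ", bad, "; expected A/C/G/T",
         if (allow_n) "/N" else "")
  }
  if (any(codes < 0L)) {
    if (!allow_n) {
      bad <- which(codes < 0L)[1L]
      stop("ambiguous base 'N' at position ", bad,
           " not allowed in this context")
    }
    codes[codes < 0L] <- NA_integer_
  }
  codes
}

#' Decode integer codes back to a DNA string
#' @param codes integer vector over `0:3` (`NA` becomes `N`)
#' @return character string
#' @export
decode_seq <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- DNA_BASES[codes[ok] + 1L]
  paste(out, collapse = "")
}

#' Convert between sequence vectors and integer code matrices
#'
#' An ensemble is either a character vector of equal-length sequences or an
#' integer matrix of base codes (one row per sequence, entries 0..3); most
#' package functions accept both.  `encode_ensemble()` normalizes to the
#' matrix form (erroring on ragged lengths), `decode_ensemble()` converts
#' back to strings.
#'
#' @param ensemble character vector of equal-length sequences, or an integer
#'   code matrix (passed through after validation)
#' @param allow_n mask `N` as `NA` instead of erroring
#' @return integer code matrix
#' @export
encode_ensemble <- function(ensemble, allow_n = FALSE) {
  if (!is.matrix(ensemble) && is.numeric(ensemble))
    ensemble <- matrix(as.integer(ensemble), nrow = 1L)
  if (is.matrix(ensemble) && is.numeric(ensemble)) {
    storage.mode(ensemble) <- "integer"
    if (any(ensemble < 0L | ensemble > 3L, na.rm = TRUE))
      stop("code matrix entries must be in 0:3")
    return(ensemble)
  }
  stopifnot(is.character(ensemble), length(ensemble) >= 1L)
  lens <- nchar(ensemble)
  if (length(unique(lens)) != 1L)
    stop("ragged ensemble: sequence lengths ", min(lens), "..", max(lens),
         "; all sequences must have identical length")
  t(vapply(ensemble, encode_seq, integer(lens[1L]), allow_n = allow_n,
           USE.NAMES = FALSE))
}

#' @rdname encode_ensemble
#' @param codes integer code matrix
#' @export
decode_ensemble <- function(codes) {
  apply(codes, 1L, decode_seq)
}

#' Read sequences from a FASTA file
#'
#' Reads all records in file order, uppercasing the sequence.  Characters
#' outside `{A,C,G,T,N}` raise an error naming the offending record.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines)
#' @return named character vector of uppercase sequences (possibly empty)
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonempty[1L]]), ">"))
    stop("malformed FASTA in '", path, "': line ", nonempty[1L],
         " does not start a '>' header")
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    stop("record '", names(seqs)[i], "' contains invalid character '",
         ch, "'; expected A/C/G/T/N")
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs character vector of sequences; names become record identifiers
#'   (unnamed records are labelled `seq_1`, `seq_2`, ...)
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs))
  nm <- names(seqs) %||% rep("", length(seqs))
  blank <- !nzchar(nm)
  nm[blank] <- paste0("seq_", which(blank))
  ss <- Biostrings::BStringSet(setNames(unname(seqs), nm))
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Reverse complement
#' @param x character vector of DNA sequences
#' @return reverse-complemented sequences (names preserved)
#' @export
reverse_complement <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Enumerate fixed-width windows of a genome
#'
#' Yields all windows starting at `0, step, 2*step, ...` (0-based, half-open
#' `[start, start + width)`).  Windows overlapping an `N` are skipped and
#' their starts recorded in the `"skipped"` attribute.
#'
#' @param genome a single character string (may contain `N`)
#' @param width window width in bp (147 for nucleosomal windows)
#' @param step distance between consecutive window starts
#' @return data.frame with columns `start` (0-based integer) and `seq`
#'   (character), with attribute `skipped` listing N-masked starts
#' @export
windows <- function(genome, width = 147L, step = 1L) {
  stopifnot(is.character(genome), length(genome) == 1L)
  width <- as.integer(width); step <- as.integer(step)
  L <- nchar(genome)
  if (width > L) stop("width (", width, ") exceeds genome length (", L, ")")
  if (step < 1L) stop("step must be >= 1")
  codes <- encode_seq(genome, allow_n = TRUE)
  starts <- seq.int(0L, L - width, by = step)
  # window [s, s+width) contains an N iff cumulative NA count increases
  nacum <- c(0L, cumsum(is.na(codes)))
  has_n <- (nacum[starts + width + 1L] - nacum[starts + 1L]) > 0L
  keep <- starts[!has_n]
  out <- data.frame(
    start = keep,
    seq = substring(toupper(genome), keep + 1L, keep + width),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- starts[has_n]
  out
}

#' Generate a random genome sequence
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length sequence length in bp
#' @param seed optional integer seed (the caller's RNG state is untouched)
#' @param gc GC fraction in `[0, 1]`
#' @return a single character string
#' @export
random_genome <- function(length, seed = NULL, gc = 0.5) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- with_seed(seed,
    sample.int(4L, size = length, replace = TRUE, prob = p) - 1L)
  decode_seq(codes)
}

#' Generate an ensemble of random fixed-length sequences
#'
#' Convenience fixture generator: `n` i.i.d. uniform (or GC-biased) sequences
#' of identical length.
#'
#' @param n number of sequences
#' @param length length of each sequence (147 for nucleosomal windows)
#' @param seed optional integer seed
#' @param gc GC fraction
#' @return character vector of `n` sequences
#' @export
random_ensemble <- function(n, length = 147L, seed = NULL, gc = 0.5) {
  stopifnot(n >= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- with_seed(seed,
    matrix(sample.int(4L, size = n * length, replace = TRUE, prob = p) - 1L,
           nrow = n))
  decode_ensemble(codes)
}

#' Size of the nucleosomal sequence space
#'
#' Number of distinct DNA sequences of a given length: `4^length`.  For the
#' 147-bp nucleosome this is about `3.2e88`, which is why affinity models must
#' be parametric rather than enumerative.
#'
#' @param length sequence length in bp
#' @return numeric scalar `4^length`
#' @export
sequence_space_size <- function(length = 147L) {
  4^as.numeric(length)
}
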