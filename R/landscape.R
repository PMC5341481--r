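# Sliding-window energy landscapes and signal decomposition.
#
# A landscape maps each 147-bp window start of a genomic sequence to a
# scalar energy in kT.  Landscapes from different models carry unknown
# additive offsets; Boltzmann normalization over the common window set makes
# them directly comparable.  The benchmark decomposes a landscape into an
# 11-bp local average (slow component) and the residual ~10-bp periodic
# component.

#' Construct an energy landscape
#'
#' @param positions 0-based window start indices (strictly increasing)
#' @param values energies in kT, one per position, all finite
#' @param kT energy unit scale
#' @param normalized has Boltzmann normalization been applied?
#' @param source free-text label (e.g. "markov-order-1", "toy-exact-meanE")
#' @return object of class `energy_landscape`
#' @export
energy_landscape <- function(positions, values, kT = 1, normalized = FALSE,
                             source = "") {
  positions <- as.integer(positions)
  stopifnot(length(positions) == length(values),
            all(is.finite(values)),
            !is.unsorted(positions, strictly = TRUE))
  structure(
    list(positions = positions, values = as.numeric(values), kT = kT,
         normalized = isTRUE(normalized), source = source),
    class = "energy_landscape"
  )
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("Energy landscape", if (nzchar(x$source)) paste0(" [", x$source, "]"),
      ": ", length(x$values), " windows, positions ",
      min(x$positions), "..", max(x$positions), "\n", sep = "")
  cat(sprintf("  kT = %.4g; normalized: %s; range %.3f .. %.3f kT\n",
              x$kT, x$normalized, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.energy_landscape <- function(x, ..., xlab = "window start (bp)",
                                  ylab = "energy (kT)", type = "l") {
  graphics::plot(x$positions, x$values, type = type, xlab = xlab,
                 ylab = ylab, main = x$source, ...)
  invisible(x)
}

#' @export
as.data.frame.energy_landscape <- function(x, ...) {
  data.frame(position = x$positions, energy_kT = x$values)
}

#' Compute a sliding-window energy landscape of a genome
#'
#' Scores every step-1 window of width `width` with the given model.
#' Windows overlapping an `N` are excluded (their starts are recorded in the
#' `"skipped"` attribute).
#'
#' @param genome a single character string (may contain `N`)
#' @param model a `nucleomarkov` fit (scores windows by Markov free energy
#'   `-kT log P`), a `toy_nucleosome` model (exact mean energy or free
#'   energy; see `what`), or a plain function mapping one window string to a
#'   scalar energy
#' @param width window width; defaults to the model's window length
#' @param ... passed to methods
#' @return an [energy_landscape()]
#' @export
compute_landscape <- function(genome, model, ...) UseMethod("compute_landscape",
                                                            model)

# shared plumbing: encoded genome + window starts without N
landscape_starts <- function(genome, width) {
  codes <- encode_seq(genome, allow_n = TRUE)
  L <- length(codes)
  if (width > L) stop("width (", width, ") exceeds genome length (", L, ")")
  starts <- 0:(L - width)
  nacum <- c(0L, cumsum(is.na(codes)))
  has_n <- (nacum[starts + width + 1L] - nacum[starts + 1L]) > 0L
  list(codes = codes, starts = starts[!has_n], skipped = starts[has_n])
}

#' @rdname compute_landscape
#' @export
compute_landscape.nucleomarkov <- function(genome, model,
                                           width = model$window_length, ...) {
  if (width != model$window_length)
    stop("width must equal the model window length (", model$window_length,
         ")")
  ls0 <- landscape_starts(genome, width)
  m <- model$order
  npos <- width - m
  gk <- genome_kmer_codes(ls0$codes, m + 1L)
  nw <- length(ls0$starts)
  if (nw == 0L) stop("no scorable windows (all masked by N)")
  logp <- numeric(nw)
  if (m > 0L) {
    lead_ids <- gk[ls0$starts + 1L] %/% 4L
    logp <- unname(model$loglead[lead_ids + 1L])
  }
  # accumulate conditional log-probs in chunks of windows to bound memory
  chunk <- 20000L
  for (lo in seq.int(1L, nw, by = chunk)) {
    hi <- min(lo + chunk - 1L, nw)
    s <- ls0$starts[lo:hi]
    idx <- outer(seq_len(npos), s, `+`)      # genome k-mer index (1-based)
    v <- model$logcond[cbind(rep(seq_len(npos), times = length(s)),
                             gk[idx] + 1L)]
    dim(v) <- c(npos, length(s))
    logp[lo:hi] <- logp[lo:hi] + colSums(v)
  }
  if (model$zero_policy == "strict" && anyNA(logp))
    stop("ensemble failure: a zero-probability k-mer occurred in window(s) ",
         "starting at ", paste(head(ls0$starts[is.na(logp)], 3L),
                               collapse = ", "),
         " (strict zero policy)")
  out <- energy_landscape(ls0$starts, -model$kT * logp, kT = model$kT,
                          source = paste0("markov-order-", m))
  attr(out, "skipped") <- ls0$skipped
  out
}

# genome-wide k-mer codes: integer vector, entry i = code of the k-mer
# starting at (1-based) genome position i; NA where masked.
genome_kmer_codes <- function(codes, k) {
  G <- length(codes)
  n <- G - k + 1L
  ids <- integer(n)
  for (t in seq_len(k)) ids <- ids + codes[t:(t + n - 1L)] * 4L^(k - t)
  ids
}

#' @rdname compute_landscape
#' @param what for a toy model: `"mean_energy"` scores windows by the exact
#'   thermal mean energy `<E>_S` ([exact_mean_energy()]), `"free_energy"` by
#'   the exact free energy `F(S)` ([exact_free_energy()])
#' @export
compute_landscape.toy_nucleosome <- function(genome, model,
                                             width = model$window_length,
                                             what = c("mean_energy",
                                                      "free_energy"), ...) {
  what <- match.arg(what)
  if (width != model$window_length)
    stop("width must equal the model window length (", model$window_length,
         ")")
  ls0 <- landscape_starts(genome, width)
  if (length(ls0$starts) == 0L) stop("no scorable windows (all masked by N)")
  wcodes <- matrix(ls0$codes[outer(ls0$starts, seq_len(width), `+`)],
                   nrow = length(ls0$starts))
  st <- toy_gaussian_stats(model, wcodes)
  ns <- width - 1L
  kT <- model$kT
  vals <- if (what == "mean_energy") {
    st[, 1L] + ns * kT / 2
  } else {
    st[, 1L] - (kT / 2) * (ns * log(2 * pi * kT) - st[, 2L])
  }
  out <- energy_landscape(ls0$starts, vals, kT = kT,
                          source = paste0("toy-exact-",
                                          if (what == "mean_energy") "meanE"
                                          else "F"))
  attr(out, "skipped") <- ls0$skipped
  out
}

#' @rdname compute_landscape
#' @param width window width (required for a function scorer)
#' @param kT energy unit of the scorer's output (function scorer)
#' @export
compute_landscape.function <- function(genome, model, width = 147L, kT = 1,
                                       ...) {
  w <- windows(genome, width = width, step = 1L)
  vals <- vapply(w$seq, model, numeric(1), USE.NAMES = FALSE)
  out <- energy_landscape(w$start, vals, kT = kT, source = "custom")
  attr(out, "skipped") <- attr(w, "skipped")
  out
}

#' Boltzmann-normalize an energy landscape
#'
#' Adds the unique constant making `sum_w exp(-value_w / kT) = 1` over the
#' landscape's own window set, i.e. turns the values into minus-log of a
#' normalized Boltzmann distribution.  A pure additive shift: the shape of
#' the landscape (all pairwise differences) is unchanged, and the operation
#' is idempotent.
#'
#' @param ls an [energy_landscape()]
#' @return normalized `energy_landscape`
#' @export
normalize_landscape <- function(ls) {
  stopifnot(inherits(ls, "energy_landscape"))
  shift <- ls$kT * logsumexp(-ls$values / ls$kT)
  out <- energy_landscape(ls$positions, ls$values + shift, kT = ls$kT,
                          normalized = TRUE, source = ls$source)
  attr(out, "skipped") <- attr(ls, "skipped")
  out
}

#' 11-bp local average of a landscape
#'
#' Centered running average over `window` consecutive window positions
#' (default 11 bp, about one helical period), keeping only positions with
#' full support: `(window - 1)/2` positions are trimmed at each end.
#'
#' @param ls an [energy_landscape()] with at least `window` values
#' @param window odd averaging width in positions
#' @return `energy_landscape` of the slowly varying component
#' @export
local_average <- function(ls, window = 11L) {
  stopifnot(inherits(ls, "energy_landscape"))
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("window must be odd")
  n <- length(ls$values)
  if (n < window)
    stop("need at least ", window, " windows (have ", n, ")")
  h <- (window - 1L) %/% 2L
  avg <- stats::filter(ls$values, rep(1 / window, window), sides = 2)
  keep <- (h + 1L):(n - h)
  energy_landscape(ls$positions[keep], as.numeric(avg[keep]), kT = ls$kT,
                   normalized = FALSE,
                   source = paste0(ls$source, if (nzchar(ls$source)) " ",
                                   "(local avg)"))
}

#' Periodic component of a landscape
#'
#' Subtracts the local average from the full signal on their common
#' positions, leaving the ~10-bp periodic part oscillating around zero.
#'
#' @inheritParams local_average
#' @return `energy_landscape` of the periodic component
#' @export
periodic_component <- function(ls, window = 11L) {
  la <- local_average(ls, window = window)
  idx <- match(la$positions, ls$positions)
  energy_landscape(la$positions, ls$values[idx] - la$values, kT = ls$kT,
                   normalized = FALSE,
                   source = paste0(ls$source, if (nzchar(ls$source)) " ",
                                   "(periodic)"))
}

# shift a landscape along the genome by `by` positions (used by the
# out-of-phase bad model)
shift_landscape <- function(ls, by) {
  energy_landscape(ls$positions + as.integer(by), ls$values, kT = ls$kT,
                   normalized = ls$normalized, source = ls$source)
}

#' Write / read an energy landscape
#'
#' TSV with two columns (`position`, `energy_kT`) and `#`-prefixed header
#' lines carrying kT, normalization state and source; or fixedStep wiggle
#' for genome browsers.
#'
#' @param ls an [energy_landscape()]
#' @param path output path
#' @param format `"tsv"` or `"wig"`
#' @param chrom chromosome name for wiggle output
#' @return `path` invisibly ([write_landscape()]); an `energy_landscape`
#'   ([read_landscape()])
#' @export
write_landscape <- function(ls, path, format = c("tsv", "wig"),
                            chrom = "chr") {
  stopifnot(inherits(ls, "energy_landscape"))
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# kT=%.17g normalized=%s source=%s", ls$kT,
                       ls$normalized, ls$source), con)
    writeLines("position\tenergy_kT", con)
    writeLines(sprintf("%d\t%.17g", ls$positions, ls$values), con)
  } else {
    # fixedStep requires a constant step; emit one block per contiguous run
    con <- file(path, "w")
    on.exit(close(con))
    runs <- cumsum(c(1L, diff(ls$positions) != 1L))
    for (r in unique(runs)) {
      i <- which(runs == r)
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1", chrom,
                         ls$positions[i[1L]] + 1L), con)  # wiggle is 1-based
      writeLines(sprintf("%.6g", ls$values[i]), con)
    }
  }
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  hdr <- readLines(path, n = 1L)
  stopifnot(startsWith(hdr, "# kT="))
  kv <- regmatches(hdr, gregexpr("(kT|normalized|source)=[^ ]*", hdr))[[1L]]
  get1 <- function(key) sub(paste0(key, "="), "",
                            kv[startsWith(kv, paste0(key, "="))][1L])
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  energy_landscape(df$position, df$energy_kT,
                   kT = as.numeric(get1("kT")),
                   normalized = identical(get1("normalized"), "TRUE"),
                   source = get1("source") %||% "")
}
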