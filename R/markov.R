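# Order-m position-specific Markov sequence models.
#
# An order-m model scores a window S of length L as
#
#   P(S) = prod_{j=0}^{L-m-1} P_n( (m+1)-mer at start j )
#        / prod_{j=1}^{L-m-1} P_n( m-mer at start j ),
#
# (0-based starts), the joint/marginal rewriting of the chain rule under the
# assumption that each base depends only on its m predecessors.  For m = 1
# this is the classic dinucleotide model; m = 0 reduces to a product of
# position-specific mononucleotide probabilities.  Equivalently,
# log P(S) = log P(leading m-mer) + sum_j log P(base | m-mer context at j),
# which is the form used internally: a per-position conditional log-prob
# matrix is precomputed once at fit time, with the zero-probability policy
# already applied, so scoring is pure table lookup.

ZERO_POLICIES <- c("flat_quarter", "smoothed", "strict")

#' Fit a position-specific Markov model to a sequence ensemble
#'
#' Counts position-specific `(order + 1)`-mers in the ensemble, derives the
#' `order`-mer denominator table by exact marginalization, and assembles an
#' order-`order` Markov model of the sequence distribution.  The free energy
#' of a sequence is `-kT * log P(S)` (additive constant unknown: only energy
#' differences are meaningful).
#'
#' Zero-probability handling: a k-mer never observed at some position leaves
#' a zero in the table, which would zero out `P(S)` for every sequence
#' carrying it.  The `zero_policy` decides what happens when such a factor is
#' needed: `"flat_quarter"` substitutes an information-free flat conditional
#' of 0.25, `"strict"` raises an "ensemble failure" error naming position and
#' k-mer, and `"smoothed"` (intended together with `smooth = TRUE`) behaves
#' like `"flat_quarter"` for residual zeros that survive smoothing.  When the
#' tables are strictly positive the policy is never invoked and all three
#' give identical scores.
#'
#' @param ensemble character vector of equal-length training sequences, or an
#'   integer code matrix (rows = sequences, entries 0..3) as returned by
#'   [mmc_sample()] with `as = "matrix"`
#' @param order Markov order m >= 0 (0 = mononucleotide, 1 = dinucleotide,
#'   2 = trinucleotide model)
#' @param smooth apply 3-bp positional smoothing ([smooth_positions()]) to
#'   the joint table before marginalizing
#' @param zero_policy one of `"flat_quarter"`, `"smoothed"`, `"strict"`
#' @param symmetrize augment the ensemble with the reverse complement of
#'   every sequence before counting, enforcing strand symmetry of the
#'   fitted tables.  Off by default: ensembles are used as given, and
#'   strands are scored as given
#' @param kT energy unit scale (energies are reported in units of kT)
#' @return an object of class `nucleomarkov` with `print`, `summary`,
#'   `coef`, `predict` and `simulate` methods
#' @seealso [log_probability()], [free_energy()], [compute_landscape()]
#' @examples
#' ens <- random_ensemble(200, length = 20, seed = 1)
#' fit <- markov_fit(ens, order = 1)
#' predict(fit, ens[1:3])
#' @export
markov_fit <- function(ensemble, order = 1L, smooth = FALSE,
                       zero_policy = if (smooth) "smoothed" else "flat_quarter",
                       symmetrize = FALSE, kT = 1) {
  order <- as.integer(order)
  stopifnot(order >= 0L)
  if (symmetrize) {
    codes <- encode_ensemble(ensemble)
    # reverse complement in code space: complement is 3 - code
    ensemble <- rbind(codes, 3L - codes[, rev(seq_len(ncol(codes))),
                                        drop = FALSE])
  }
  joint <- count_oligos(ensemble, k = order + 1L)
  if (smooth) joint <- smooth_positions(joint)
  markov_model(joint, zero_policy = zero_policy, kT = kT)
}

#' Assemble a Markov model from a joint oligonucleotide table
#'
#' Low-level constructor used by [markov_fit()] and by oracle constructions
#' (e.g. building the order-1 model from exact [transfer_matrix_marginals()]).
#' The `order`-mer denominator table is always derived from `joint` by
#' [marginalize_last()], never recounted.
#'
#' @param joint a [position_oligo_table()] with `k = order + 1`
#' @param zero_policy see [markov_fit()]
#' @param kT energy unit scale
#' @return an object of class `nucleomarkov`
#' @export
markov_model <- function(joint, zero_policy = "flat_quarter", kT = 1) {
  stopifnot(inherits(joint, "position_oligo_table"))
  zero_policy <- match.arg(zero_policy, ZERO_POLICIES)
  order <- joint$k - 1L
  L <- joint$window_length
  marginal <- if (order > 0L) marginalize_last(joint) else NULL

  J <- joint$prob                       # (L - order) x 4^(order+1)
  npos <- nrow(J)
  flat_ok <- zero_policy %in% c("flat_quarter", "smoothed")
  if (order == 0L) {
    logcond <- log(J)
    logcond[J == 0] <- if (flat_ok) log(0.25) else NA_real_
    loglead <- 0
    n_zero <- sum(J == 0)
  } else {
    Mg <- marginal$prob                 # same starts, prefix m-mers
    D <- Mg[, rep(seq_len(ncol(Mg)), each = 4L), drop = FALSE]
    logcond <- log(J) - log(D)
    zero <- (J == 0) | (D == 0)         # includes the 0/0 convention
    logcond[zero] <- if (flat_ok) log(0.25) else NA_real_
    lead <- Mg[1L, ]
    loglead <- log(lead)
    loglead[lead == 0] <- if (flat_ok) order * log(0.25) else NA_real_
    n_zero <- sum(J == 0)
  }

  structure(
    list(order = order, window_length = L, joint = joint, marginal = marginal,
         zero_policy = zero_policy, kT = kT,
         n_sequences = joint$n_sequences, smoothed = joint$smoothed,
         logcond = logcond, loglead = loglead, n_zero_cells = n_zero),
    class = "nucleomarkov"
  )
}

# Score a code matrix (rows = sequences of model window length).
# Returns natural-log probabilities.
markov_logp_codes <- function(model, codes) {
  m <- model$order
  L <- model$window_length
  if (ncol(codes) != L)
    stop("sequence length ", ncol(codes), " does not match model window ",
         "length ", L)
  npos <- L - m                          # joint starts: 0 .. L - m - 1
  ids <- kmer_codes(codes, m + 1L)       # n x npos
  n <- nrow(codes)
  logp <- numeric(n)
  if (m > 0L) {
    lead_ids <- ids[, 1L] %/% 4L         # prefix m-mer of first joint k-mer
    logp <- unname(model$loglead[lead_ids + 1L])
  }
  for (p in seq_len(npos)) {
    logp <- logp + unname(model$logcond[p, ids[, p] + 1L])
  }
  if (model$zero_policy == "strict" && anyNA(logp)) {
    # locate the first offending (position, k-mer) for the error message
    for (p in seq_len(npos)) {
      bad <- is.na(model$logcond[p, ids[, p] + 1L])
      if (any(bad)) {
        w <- kmer_names(m + 1L)[ids[which(bad)[1L], p] + 1L]
        stop("ensemble failure: zero probability for ", m + 1L, "-mer '",
             w, "' at position ", p - 1L,
             " (strict zero policy); enlarge the ensemble or use ",
             "'flat_quarter'")
      }
    }
  }
  logp
}

#' Log-probability of sequences under a Markov model
#'
#' Natural-log probability `log P(S)` per the order-m joint/marginal
#' factorization; always `<= 0`.
#'
#' @param model a `nucleomarkov` fit
#' @param seqs character vector of sequences of the model's window length,
#'   or an integer code matrix
#' @return numeric vector of log-probabilities
#' @export
log_probability <- function(model, seqs) {
  stopifnot(inherits(model, "nucleomarkov"))
  markov_logp_codes(model, encode_ensemble(seqs))
}

#' Free energy of sequences
#'
#' `F(S) = -kT log P(S)`, in units of kT.  The additive constant (partition
#' function) is unknown; only differences between sequences are meaningful.
#'
#' @param model a `nucleomarkov` fit or a [toy_nucleosome_model()]
#' @param seqs sequences (character vector or integer code matrix)
#' @param ... passed to methods
#' @return numeric vector of energies in kT
#' @export
free_energy <- function(model, seqs, ...) UseMethod("free_energy")

#' @rdname free_energy
#' @export
free_energy.nucleomarkov <- function(model, seqs, ...) {
  -model$kT * log_probability(model, seqs)
}

#' @export
print.nucleomarkov <- function(x, ...) {
  cat("Position-specific Markov model, order ", x$order,
      " (", c("mono", "di", "tri")[min(x$order + 1L, 3L)],
      if (x$order > 2L) "..." , "nucleotide)\n", sep = "")
  cat("  window length: ", x$window_length, " bp; trained on ",
      x$n_sequences, " sequences\n", sep = "")
  cat("  zero policy: ", x$zero_policy,
      if (x$smoothed) "; tables 3-bp smoothed", "\n", sep = "")
  invisible(x)
}

#' @export
summary.nucleomarkov <- function(object, ...) {
  x <- object
  cells <- length(x$joint$prob)
  out <- list(order = x$order, window_length = x$window_length,
              n_sequences = x$n_sequences, zero_policy = x$zero_policy,
              smoothed = x$smoothed, n_zero_cells = x$n_zero_cells,
              total_cells = cells,
              zero_fraction = x$n_zero_cells / cells)
  class(out) <- "summary.nucleomarkov"
  out
}

#' @export
print.summary.nucleomarkov <- function(x, ...) {
  cat("Order-", x$order, " position-specific Markov model\n", sep = "")
  cat("  window length: ", x$window_length, " bp; ensemble size: ",
      x$n_sequences, "\n", sep = "")
  cat("  zero policy: ", x$zero_policy, "; smoothed tables: ", x$smoothed,
      "\n", sep = "")
  cat(sprintf("  unobserved (position, k-mer) cells: %d of %d (%.2f%%)\n",
              x$n_zero_cells, x$total_cells, 100 * x$zero_fraction))
  invisible(x)
}

#' Extract fitted probability tables
#'
#' @param object a `nucleomarkov` fit
#' @param which `"joint"` for the `(m+1)`-mer table, `"marginal"` for the
#'   derived m-mer table, `"conditional"` for the per-position conditional
#'   log-probabilities actually used in scoring (zero policy applied)
#' @param ... unused
#' @return a [position_oligo_table()] or a numeric matrix (`"conditional"`)
#' @export
coef.nucleomarkov <- function(object,
                              which = c("joint", "marginal", "conditional"),
                              ...) {
  which <- match.arg(which)
  switch(which,
         joint = object$joint,
         marginal = object$marginal,
         conditional = object$logcond)
}

#' Predict log-probabilities or free energies for new sequences
#'
#' @param object a `nucleomarkov` fit
#' @param newdata sequences (character vector or code matrix)
#' @param type `"logp"` or `"free_energy"`
#' @param ... unused
#' @return numeric vector
#' @export
predict.nucleomarkov <- function(object, newdata,
                                 type = c("logp", "free_energy"), ...) {
  type <- match.arg(type)
  lp <- log_probability(object, newdata)
  if (type == "logp") lp else -object$kT * lp
}

#' Simulate sequences from a fitted Markov model
#'
#' Draws sequences from the fitted inhomogeneous order-m chain: the leading
#' m-mer from its marginal distribution at position 0, each further base from
#' the fitted conditional.  An unseen context (all-zero joint row block)
#' falls back to a uniform draw.
#'
#' @param object a `nucleomarkov` fit
#' @param nsim number of sequences
#' @param seed optional integer seed
#' @param ... unused
#' @return character vector of `nsim` sequences
#' @export
simulate.nucleomarkov <- function(object, nsim = 1, seed = NULL, ...) {
  m <- object$order
  L <- object$window_length
  J <- object$joint$prob
  npos <- nrow(J)
  with_seed(seed, {
    codes <- matrix(0L, nsim, L)
    if (m > 0L) {
      lead <- object$marginal$prob[1L, ]
      ctx <- sample.int(4L^m, nsim, replace = TRUE, prob = lead) - 1L
      for (t in seq_len(m)) {
        codes[, t] <- (ctx %/% 4L^(m - t)) %% 4L
      }
    } else {
      ctx <- integer(nsim)                # dummy context
    }
    for (p in seq_len(npos)) {
      # conditional over next base given context, renormalized from joint
      base_p <- integer(nsim)
      for (c0 in unique(if (m > 0L) ctx else 0L)) {
        rows <- if (m > 0L) which(ctx == c0) else seq_len(nsim)
        pr <- J[p, c0 * 4L + 1:4]
        if (sum(pr) <= 0) pr <- rep(0.25, 4L)
        base_p[rows] <- sample.int(4L, length(rows), replace = TRUE,
                                   prob = pr) - 1L
      }
      codes[, p + m] <- base_p
      if (m > 0L) ctx <- (ctx %% 4L^(m - 1L)) * 4L + base_p
    }
    decode_ensemble(codes)
  })
}

# ---- model directory serialization -----------------------------------------

#' Write a fitted Markov model to a directory
#'
#' Layout: `joint.tsv` (+ `.json` sidecar), derived `marginal.tsv` for
#' inspection, and `meta.json` with order, window length, zero policy,
#' smoothing flag, ensemble size and kT.
#'
#' @param model a `nucleomarkov` fit
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_markov_model <- function(model, dir) {
  stopifnot(inherits(model, "nucleomarkov"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_oligo_table(model$joint, file.path(dir, "joint.tsv"))
  if (!is.null(model$marginal))
    write_oligo_table(model$marginal, file.path(dir, "marginal.tsv"))
  meta <- list(order = model$order, window_length = model$window_length,
               zero_policy = model$zero_policy, smoothed = model$smoothed,
               n_sequences = model$n_sequences, kT = model$kT)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a model directory written by [write_markov_model()]
#' @param dir model directory
#' @return a `nucleomarkov` model
#' @export
read_markov_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  joint <- read_oligo_table(file.path(dir, "joint.tsv"))
  markov_model(joint, zero_policy = meta$zero_policy, kT = meta$kT)
}
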