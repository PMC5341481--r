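# Toy biophysical nucleosome model.
#
# A tractable caricature of rigid-base-pair nucleosome mechanics: one angle
# theta_n per base-pair step, a dinucleotide-dependent harmonic term
# 0.5*K(d_n)*(theta_n - theta0(d_n))^2, a harmonic constraint
# 0.5*kappa*(theta_n - c_n)^2 pulling each step towards a ~10-bp periodic
# profile c_n = A*cos(2*pi*n/p + phi) (the histone-imposed superhelical
# geometry), and an optional nearest-step coupling 0.5*lambda*(theta_{n+1} -
# theta_n)^2.  Because the energy is quadratic in theta, the sequence
# marginal P(S) = integral dtheta exp(-beta*E(S, theta)) has a closed
# Gaussian form; with lambda = 0 it factorizes over steps, making the exact
# sequence distribution an inhomogeneous nearest-neighbour Markov field with
# transfer-matrix-computable marginals.  That is precisely what makes this
# model a useful ground truth for benchmarking the Markov sequence models.

#' Default toy-model parameters
#'
#' Reads the parameter set shipped with the package: 16 dinucleotide
#' stiffnesses `K` (log-uniform in 5..50 kT_room/angle^2), intrinsic angles
#' `theta0` in -0.3..0.3, constraint stiffness `kappa = 20`, constraint
#' amplitude 0.2 with period 10 bp and phase 0, `lambda = 0`, and working
#' inverse temperature `beta = 6` (energies in units of room-temperature kT,
#' sampled at 1/6 of room temperature).
#'
#' @param path optional path to a parameter JSON file (defaults to the
#'   shipped file)
#' @return named list of parameters
#' @export
toy_default_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "toy_default_params.json",
                        package = "nucleomark")
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$K <- unlist(p$K)
  p$theta0 <- unlist(p$theta0)
  p
}

#' Construct a toy quadratic nucleosome model
#'
#' @param window_length number of base pairs wrapped (147 by default); the
#'   model has `window_length - 1` step angles
#' @param K named numeric vector of 16 dinucleotide stiffnesses (> 0),
#'   in kT_room per squared angle unit, ordered/named as `kmer_names(2)`
#' @param theta0 named numeric vector of 16 intrinsic step angles
#' @param kappa constraint stiffness (>= 0) pulling steps to the periodic
#'   profile
#' @param amplitude,period,phase constraint profile
#'   `c_n = amplitude * cos(2*pi*n/period + phase)`, `n = 0..L-2`
#' @param lambda nearest-step coupling (>= 0); `lambda = 0` gives an exactly
#'   nearest-neighbour sequence model
#' @param beta inverse working temperature in 1/kT_room (6 = one sixth of
#'   room temperature); `kT = 1/beta` in room-temperature units
#' @param params optional list as from [toy_default_params()]; individual
#'   arguments override its entries
#' @return object of class `toy_nucleosome`
#' @examples
#' toy <- toy_nucleosome_model(window_length = 20)
#' exact_free_energy(toy, random_ensemble(2, 20, seed = 1))
#' @export
toy_nucleosome_model <- function(window_length = NULL, K = NULL,
                                 theta0 = NULL, kappa = NULL,
                                 amplitude = NULL, period = NULL,
                                 phase = NULL, lambda = NULL, beta = NULL,
                                 params = toy_default_params()) {
  p <- params
  p$window_length <- window_length %||% p$window_length
  p$K <- K %||% p$K
  p$theta0 <- theta0 %||% p$theta0
  p$kappa <- kappa %||% p$kappa
  p$amplitude <- amplitude %||% p$amplitude
  p$period <- period %||% p$period
  p$phase <- phase %||% p$phase
  p$lambda <- lambda %||% p$lambda
  p$beta <- beta %||% p$beta

  L <- as.integer(p$window_length)
  stopifnot(L >= 2L, length(p$K) == 16L, length(p$theta0) == 16L,
            all(p$K > 0), p$kappa >= 0, p$lambda >= 0, p$beta > 0,
            p$period > 0)
  dn <- kmer_names(2L)
  if (!is.null(names(p$K))) p$K <- p$K[dn]
  if (!is.null(names(p$theta0))) p$theta0 <- p$theta0[dn]
  steps <- 0:(L - 2L)
  cprof <- p$amplitude * cos(2 * pi * steps / p$period + p$phase)
  structure(
    list(window_length = L, K = unname(p$K), theta0 = unname(p$theta0),
         kappa = p$kappa, amplitude = p$amplitude, period = p$period,
         phase = p$phase, lambda = p$lambda, beta = p$beta, kT = 1 / p$beta,
         cprof = cprof),
    class = "toy_nucleosome"
  )
}

#' @export
print.toy_nucleosome <- function(x, ...) {
  cat("Toy quadratic nucleosome model\n")
  cat("  window: ", x$window_length, " bp (", x$window_length - 1L,
      " step angles)\n", sep = "")
  cat(sprintf("  K in [%.2f, %.2f], kappa = %.3g, lambda = %.3g\n",
              min(x$K), max(x$K), x$kappa, x$lambda))
  cat(sprintf("  constraint: %.3g * cos(2 pi n / %.3g + %.3g)\n",
              x$amplitude, x$period, x$phase))
  cat(sprintf("  beta = %.3g (kT = %.4g kT_room)\n", x$beta, x$kT))
  invisible(x)
}

#' Toy-model energy of a (sequence, configuration) pair
#'
#' `E(S, theta) = sum_n 0.5 K(d_n) (theta_n - theta0(d_n))^2
#'              + 0.5 kappa (theta_n - c_n)^2
#'              + sum_n 0.5 lambda (theta_{n+1} - theta_n)^2`.
#'
#' @param model a [toy_nucleosome_model()]
#' @param seq a single sequence of the model's window length
#' @param theta numeric vector of `window_length - 1` step angles
#' @return scalar energy (kT_room units)
#' @export
toy_energy <- function(model, seq, theta) {
  stopifnot(inherits(model, "toy_nucleosome"))
  codes <- if (is.character(seq)) encode_seq(seq) else as.integer(seq)
  L <- model$window_length
  stopifnot(length(codes) == L, length(theta) == L - 1L)
  d <- codes[-L] * 4L + codes[-1L]
  E <- sum(0.5 * model$K[d + 1L] * (theta - model$theta0[d + 1L])^2 +
           0.5 * model$kappa * (theta - model$cprof)^2)
  if (model$lambda > 0 && length(theta) >= 2L)
    E <- E + sum(0.5 * model$lambda * diff(theta)^2)
  E
}

# Gaussian statistics (E(theta*), log det M) for each row of a code matrix.
toy_gaussian_stats <- function(model, codes) {
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1L)
  storage.mode(codes) <- "integer"
  toy_gaussian_stats_cpp(codes, model$K, model$theta0, model$kappa,
                         model$cprof, model$lambda)
}

#' Exact free energy of sequences under the toy model
#'
#' Closed-form Gaussian marginalization of the configurational degrees of
#' freedom: with `E = 0.5 theta' M theta - b' theta + c0`,
#' `F(S) = E(theta*) - (kT/2) * ((L-1) log(2 pi kT) - log det M)` where
#' `theta* = M^{-1} b` and `E(theta*) = c0 - 0.5 b' M^{-1} b`.  With
#' `lambda = 0` this reduces to a sum of per-step terms (see
#' [toy_step_free_energies()]).
#'
#' @param model a [toy_nucleosome_model()]
#' @param seqs character vector of sequences or integer code matrix
#' @return numeric vector of free energies in kT_room units
#' @export
exact_free_energy <- function(model, seqs) {
  stopifnot(inherits(model, "toy_nucleosome"))
  codes <- encode_ensemble(seqs)
  st <- toy_gaussian_stats(model, codes)
  ns <- model$window_length - 1L
  kT <- model$kT
  st[, 1L] - (kT / 2) * (ns * log(2 * pi * kT) - st[, 2L])
}

#' @rdname free_energy
#' @details For a `toy_nucleosome` model, `free_energy()` is the exact
#'   Gaussian result of [exact_free_energy()].
#' @export
free_energy.toy_nucleosome <- function(model, seqs, ...) {
  exact_free_energy(model, seqs)
}

#' Exact thermal mean energy of a wrapped sequence
#'
#' For a quadratic energy, equipartition gives
#' `<E>_S = E(S, theta*) + (L - 1) * kT / 2` exactly.
#'
#' @inheritParams exact_free_energy
#' @return numeric vector of mean energies in kT_room units
#' @export
exact_mean_energy <- function(model, seqs) {
  stopifnot(inherits(model, "toy_nucleosome"))
  codes <- encode_ensemble(seqs)
  st <- toy_gaussian_stats(model, codes)
  st[, 1L] + (model$window_length - 1L) * model$kT / 2
}

#' Per-step free energies of the nearest-neighbour toy model
#'
#' With `lambda = 0` the free energy decomposes as
#' `F(S) = sum_n f_n(d_n)` with
#' `f_n(d) = 0.5 * Keff(d) * (theta0(d) - c_n)^2
#'         + (kT/2) * log((K(d) + kappa) / (2 pi kT))`,
#' `Keff = K * kappa / (K + kappa)`.  This is the exact per-(position, step)
#' energy table that defines the toy sequence distribution as a Markov field.
#'
#' @param model a [toy_nucleosome_model()] with `lambda = 0`
#' @return numeric matrix `(window_length - 1) x 16` of `f_n(d)` in kT_room
#' @export
toy_step_free_energies <- function(model) {
  stopifnot(inherits(model, "toy_nucleosome"))
  if (model$lambda != 0)
    stop("per-step decomposition requires lambda = 0")
  kT <- model$kT
  Keff <- model$K * model$kappa / (model$K + model$kappa)
  ent <- (kT / 2) * log((model$K + model$kappa) / (2 * pi * kT))
  # outer over (step position, dinucleotide)
  f <- outer(model$cprof, model$theta0, function(cn, t0) (t0 - cn)^2)
  sweep(f, 2L, 0.5 * Keff, `*`) + rep(ent, each = length(model$cprof))
}

#' MMC / MC sampler configuration
#'
#' @param n_samples number of recorded sequences (or energy samples)
#' @param burn_in_sweeps sweeps (one sweep = `window_length` elementary
#'   moves) discarded before recording
#' @param thinning_sweeps sweeps between recorded samples
#' @param mutation_fraction probability that an elementary move is a
#'   single-base mutation rather than a spatial perturbation (must be in
#'   (0, 1) for MMC; forced to 0 for fixed-sequence MC)
#' @param spatial_step half-width of the uniform spatial proposal
#' @param seed integer seed for the sampler's own RNG stream
#' @return list of class `mmc_config`
#' @export
mmc_config <- function(n_samples, burn_in_sweeps = 200L,
                       thinning_sweeps = 10L, mutation_fraction = 0.5,
                       spatial_step = 0.15, seed = 1L) {
  stopifnot(n_samples >= 1, burn_in_sweeps >= 0, thinning_sweeps >= 1,
            mutation_fraction >= 0, mutation_fraction < 1,
            spatial_step > 0)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in_sweeps = as.integer(burn_in_sweeps),
                 thinning_sweeps = as.integer(thinning_sweeps),
                 mutation_fraction = mutation_fraction,
                 spatial_step = spatial_step,
                 seed = as.integer(seed)),
            class = "mmc_config")
}

#' Sample nucleosome-favoured sequences by Mutation Monte Carlo
#'
#' Runs a Metropolis chain over joint (sequence, configuration) space:
#' elementary moves are either a spatial perturbation of one step angle
#' (uniform in `+- spatial_step`) or the mutation of one base to a uniformly
#' chosen alternative, selected with probability `mutation_fraction`.  Both
#' proposals are symmetric, so the chain satisfies detailed balance with
#' respect to `exp(-beta E(S, theta))`; recording only the sequences
#' marginalizes the configurational degrees of freedom and samples the
#' Boltzmann sequence distribution `P(S)`.
#'
#' @param model a [toy_nucleosome_model()]
#' @param config an [mmc_config()] (with `0 < mutation_fraction < 1`)
#' @param as `"character"` for a vector of sequence strings, `"matrix"` for
#'   the raw integer code matrix (much faster to retrain on)
#' @return ensemble of `config$n_samples` sequences
#' @export
mmc_sample <- function(model, config, as = c("character", "matrix")) {
  stopifnot(inherits(model, "toy_nucleosome"), inherits(config, "mmc_config"))
  as <- match.arg(as)
  if (config$mutation_fraction <= 0)
    stop("MMC requires mutation_fraction > 0 (use mc_mean_energy for ",
         "fixed-sequence chains)")
  codes <- mmc_sample_cpp(model$window_length, model$K, model$theta0,
                          model$kappa, model$cprof, model$lambda, model$beta,
                          config$mutation_fraction, config$spatial_step,
                          config$n_samples, config$burn_in_sweeps,
                          config$thinning_sweeps, config$seed)
  if (as == "matrix") codes else decode_ensemble(codes)
}

#' Monte Carlo estimate of the mean wrapped energy of one sequence
#'
#' Spatial-only Metropolis chain over the step angles of a fixed sequence;
#' the time average of `E(S, theta)` after burn-in estimates `<E>_S`.  The
#' standard error is computed by batch means.
#'
#' @param model a [toy_nucleosome_model()]
#' @param seq a single sequence of the model's window length
#' @param config an [mmc_config()]; its `mutation_fraction` is ignored
#'   (spatial moves only)
#' @param n_batches number of batches for the batch-means standard error
#' @return list with `estimate`, `se`, `n_samples`
#' @export
mc_mean_energy <- function(model, seq, config, n_batches = 50L) {
  stopifnot(inherits(model, "toy_nucleosome"), inherits(config, "mmc_config"))
  codes <- if (is.character(seq)) encode_seq(seq) else as.integer(seq)
  stopifnot(length(codes) == model$window_length)
  e <- mc_energy_samples_cpp(codes, model$K, model$theta0, model$kappa,
                             model$cprof, model$lambda, model$beta,
                             config$spatial_step, config$n_samples,
                             config$burn_in_sweeps, config$thinning_sweeps,
                             config$seed)
  nb <- min(n_batches, length(e))
  bsize <- length(e) %/% nb
  bm <- vapply(seq_len(nb), function(b)
    mean(e[((b - 1L) * bsize + 1L):(b * bsize)]), numeric(1))
  list(estimate = mean(e[seq_len(nb * bsize)]),
       se = sd(bm) / sqrt(nb),
       n_samples = length(e))
}

#' Exact position-specific k-mer marginals of the toy sequence distribution
#'
#' For `lambda = 0` the sequence distribution is
#' `P(S) propto prod_n exp(-beta f_n(d_n))` (see
#' [toy_step_free_energies()]), an inhomogeneous nearest-neighbour Markov
#' field.  Forward-backward products of 4x4 transfer matrices give its exact
#' position-specific k-mer marginals.
#'
#' @param model a [toy_nucleosome_model()] with `lambda = 0`
#' @param k oligonucleotide length (1, 2 or 3 typically)
#' @return a [position_oligo_table()] (`n_sequences = NA`: analytic table)
#' @export
transfer_matrix_marginals <- function(model, k = 2L) {
  stopifnot(inherits(model, "toy_nucleosome"))
  if (model$lambda != 0)
    stop("transfer-matrix marginals require lambda = 0; use brute-force ",
         "enumeration at small window length for lambda > 0")
  k <- as.integer(k)
  L <- model$window_length
  stopifnot(k >= 1L, k <= L)
  f <- toy_step_free_energies(model)          # (L-1) x 16
  ns <- L - 1L
  # scaled transfer matrices Psi_n[a, b] = exp(-beta * (f_n(ab) - min f_n))
  Psi <- lapply(seq_len(ns), function(n) {
    m <- matrix(exp(-model$beta * (f[n, ] - min(f[n, ]))), 4L, 4L,
                byrow = TRUE)            # row = first base (most significant)
    m
  })
  # forward and backward messages, rescaled to avoid under/overflow
  alpha <- matrix(0, L, 4L); beta_m <- matrix(0, L, 4L)
  alpha[1L, ] <- 0.25
  for (n in seq_len(ns)) {
    v <- drop(alpha[n, ] %*% Psi[[n]])
    alpha[n + 1L, ] <- v / sum(v)
  }
  beta_m[L, ] <- 0.25
  for (n in rev(seq_len(ns))) {
    v <- drop(Psi[[n]] %*% beta_m[n + 1L, ])
    beta_m[n, ] <- v / sum(v)
  }
  npos <- L - k + 1L
  prob <- matrix(0, npos, 4L^k)
  kgrid <- as.matrix(expand.grid(rep(list(0:3), k)))  # col 1 varies fastest
  # column t of the table's k-mer code: base t has weight 4^(k-t); kgrid's
  # fastest column is the last base, so reorder
  bases <- kgrid[, rev(seq_len(k)), drop = FALSE]     # bases[, t] = t-th base
  codes_id <- as.integer(bases %*% 4L^((k - 1L):0L))
  for (j in seq_len(npos)) {
    w <- alpha[j, bases[, 1L] + 1L]
    if (k > 1L) for (t in seq_len(k - 1L)) {
      w <- w * Psi[[j + t - 1L]][cbind(bases[, t] + 1L, bases[, t + 1L] + 1L)]
    }
    w <- w * beta_m[j + k - 1L, bases[, k] + 1L]
    prob[j, codes_id + 1L] <- w / sum(w)
  }
  position_oligo_table(prob, k = k, window_length = L,
                       n_sequences = NA_real_)
}

#' Write / read toy-model parameters as JSON
#' @param model a [toy_nucleosome_model()]
#' @param path JSON path
#' @return `path` invisibly ([write_toy_params()]); a model
#'   ([read_toy_params()])
#' @export
write_toy_params <- function(model, path) {
  stopifnot(inherits(model, "toy_nucleosome"))
  dn <- kmer_names(2L)
  x <- list(window_length = model$window_length,
            K = as.list(setNames(model$K, dn)),
            theta0 = as.list(setNames(model$theta0, dn)),
            kappa = model$kappa, amplitude = model$amplitude,
            period = model$period, phase = model$phase,
            lambda = model$lambda, beta = model$beta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_toy_params
#' @export
read_toy_params <- function(path) {
  toy_nucleosome_model(params = toy_default_params(path))
}
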