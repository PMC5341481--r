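# RMSD benchmarking of approximate landscapes against a reference.
#
# Model quality is summarized by three RMSDs — full signal, 11-bp local
# average, periodic component — each expressed relative to an
# information-free "bad model": a uniform landscape for the full and
# averaged signals, and the reference's own periodic signal pushed out of
# phase by half a period (5 bp) for the periodicity.

#' Root-mean-square deviation between two landscapes
#'
#' Computed over the positions the two landscapes share.
#'
#' @param a,b [energy_landscape()] objects with at least one common position
#' @return RMSD in kT
#' @export
rmsd <- function(a, b) {
  stopifnot(inherits(a, "energy_landscape"), inherits(b, "energy_landscape"))
  common <- intersect(a$positions, b$positions)
  if (length(common) == 0L)
    stop("landscapes share no positions")
  av <- a$values[match(common, a$positions)]
  bv <- b$values[match(common, b$positions)]
  sqrt(mean((av - bv)^2))
}

# Boltzmann-normalized uniform landscape over the same positions: the
# "no sequence information" bad model (constant kT log N after
# normalization).
uniform_landscape <- function(reference) {
  normalize_landscape(
    energy_landscape(reference$positions,
                     rep(0, length(reference$positions)),
                     kT = reference$kT, source = "uniform"))
}

#' Bad-model baseline RMSDs for a reference landscape
#'
#' * `bad_full`: RMSD between the (normalized) reference and a
#'   Boltzmann-normalized uniform landscape over the same positions;
#' * `bad_avg`: the same comparison after 11-bp local averaging;
#' * `bad_periodic`: RMSD between the reference's periodic component and the
#'   same signal shifted by half a period (`round(period/2)` positions,
#'   5 bp for the ~10-bp nucleosomal periodicity), i.e. pushed out of phase.
#'
#' These set the scale of the structure in the landscape that a model must
#' predict; model RMSDs are reported relative to them.
#'
#' @param reference an [energy_landscape()] (normalized; normalization is
#'   applied if missing) with at least 11 + shift positions
#' @param period helical period in bp (shift is `round(period/2)`)
#' @param avg_window local-average width
#' @return named numeric vector `c(bad_full, bad_avg, bad_periodic)` in kT
#' @export
bad_model_baselines <- function(reference, period = 10, avg_window = 11L) {
  stopifnot(inherits(reference, "energy_landscape"))
  if (!reference$normalized) reference <- normalize_landscape(reference)
  unif <- uniform_landscape(reference)
  pc <- periodic_component(reference, window = avg_window)
  shift <- as.integer(round(period / 2))
  c(bad_full = rmsd(reference, unif),
    bad_avg = rmsd(local_average(reference, avg_window),
                   local_average(unif, avg_window)),
    bad_periodic = rmsd(pc, shift_landscape(pc, shift)))
}

#' Benchmark an approximate landscape against a reference
#'
#' Both landscapes are Boltzmann-normalized (idempotent if already done),
#' then compared by RMSD on the full signal, the 11-bp local average and the
#' periodic component; each RMSD is also expressed as a percentage of the
#' corresponding bad-model baseline derived from the reference.
#'
#' @param approx,reference [energy_landscape()] objects
#' @param period helical period in bp for the out-of-phase baseline
#' @param avg_window local-average width in positions
#' @param label model label carried into the report
#' @return object of class `benchmark_report`: list with `rmsd_full`,
#'   `rmsd_avg`, `rmsd_periodic`, `bad_full`, `bad_avg`, `bad_periodic`
#'   (kT), `rel_full`, `rel_avg`, `rel_periodic` (percent), `n_windows`,
#'   `model_label`
#' @export
benchmark_model <- function(approx, reference, period = 10, avg_window = 11L,
                            label = approx$source) {
  stopifnot(inherits(approx, "energy_landscape"),
            inherits(reference, "energy_landscape"))
  common <- intersect(approx$positions, reference$positions)
  if (length(common) < avg_window)
    stop("need at least ", avg_window, " common positions")
  # restrict to common positions first, then normalize both over that set
  take <- function(ls) normalize_landscape(
    energy_landscape(common, ls$values[match(common, ls$positions)],
                     kT = ls$kT, source = ls$source))
  a <- take(approx)
  r <- take(reference)
  bad <- bad_model_baselines(r, period = period, avg_window = avg_window)
  res <- c(rmsd_full = rmsd(a, r),
           rmsd_avg = rmsd(local_average(a, avg_window),
                           local_average(r, avg_window)),
           rmsd_periodic = rmsd(periodic_component(a, avg_window),
                                periodic_component(r, avg_window)))
  rel <- ifelse(bad > 0, 100 * res / bad, NA_real_)
  structure(
    list(rmsd_full = unname(res[1L]), rmsd_avg = unname(res[2L]),
         rmsd_periodic = unname(res[3L]),
         bad_full = unname(bad[1L]), bad_avg = unname(bad[2L]),
         bad_periodic = unname(bad[3L]),
         rel_full = unname(rel[1L]), rel_avg = unname(rel[2L]),
         rel_periodic = unname(rel[3L]),
         n_windows = length(common), model_label = label),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report", if (nzchar(x$model_label))
    paste0(" [", x$model_label, "]"), " (", x$n_windows, " windows)\n",
    sep = "")
  row <- function(name, r, b, p)
    cat(sprintf("  %-9s RMSD %8.4f kT   bad %8.4f kT   rel %6.1f%%\n",
                name, r, b, p))
  row("full", x$rmsd_full, x$bad_full, x$rel_full)
  row("average", x$rmsd_avg, x$bad_avg, x$rel_avg)
  row("periodic", x$rmsd_periodic, x$bad_periodic, x$rel_periodic)
  invisible(x)
}

#' @export
as.data.frame.benchmark_report <- function(x, ...) {
  data.frame(model = x$model_label,
             signal = c("full", "average", "periodic"),
             rmsd_kT = c(x$rmsd_full, x$rmsd_avg, x$rmsd_periodic),
             bad_kT = c(x$bad_full, x$bad_avg, x$bad_periodic),
             rel_percent = c(x$rel_full, x$rel_avg, x$rel_periodic),
             stringsAsFactors = FALSE)
}

#' RMSD versus training-ensemble size
#'
#' For each combination of subset size, Markov order and zero-probability
#' policy: subsample the ensemble (the same subset is reused across orders
#' and policies at a given size), fit the model, score the genome, normalize
#' and compute the full-signal RMSD against the reference landscape.
#' Deterministic given `seed`.
#'
#' @param ensemble training ensemble (character vector or code matrix)
#' @param sizes integer vector of subset sizes (each `<=` ensemble size)
#' @param orders integer vector of Markov orders
#' @param policies subset of `c("flat_quarter", "smoothed")`:
#'   `"flat_quarter"` trains on raw tables with the flat-0.25 fallback,
#'   `"smoothed"` trains on 3-bp position-smoothed tables
#' @param genome genome sequence to score
#' @param reference reference [energy_landscape()]
#' @param seed integer seed driving the subsampling
#' @param width window width
#' @return data.frame with columns `size`, `order`, `policy`, `rmsd_full`,
#'   `rel_full`, `n_zero_cells`
#' @export
ensemble_size_sweep <- function(ensemble, sizes, orders,
                                policies = c("flat_quarter", "smoothed"),
                                genome, reference, seed = 1L, width = 147L) {
  policies <- match.arg(policies, c("flat_quarter", "smoothed"),
                        several.ok = TRUE)
  N <- if (is.matrix(ensemble)) nrow(ensemble) else length(ensemble)
  if (max(sizes) > N)
    stop("max(sizes) = ", max(sizes), " exceeds ensemble size ", N)
  rows <- list()
  for (si in seq_along(sizes)) {
    sub <- subsample(ensemble, sizes[si],
                     seed = substream_seed(seed, paste0("subsample", si)))
    for (ord in orders) {
      for (pol in policies) {
        fit <- markov_fit(sub, order = ord, smooth = (pol == "smoothed"),
                          zero_policy = if (pol == "smoothed") "smoothed"
                                        else "flat_quarter",
                          kT = reference$kT)
        ls <- compute_landscape(genome, fit, width = width)
        rep_ <- benchmark_model(ls, reference)
        rows[[length(rows) + 1L]] <- data.frame(
          size = sizes[si], order = ord, policy = pol,
          rmsd_full = rep_$rmsd_full, rel_full = rep_$rel_full,
          n_zero_cells = fit$n_zero_cells, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Scatter comparison of two landscapes
#'
#' Density scatter (base `smoothScatter`) of approximate versus reference
#' window energies with the identity diagonal, the per-window view behind
#' the full-signal RMSD.
#'
#' @param approx,reference [energy_landscape()] objects (normalized
#'   internally)
#' @param ... passed to [graphics::smoothScatter()]
#' @return invisibly, the data.frame of paired energies
#' @export
plot_landscape_comparison <- function(approx, reference, ...) {
  common <- intersect(approx$positions, reference$positions)
  a <- normalize_landscape(energy_landscape(
    common, approx$values[match(common, approx$positions)], kT = approx$kT))
  r <- normalize_landscape(energy_landscape(
    common, reference$values[match(common, reference$positions)],
    kT = reference$kT))
  df <- data.frame(reference = r$values, approx = a$values)
  graphics::smoothScatter(df$reference, df$approx,
                          xlab = "reference energy (kT)",
                          ylab = "approximate energy (kT)", ...)
  graphics::abline(0, 1)
  invisible(df)
}
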