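# End-to-end orchestration: simulate -> train -> landscape -> benchmark.

#' Run the full benchmarking pipeline
#'
#' Generates (or loads) a training ensemble from the toy nucleosome model by
#' Mutation Monte Carlo, fits Markov models of the requested orders, scores
#' a genome into energy landscapes, and benchmarks each against the toy
#' model's exact mean-energy landscape.  All randomness flows from the
#' single `seed` through named per-stage substreams, so stages are
#' independently reproducible.
#'
#' @param seed single integer master seed
#' @param outdir optional output directory; when given, the ensemble
#'   (FASTA), landscapes (TSV), reports (JSON) and a provenance record are
#'   written there
#' @param toy a [toy_nucleosome_model()]; defaults to the shipped parameters
#'   with the given `lambda`
#' @param lambda nearest-step coupling used when `toy` is not supplied
#' @param genome_length length of the random genome to score (bp)
#' @param ensemble_size number of MMC-sampled training sequences
#' @param orders Markov orders to fit and benchmark
#' @param smooth train on 3-bp smoothed tables
#' @param burn_in_sweeps,thinning_sweeps,mutation_fraction,spatial_step MMC
#'   settings, see [mmc_config()]
#' @return invisibly, a list with `toy`, `genome`, `ensemble` (code
#'   matrix), `reference` (exact mean-energy landscape), `landscapes` (one
#'   per order), `reports` (one [benchmark_model()] report per order) and
#'   `files` (paths written, if any)
#' @export
run_pipeline <- function(seed = 1L, outdir = NULL, toy = NULL, lambda = 0,
                         genome_length = 5000L, ensemble_size = 20000L,
                         orders = c(0L, 1L, 2L), smooth = FALSE,
                         burn_in_sweeps = 200L, thinning_sweeps = 10L,
                         mutation_fraction = 0.5, spatial_step = 0.15) {
  if (is.null(toy)) toy <- toy_nucleosome_model(lambda = lambda)
  genome <- random_genome(genome_length,
                          seed = substream_seed(seed, "genome"))
  cfg <- mmc_config(n_samples = ensemble_size,
                    burn_in_sweeps = burn_in_sweeps,
                    thinning_sweeps = thinning_sweeps,
                    mutation_fraction = mutation_fraction,
                    spatial_step = spatial_step,
                    seed = substream_seed(seed, "mmc"))
  ensemble <- mmc_sample(toy, cfg, as = "matrix")
  reference <- normalize_landscape(
    compute_landscape(genome, toy, what = "mean_energy"))

  landscapes <- list()
  reports <- list()
  for (ord in orders) {
    fit <- markov_fit(ensemble, order = ord, smooth = smooth, kT = toy$kT)
    ls <- normalize_landscape(compute_landscape(genome, fit))
    landscapes[[as.character(ord)]] <- ls
    reports[[as.character(ord)]] <- benchmark_model(ls, reference)
  }

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(setNames(genome, "genome"),
                file.path(outdir, "genome.fasta"))
    write_fasta(decode_ensemble(ensemble),
                file.path(outdir, "ensemble.fasta"))
    write_landscape(reference, file.path(outdir, "reference.tsv"))
    for (ord in names(landscapes))
      write_landscape(landscapes[[ord]],
                      file.path(outdir, paste0("landscape_order", ord,
                                               ".tsv")))
    jsonlite::write_json(lapply(reports, unclass),
                         file.path(outdir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_provenance(file.path(outdir, "provenance.json"),
                     list(command = "run_pipeline", seed = seed,
                          lambda = toy$lambda, beta = toy$beta,
                          genome_length = genome_length,
                          ensemble_size = ensemble_size,
                          orders = orders, smooth = smooth))
    files <- list.files(outdir, full.names = TRUE)
  }
  invisible(list(toy = toy, genome = genome, ensemble = ensemble,
                 reference = reference, landscapes = landscapes,
                 reports = reports, files = files))
}

# Provenance record written next to every CLI/pipeline output.
write_provenance <- function(path, config) {
  rec <- list(
    config = config,
    package = "nucleomark",
    version = as.character(utils::packageVersion("nucleomark")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
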