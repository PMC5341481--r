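test_that("toy energy matches a term-by-term reference and its ground state", {
  toy <- test_toy(5, lambda = 2)
  set.seed(51)
  for (i in 1:10) {
    codes <- sample(0:3, 5, replace = TRUE)
    theta <- runif(4, -0.5, 0.5)
    expect_equal(toy_energy(toy, codes, theta),
                 oracle_toy_energy(toy, codes, theta), tolerance = 1e-12)
  }

  # kappa = 0, lambda = 0: theta at the intrinsic angles gives E = 0
  toy0 <- test_toy(6, kappa = 0, lambda = 0)
  codes <- encode_seq("ACGTAC")
  d <- 4 * codes[-6] + codes[-1]
  expect_equal(toy_energy(toy0, codes, toy0$theta0[d + 1]), 0,
               tolerance = 1e-12)

  # uniform K, theta0 = 0, theta = 0: E = 0.5 kappa sum c_n^2, any sequence
  toyu <- toy_nucleosome_model(window_length = 6, K = rep(10, 16),
                               theta0 = rep(0, 16), kappa = 20, lambda = 0)
  expect_equal(toy_energy(toyu, codes, rep(0, 5)),
               0.5 * 20 * sum(toyu$cprof^2), tolerance = 1e-12)
  expect_equal(toy_energy(toyu, encode_seq("TTTTTT"), rep(0, 5)),
               toy_energy(toyu, codes, rep(0, 5)), tolerance = 1e-15)
})

test_that("exact free energy agrees between tridiagonal and dense routes", {
  for (lam in c(0, 4)) {
    toy <- test_toy(9, lambda = lam)
    codes <- encode_ensemble(random_ensemble(15, 9, seed = 52))
    got <- exact_free_energy(toy, codes)
    ref <- apply(codes, 1, oracle_dense_free_energy, model = toy)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("lambda=0 free energy decomposes into per-step terms", {
  toy <- test_toy(10)
  codes <- encode_ensemble(random_ensemble(20, 10, seed = 53))
  f <- toy_step_free_energies(toy)
  ref <- apply(codes, 1, function(s) {
    d <- 4 * s[-10] + s[-1]
    sum(f[cbind(1:9, d + 1)])
  })
  expect_equal(exact_free_energy(toy, codes), ref, tolerance = 1e-10)
})

test_that("kappa=0, lambda=0 free energy depends only on dinucleotide composition", {
  toy <- test_toy(7, kappa = 0, lambda = 0)
  # distinct Eulerian orderings of the same dinucleotide (edge) multiset
  a <- "ACGACTA"    # dinucs: AC CG GA AC CT TA
  b <- "ACTACGA"    # dinucs: AC CT TA AC CG GA  (same multiset)
  da <- sort(substring(a, 1:6, 2:7))
  db <- sort(substring(b, 1:6, 2:7))
  expect_identical(da, db)
  expect_equal(exact_free_energy(toy, a), exact_free_energy(toy, b),
               tolerance = 1e-10)
})

test_that("free energy approaches the energy minimum at low temperature", {
  toy_cold <- test_toy(7, lambda = 1, beta = 1e6)   # kT = 1e-6
  codes <- encode_seq("ACGTTGA")
  Fc <- exact_free_energy(toy_cold, codes)
  emin_num <- optim(rep(0, 6), function(th) toy_energy(toy_cold, codes, th),
                    method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 1000))$value
  expect_equal(Fc, emin_num, tolerance = 1e-3)
  # equipartition: <E>_S - E(theta*) = (L-1) kT / 2 exactly
  emin <- exact_mean_energy(toy_cold, codes) - 6 * toy_cold$kT / 2
  expect_equal(emin, emin_num, tolerance = 1e-3)
  toy_warm <- test_toy(7, lambda = 1, beta = 2)
  emin_warm <- optim(rep(0, 6), function(th) toy_energy(toy_warm, codes, th),
                     method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 1000))$value
  expect_equal(exact_mean_energy(toy_warm, codes),
               emin_warm + 6 * toy_warm$kT / 2, tolerance = 1e-6)
})

test_that("plain MC mean energy matches the equipartition closed form", {
  toy <- test_toy(20, beta = 2)     # kT = 0.5
  seqs <- random_ensemble(3, 20, seed = 54)
  for (s in seqs) {
    est <- mc_mean_energy(toy, s, mmc_config(20000, burn_in_sweeps = 200,
                                             thinning_sweeps = 2,
                                             spatial_step = 0.6, seed = 55))
    expect_lt(abs(est$estimate - exact_mean_energy(toy, s)), 3 * est$se)
  }
  # determinism
  e1 <- mc_mean_energy(toy, seqs[1], mmc_config(2000, seed = 7))
  e2 <- mc_mean_energy(toy, seqs[1], mmc_config(2000, seed = 7))
  expect_identical(e1$estimate, e2$estimate)
  # zero-temperature limit: the chain collapses onto the energy minimum
  cold <- test_toy(20, beta = 1e4)
  est <- mc_mean_energy(cold, seqs[1],
                        mmc_config(5000, burn_in_sweeps = 2000,
                                   thinning_sweeps = 1,
                                   spatial_step = 0.01, seed = 8))
  emin <- exact_mean_energy(cold, seqs[1]) - 19 * cold$kT / 2
  expect_lt(abs(est$estimate - emin), 0.01)
})

test_that("transfer-matrix marginals are exact at small window length", {
  toy <- test_toy(8)
  all8 <- enumerate_codes(8)
  lp <- oracle_toy_logp(toy, all8)
  p <- exp(lp)
  for (k in 1:3) {
    tm <- transfer_matrix_marginals(toy, k)
    expect_lt(max(abs(rowSums(tm$prob) - 1)), 1e-12)
    # brute-force marginals over all 4^8 sequences
    for (pos in c(1, 4, 8 - k + 1)) {
      ids <- rep(0L, nrow(all8))
      for (t in seq_len(k)) ids <- ids + all8[, pos + t - 1] * 4L^(k - t)
      bf <- vapply(0:(4^k - 1), function(w) sum(p[ids == w]), numeric(1))
      expect_equal(tm$prob[pos, ], bf, tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
  expect_error(transfer_matrix_marginals(test_toy(8, lambda = 1)),
               "lambda = 0")
})

test_that("a sequence-independent model has uniform marginals and MMC output", {
  toyu <- toy_nucleosome_model(window_length = 10, K = rep(15, 16),
                               theta0 = rep(0.1, 16), kappa = 20)
  tm <- transfer_matrix_marginals(toyu, 2)
  expect_lt(max(abs(tm$prob - 1 / 16)), 1e-12)
  ens <- mmc_sample(toyu, mmc_config(5000, seed = 56), as = "matrix")
  emp <- count_oligos(ens, 1)$prob
  expect_gt(mean(abs(emp - 0.25) < 4 * sqrt(0.25 * 0.75 / 5000)), 0.95)
})

test_that("MMC sampling reproduces the exact sequence distribution", {
  toy <- test_toy(10)
  ens <- mmc_sample(toy, mmc_config(20000, seed = 57), as = "matrix")
  expect_identical(dim(ens), c(20000L, 10L))
  # same seed, same ensemble
  ens2 <- mmc_sample(toy, mmc_config(20000, seed = 57), as = "matrix")
  expect_identical(ens, ens2)
  emp <- count_oligos(ens, 2)
  tm <- transfer_matrix_marginals(toy, 2)
  se <- sqrt(pmax(tm$prob * (1 - tm$prob) / 20000, 1e-12))
  expect_gt(mean(abs(emp$prob - tm$prob) < 4 * se), 0.95)
})

test_that("the order-1 model built from exact marginals reproduces exact P(S)", {
  toy <- test_toy(8)
  fit <- markov_model(transfer_matrix_marginals(toy, 2),
                      zero_policy = "strict", kT = toy$kT)
  all8 <- enumerate_codes(8)
  lp_true <- oracle_toy_logp(toy, all8)
  lp_fit <- log_probability(fit, all8)
  dev <- lp_fit - lp_true
  expect_lt(max(abs(dev - mean(dev))), 1e-8)
  # relative error of probabilities after removing the constant
  expect_lt(max(abs(exp(dev - mean(dev)) - 1)), 1e-8)
})

test_that("toy parameter files round-trip", {
  toy <- toy_nucleosome_model(window_length = 30, lambda = 2.5, beta = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_toy_params(toy, path)
  back <- read_toy_params(path)
  expect_equal(back$K, toy$K, tolerance = 1e-12)
  expect_equal(back$theta0, toy$theta0, tolerance = 1e-12)
  expect_identical(back$window_length, 30L)
  expect_equal(back$lambda, 2.5)
  expect_equal(back$beta, 4)
  expect_equal(back$cprof, toy$cprof, tolerance = 1e-12)
})
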