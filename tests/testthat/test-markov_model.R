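test_that("uniform tables score every sequence at -L log 4 for all orders", {
  L <- 12L
  for (m in 0:2) {
    joint <- position_oligo_table(
      matrix(4^-(m + 1), L - m, 4^(m + 1)), k = m + 1L, window_length = L)
    fit <- markov_model(joint, zero_policy = "strict")
    seqs <- random_ensemble(5, L, seed = 31)
    expect_equal(log_probability(fit, seqs), rep(-L * log(4), 5),
                 tolerance = 1e-12)
    expect_equal(free_energy(fit, seqs), rep(L * log(4), 5),
                 tolerance = 1e-12)
  }
})

test_that("Markov scores equal the brute-force chain-rule product", {
  # window length 6, order 1, 50-sequence ensemble: check all 4^6 sequences
  ens <- encode_ensemble(random_ensemble(50, 6, seed = 32))
  fit <- markov_fit(ens, order = 1, zero_policy = "flat_quarter")
  all6 <- enumerate_codes(6)
  got <- log_probability(fit, all6)
  # compare on sequences whose every factor is observed (no policy firing)
  ref <- apply(all6, 1, function(s) oracle_chain_rule_logp(ens, 1, s))
  finite_ref <- is.finite(ref)
  expect_gt(sum(finite_ref), 2000)   # most sequences fully observed
  expect_equal(got[finite_ref], ref[finite_ref], tolerance = 1e-10)

  # order 2 on a smaller check set
  fit2 <- markov_fit(ens, order = 2)
  idx <- seq(1, 4^6, by = 37)
  ref2 <- apply(all6[idx, ], 1, function(s) oracle_chain_rule_logp(ens, 2, s))
  got2 <- log_probability(fit2, all6[idx, ])
  keep <- is.finite(ref2)
  expect_equal(got2[keep], ref2[keep], tolerance = 1e-10)
})

test_that("log-probabilities are never positive", {
  ens <- random_ensemble(100, 10, seed = 33)
  probes <- random_ensemble(50, 10, seed = 34)
  for (m in 0:2) {
    fit <- markov_fit(ens, order = m)
    expect_true(all(log_probability(fit, probes) <= 1e-12))
  }
})

test_that("a single-sequence ensemble concentrates all mass on itself", {
  s <- random_ensemble(1, 15, seed = 35)
  fit <- markov_fit(rep(s, 3), order = 1)
  expect_equal(log_probability(fit, s), 0, tolerance = 1e-12)
  other <- random_ensemble(1, 15, seed = 36)
  # every factor along `other` that differs triggers the flat 0.25 policy
  expect_lt(log_probability(fit, other), log(0.25) / 2)
  fit_strict <- markov_fit(rep(s, 3), order = 1, zero_policy = "strict")
  expect_error(log_probability(fit_strict, other),
               "ensemble failure: zero probability")
})

test_that("zero policy substitutes a flat conditional of 0.25 per affected position", {
  # ensemble where position 3 is always A: P(base != A at pos 3) = 0
  ens <- random_ensemble(40, 8, seed = 37)
  ens <- paste0(substr(ens, 1, 2), "A", substr(ens, 4, 8))
  fit0 <- markov_fit(ens, order = 0)
  probe_hit <- paste0(substr(ens[1], 1, 2), "C", substr(ens[1], 4, 8))
  probe_ref <- ens[1]
  # exactly one factor differs between the two scores: log P(A at 3) vs log 0.25
  d <- log_probability(fit0, probe_ref) - log_probability(fit0, probe_hit)
  pA <- count_oligos(ens, 1)$prob[3, "A"]
  expect_equal(d, log(pA) - log(0.25), tolerance = 1e-12)
})

test_that("policies agree whenever tables are strictly positive", {
  # big ensemble at tiny window: all dinucleotides observed everywhere
  ens <- random_ensemble(3000, 6, seed = 38)
  fits <- lapply(c("flat_quarter", "smoothed", "strict"), function(zp)
    markov_fit(ens, order = 1, zero_policy = zp))
  expect_identical(fits[[1]]$n_zero_cells, 0L)
  probes <- enumerate_codes(6)[seq(1, 4^6, by = 11), ]
  base <- log_probability(fits[[1]], probes)
  for (f in fits[-1])
    expect_equal(log_probability(f, probes), base, tolerance = 1e-14)
})

test_that("total probability telescopes to 1 for strictly positive models", {
  ens <- random_ensemble(4000, 7, seed = 39)
  all7 <- enumerate_codes(7)
  for (m in 0:2) {
    fit <- markov_fit(ens, order = m, zero_policy = "strict")
    expect_identical(fit$n_zero_cells, 0L)
    total <- exp(logsumexp_test(log_probability(fit, all7)))
    expect_lt(abs(total - 1), 1e-9)
  }
})

test_that("free energy scales linearly in kT and differences drop the offset", {
  ens <- random_ensemble(200, 10, seed = 40)
  probes <- random_ensemble(20, 10, seed = 41)
  f1 <- markov_fit(ens, order = 1, kT = 1)
  f2 <- markov_fit(ens, order = 1, kT = 2)
  expect_equal(free_energy(f2, probes), 2 * free_energy(f1, probes),
               tolerance = 1e-12)
  # offset invariance of differences
  e <- free_energy(f1, probes)
  expect_equal(diff(e), diff(e + 7.3), tolerance = 1e-12)
})

test_that("an order-m fit recovers the conditionals of its generating chain", {
  # generate from a known order-1 chain (a fitted model), refit, compare
  gen <- markov_fit(random_ensemble(500, 8, seed = 42), order = 1)
  draws <- simulate(gen, nsim = 20000, seed = 43)
  refit <- markov_fit(draws, order = 1)
  j0 <- gen$joint$prob
  j1 <- refit$joint$prob
  se <- sqrt(pmax(j0 * (1 - j0) / 20000, 1e-12))
  expect_gt(mean(abs(j1 - j0) < 4 * se), 0.99)
})

test_that("symmetrized fits are strand-symmetric and default fits are not", {
  ens <- random_ensemble(400, 10, seed = 48)
  probes <- random_ensemble(30, 10, seed = 49)
  rc <- unname(reverse_complement(probes))
  sym <- markov_fit(ens, order = 1, symmetrize = TRUE)
  expect_equal(log_probability(sym, probes), log_probability(sym, rc),
               tolerance = 1e-12)
  # the symmetrized joint table is invariant under (mirror position,
  # reverse-complement k-mer)
  J <- sym$joint$prob
  rcmap <- match(unname(reverse_complement(kmer_names(2))), kmer_names(2))
  expect_equal(J, J[nrow(J):1, rcmap], tolerance = 1e-12,
               ignore_attr = TRUE)
  asym <- markov_fit(ens, order = 1)
  expect_gt(max(abs(log_probability(asym, probes) -
                      log_probability(asym, rc))), 1e-6)
})

test_that("model directories round-trip through disk", {
  ens <- random_ensemble(150, 9, seed = 44)
  fit <- markov_fit(ens, order = 2, smooth = TRUE, kT = 1 / 6)
  dir <- withr::local_tempdir()
  write_markov_model(fit, dir)
  back <- read_markov_model(dir)
  probes <- random_ensemble(10, 9, seed = 45)
  expect_equal(log_probability(back, probes), log_probability(fit, probes),
               tolerance = 1e-12)
  expect_identical(back$order, fit$order)
  expect_identical(back$zero_policy, "smoothed")
  expect_true(back$smoothed)
  expect_equal(back$kT, 1 / 6)
})

test_that("simulated sequences match the fitted position-specific marginals", {
  gen <- markov_fit(random_ensemble(300, 8, seed = 46), order = 0)
  draws <- simulate(gen, nsim = 10000, seed = 47)
  emp <- count_oligos(draws, 1)$prob
  tgt <- gen$joint$prob
  se <- sqrt(pmax(tgt * (1 - tgt) / 10000, 1e-12))
  expect_gt(mean(abs(emp - tgt) < 4 * se), 0.95)
})
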