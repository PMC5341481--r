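test_that("landscape computation yields one value per scorable window", {
  g <- random_genome(200, seed = 61)
  # constant scorer
  ls <- compute_landscape(g, function(s) 3.5, width = 147)
  expect_identical(length(ls$values), 54L)
  expect_true(all(ls$values == 3.5))

  # Markov scorer with uniform tables: constant at 147 kT log 4
  joint <- position_oligo_table(matrix(0.0625, 146, 16), k = 2,
                                window_length = 147)
  fit <- markov_model(joint, zero_policy = "strict")
  lsm <- compute_landscape(g, fit)
  expect_equal(lsm$values, rep(147 * log(4), 54), tolerance = 1e-10)

  # the fast Markov path agrees with per-window scoring
  ens <- random_ensemble(500, 30, seed = 62)
  fit30 <- markov_fit(ens, order = 1)
  g2 <- random_genome(120, seed = 63)
  ls2 <- compute_landscape(g2, fit30)
  w <- windows(g2, width = 30)
  expect_equal(ls2$values, free_energy(fit30, w$seq), tolerance = 1e-12)
  expect_identical(ls2$positions, w$start)
})

test_that("N-containing windows are excluded from landscapes", {
  g <- paste0(random_genome(60, seed = 64), "N",
              random_genome(60, seed = 65))
  ens <- random_ensemble(200, 20, seed = 66)
  fit <- markov_fit(ens, order = 1)
  ls <- compute_landscape(g, fit, width = 20)
  expect_identical(attr(ls, "skipped"), 41:60)
  expect_false(any(ls$positions %in% 41:60))
  # values at unmasked windows equal direct scoring of those windows
  keep <- windows(g, width = 20)
  expect_equal(ls$values, free_energy(fit, keep$seq), tolerance = 1e-12)
})

test_that("toy-model landscapes use the exact closed forms per window", {
  toy <- test_toy(15, lambda = 3)
  g <- random_genome(80, seed = 67)
  w <- windows(g, width = 15)
  lsE <- compute_landscape(g, toy, what = "mean_energy")
  lsF <- compute_landscape(g, toy, what = "free_energy")
  expect_equal(lsE$values, exact_mean_energy(toy, w$seq), tolerance = 1e-10)
  expect_equal(lsF$values, exact_free_energy(toy, w$seq), tolerance = 1e-10)
  expect_equal(lsE$kT, toy$kT)
})

test_that("Boltzmann normalization is an idempotent pure shift", {
  set.seed(68)
  vals <- rnorm(40, mean = 5, sd = 2)
  ls <- energy_landscape(0:39, vals, kT = 1 / 6)
  n1 <- normalize_landscape(ls)
  # pure shift: pairwise differences preserved to machine precision
  expect_equal(diff(n1$values), diff(vals), tolerance = 1e-12)
  # normalization condition
  expect_lt(abs(logsumexp_test(-n1$values / n1$kT)), 1e-9)
  # idempotent
  n2 <- normalize_landscape(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-12)
  # constant landscape of N windows -> kT log N everywhere
  cl <- normalize_landscape(energy_landscape(0:9, rep(2, 10), kT = 0.5))
  expect_equal(cl$values, rep(0.5 * log(10), 10), tolerance = 1e-12)
  # landscapes differing by a constant coincide after normalization
  m1 <- normalize_landscape(energy_landscape(0:39, vals + 11.7, kT = 1 / 6))
  expect_equal(m1$values, n1$values, tolerance = 1e-12)
})

test_that("local average matches an independent moving average", {
  set.seed(69)
  vals <- cumsum(rnorm(60))
  ls <- energy_landscape(0:59, vals)
  la <- local_average(ls, 11)
  expect_identical(la$positions, 5:54)
  expect_equal(la$values, oracle_moving_average(vals, 11), tolerance = 1e-12)
  # constant landscape stays constant, 10 fewer points
  lc <- local_average(energy_landscape(0:59, rep(1.5, 60)))
  expect_identical(length(lc$values), 50L)
  expect_true(all(abs(lc$values - 1.5) < 1e-12))
  # a sinusoid of period exactly 11 averages to zero
  s <- sin(2 * pi * (0:59) / 11)
  lsn <- local_average(energy_landscape(0:59, s), 11)
  expect_lt(max(abs(lsn$values)), 1e-9)
  expect_error(local_average(energy_landscape(0:5, rnorm(6)), 11),
               "at least 11")
})

test_that("full signal = local average + periodic component exactly", {
  set.seed(70)
  vals <- rnorm(80) + 0.05 * (0:79)
  ls <- energy_landscape(0:79, vals)
  la <- local_average(ls)
  pc <- periodic_component(ls)
  expect_identical(la$positions, pc$positions)
  idx <- match(la$positions, ls$positions)
  expect_equal(la$values + pc$values, vals[idx], tolerance = 1e-12)
})

test_that("periodic component isolates a sinusoid riding on a slow ramp", {
  pos <- 0:199
  ramp <- 0.02 * pos
  per <- 0.4 * sin(2 * pi * pos / 10)
  ls <- energy_landscape(pos, ramp + per)
  pc <- periodic_component(ls)
  # interior agreement: the 11-point average of the period-10 sinusoid is
  # small but nonzero; tolerance from the independent oracle
  ref <- (ramp + per)[match(pc$positions, pos)] -
    oracle_moving_average(ramp + per, 11)
  expect_equal(pc$values, ref, tolerance = 1e-12)
  expect_lt(max(abs(pc$values - per[match(pc$positions, pos)])), 0.05)
  # applying the decomposition again changes values less than the first
  # removal did (contraction sanity check)
  pc2 <- periodic_component(pc)
  common <- match(pc2$positions, pc$positions)
  d2 <- max(abs(pc2$values - pc$values[common]))
  d1 <- max(abs(pc$values -
                  (ramp + per)[match(pc$positions, pos)]))
  expect_lt(d2, d1)
})

test_that("landscape TSV round-trip preserves values and metadata", {
  ls <- normalize_landscape(
    energy_landscape(10:49, rnorm(40), kT = 1 / 6, source = "markov-order-1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(ls, path)
  back <- read_landscape(path)
  expect_equal(back$values, ls$values, tolerance = 1e-15)
  expect_identical(back$positions, ls$positions)
  expect_equal(back$kT, ls$kT)
  expect_true(back$normalized)
  expect_identical(back$source, "markov-order-1")
  # wiggle export is line-parseable and 1-based
  wig <- withr::local_tempfile(fileext = ".wig")
  write_landscape(ls, wig, format = "wig")
  expect_match(readLines(wig, n = 1), "fixedStep chrom=chr start=11 step=1")
})
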