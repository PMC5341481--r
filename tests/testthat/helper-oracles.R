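# Independent reference implementations used as oracles.  These are written
# naively (term-by-term sums, dense linear algebra, explicit chain rule) and
# deliberately share no code with the package internals they check.

# all 4^L sequences of length L as an integer code matrix (rows), first base
# in column 1
enumerate_codes <- function(L) {
  g <- expand.grid(rep(list(0:3), L))
  as.matrix(g)[, L:1, drop = FALSE]
}

# naive term-by-term toy energy
oracle_toy_energy <- function(model, codes, theta) {
  L <- length(codes)
  E <- 0
  for (n in seq_len(L - 1)) {
    d <- 4 * codes[n] + codes[n + 1]
    E <- E + 0.5 * model$K[d + 1] * (theta[n] - model$theta0[d + 1])^2
    E <- E + 0.5 * model$kappa * (theta[n] - model$cprof[n])^2
  }
  if (L >= 3)
    for (n in seq_len(L - 2))
      E <- E + 0.5 * model$lambda * (theta[n + 1] - theta[n])^2
  E
}

# dense-matrix Gaussian free energy: E = 0.5 t'Mt - b't + c0
oracle_dense_free_energy <- function(model, codes) {
  L <- length(codes)
  ns <- L - 1
  d <- 4 * codes[-L] + codes[-1]
  K <- model$K[d + 1]; t0 <- model$theta0[d + 1]; cp <- model$cprof
  M <- diag(K + model$kappa, ns)
  if (model$lambda > 0 && ns >= 2) {
    for (n in seq_len(ns - 1)) {
      M[n, n] <- M[n, n] + model$lambda
      M[n + 1, n + 1] <- M[n + 1, n + 1] + model$lambda
      M[n, n + 1] <- M[n, n + 1] - model$lambda
      M[n + 1, n] <- M[n + 1, n] - model$lambda
    }
  }
  b <- K * t0 + model$kappa * cp
  c0 <- sum(0.5 * K * t0^2 + 0.5 * model$kappa * cp^2)
  kT <- model$kT
  c0 - 0.5 * sum(b * solve(M, b)) -
    (kT / 2) * (ns * log(2 * pi * kT) -
                  as.numeric(determinant(M)$modulus))
}

# exact sequence log-probabilities (normalized) of a small-L toy model by
# brute-force enumeration
oracle_toy_logp <- function(model, codes_all) {
  F <- apply(codes_all, 1, oracle_dense_free_energy, model = model)
  lp <- -model$beta * F
  lp - log(sum(exp(lp - max(lp)))) - max(lp)
}

# chain-rule Markov score computed directly from counted tables:
# sum log P(joint k-mers) - sum log P(marginal prefix m-mers), with the
# marginal obtained by independent recounting
oracle_chain_rule_logp <- function(ensemble_codes, order, seq_codes) {
  L <- ncol(ensemble_codes)
  n <- nrow(ensemble_codes)
  jointp <- function(pos, w) {
    # probability of the (order+1)-mer w (vector of codes) at 0-based pos
    hits <- rep(TRUE, n)
    for (t in seq_along(w))
      hits <- hits & (ensemble_codes[, pos + t] == w[t])
    sum(hits) / n
  }
  m <- order
  lp <- 0
  for (j in 0:(L - m - 1)) {         # numerator (m+1)-mers at every start
    lp <- lp + log(jointp(j, seq_codes[(j + 1):(j + m + 1)]))
  }
  if (m > 0) {
    for (j in 1:(L - m - 1)) {       # denominator m-mers at starts 1..L-m-1
      lp <- lp - log(jointp(j, seq_codes[(j + 1):(j + m)]))
    }
  }
  lp
}

# independent centered moving average keeping full-support points only
oracle_moving_average <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  sapply((h + 1):(n - h), function(i) mean(x[(i - h):(i + h)]))
}

# stable log-sum-exp, written independently of the package internal
logsumexp_test <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# default small toy model used across tests
test_toy <- function(L = 10, ...) toy_nucleosome_model(window_length = L, ...)
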