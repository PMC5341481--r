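# Internal helpers shared across modules.

#' Numerically stable log-sum-exp
#' @param x numeric vector
#' @return log(sum(exp(x))) computed without overflow
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under a temporary R RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.  `seed = NULL` runs the code
# against the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible per-stage sub-seed from one global seed.  Stages are
# named so they can be re-run independently; results stay below 2^31.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
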