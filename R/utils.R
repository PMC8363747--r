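# Internal numeric helpers shared across modules.

# Two-sided standard-normal quantile for a confidence level
# (0.95 -> 1.959964...). Exact quantile, never the 1.96 shorthand,
# so CI <-> SE round trips are tight.
zQuantile <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  stats::qnorm(1 - (1 - level) / 2)
}

# Two-sided normal p-value for an estimate and its standard error.
twoSidedP <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

# Numerically stable log(sum(exp(x))).
logSumExp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
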