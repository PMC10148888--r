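# Internal helpers shared across the package.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# All user-facing randomness in the package goes through this so that a
# function call never perturbs the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministically spawn a sub-seed from a master seed and a stage label,
# kept below 2^31 so it is always a valid R integer seed.
spawn_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587L)
}

stopf <- function(fmt, ..., class = "pwmmrm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# logistic with guard against overflow in exp()
logistic <- function(x) 1 / (1 + exp(-pmin(pmax(x, -700), 700)))
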