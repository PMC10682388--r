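# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's state afterwards.  Keeps cohort generation independent of any
# randomness the caller has in flight.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic substream seed for (participant, task) derived from a master
# seed by a counter scheme.  Adding participants to a cohort never perturbs
# the streams of existing ones.  All arithmetic stays below 2^31.
substream_seed <- function(master, participant = 0L, task = 0L) {
  master <- as.numeric(master) %% 2147483647
  s <- (master + participant * 100003 + task * 10007 + 1) %% 2147483647
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
    stopf("`%s` must be a single positive integer, got %s", name,
          paste(format(x), collapse = ", "))
  }
  invisible(as.integer(x))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stopf("`%s` must be a single finite number in [%s, %s]", name,
          format(lower), format(upper))
  }
  invisible(as.numeric(x))
}
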