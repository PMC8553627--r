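# Internal RNG helpers. Every stochastic operation in the package takes an
# explicit integer seed and leaves the caller's RNG state untouched.

# Evaluate `code` under set.seed(seed), restoring the global RNG state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed for unit i (train, channel or surrogate) of a
# root seed. Independent of how many units exist, so adding a channel never
# perturbs existing channels. Multiplier kept small enough that the product
# stays exactly representable in a double.
substream_seed <- function(seed, i) {
  m <- 2147483647
  s <- ((seed %% 94906265) * 22695477 + i * 7919 + 1) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("sttcnet_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("sttcnet_format_error", "error")))
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
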