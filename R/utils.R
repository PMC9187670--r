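# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Seed the RNG only when a seed is supplied; generators are pure functions of
# (config, seed) under this convention.
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stop_if_not(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
                "`seed` must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
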