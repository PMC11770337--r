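#' @keywords internal
"_PACKAGE"

# Classed conditions used across the package.  The CLI maps these to exit
# codes (usage -> 2, data -> 3, numerical -> 4).
abort_usage <- function(msg) stop(errorCondition(msg, class = c("pottspep_usage_error", "error")))
abort_data <- function(msg) stop(errorCondition(msg, class = c("pottspep_data_error", "error")))
abort_numeric <- function(msg) stop(errorCondition(msg, class = c("pottspep_numeric_error", "error")))

#' Evaluate an expression with a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_usage("a single integer seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a base seed and a stream label,
# staying inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  x <- (as.numeric(seed) * 48271 + 1103 * stream) %% 2147483647
  as.integer(max(1, x))
}

# Stable short hash of a configuration list (order-independent at top level).
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  raw <- charToRaw(as.character(txt))
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
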