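# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(structure(
    class = c("easementsim_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_input <- function(...) {
  stop(structure(
    class = c("easementsim_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < lower || x > upper) {
    stop_config(sprintf("'%s' must be a single number in [%s, %s], got: %s",
                        name, format(lower), format(upper),
                        paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower ||
      x != as.integer(x)) {
    stop_config(sprintf("'%s' must be an integer >= %d", name, lower))
  }
  invisible(as.integer(x))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# All package randomness flows through this (or through the caller's stream
# when seed is NULL), so results are bit-reproducible for a fixed seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive independent sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
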