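#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so seeded generators do not perturb the caller's
#' random stream. With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# timestamp resolution of the acquisition system: 25 microseconds
TICK <- 25e-6

#' Quantize event times to the 25 microsecond acquisition grid
#' @param t numeric vector of times in seconds.
#' @return times rounded to the nearest multiple of 25 us.
#' @export
quantize_times <- function(t) round(t / TICK) * TICK

# internal: derive a sub-seed from a base seed, kept within 32-bit range
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 1013) %% 2147483562)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
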