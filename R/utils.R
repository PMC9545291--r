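#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates
#' `expr`, and restores the previous RNG state so package functions never
#' disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hashing so that independent pipeline stages
#' (animals, contrasts, repeats, ensemble members) get decorrelated but
#' reproducible streams from one master seed. Stays below 2^31.
#'
#' @param seed master seed (integer).
#' @param ... integer indices identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.numeric(k) * 104729 + 12345) %% 2147483647
  }
  as.integer(h)
}

# Round times to kill floating-point fuzz before window comparisons.
round_t <- function(t) round(t, 9)

#' Standard trial time axis
#'
#' @param rate sampling rate in Hz.
#' @param t_start,t_end window limits in seconds (inclusive at both ends).
#' @return numeric vector of sample times.
#' @keywords internal
trial_times <- function(rate, t_start = -0.1, t_end = 1.0) {
  round_t(seq(t_start, t_end, by = 1 / rate))
}
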