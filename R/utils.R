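#' Derive a child seed from a master seed
#'
#' All stages of the simulator and sampler draw their own seed from one
#' master seed so that a single integer reproduces a whole run.  Child seeds
#' stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param stage integer stage offset (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) * 7919 + 104729 * stage) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single numeric value", name))
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) stop(sprintf("'%s' must lie in the unit interval", name))
  invisible(x)
}
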