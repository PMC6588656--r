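#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed so that stages can be re-run in isolation and still reproduce.  The
#' derivation is a small affine congruential map kept strictly below 2^31 so
#' the result is always a valid R integer seed.
#'
#' @param seed master seed (single integer, may be NULL).
#' @param stage integer stage index (>= 0).
#' @return an integer seed, or NULL if `seed` is NULL.
#' @export
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  s <- (abs(seed) %% 2147483647) * 69069 + 7919 * (stage + 1) + 1
  as.integer(s %% 2147483647)
}

# Set the RNG seed for the remainder of the calling function only.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
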