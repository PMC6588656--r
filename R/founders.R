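#' Generate founder parents
#'
#' Founders are fully inbred elite lines: each carries two identical
#' haplotypes, so a single 0/1 allele row per parent describes it.  Marker
#' allele frequencies across founders follow the requested spectrum.
#'
#' @param n_parents number of founders.
#' @param map a [genetic_map()].
#' @param spectrum `"uniform"` draws per-marker frequencies from
#'   U(`freq_range`); `"fixed"` uses `fixed_p` at every marker.
#' @param freq_range range of the uniform frequency spectrum.
#' @param fixed_p frequency used when `spectrum = "fixed"`.
#' @param seed optional integer seed.
#' @return object of class `founder_pop`: list with `haplotypes`
#'   (`n_parents` x markers 0/1 integer matrix, one row per inbred founder),
#'   `map`, and `freqs` (the spectrum draws).
#' @export
generate_founders <- function(n_parents, map, spectrum = c("uniform", "fixed"),
                              freq_range = c(0.05, 0.95), fixed_p = 0.5,
                              seed = NULL) {
  stopifnot(n_parents >= 1)
  if (!inherits(map, "genetic_map") || NROW(map) == 0)
    stop_fmt("a non-empty genetic_map is required")
  spectrum <- match.arg(spectrum)
  local_seed(seed)
  m <- nrow(map)
  p <- switch(spectrum,
              uniform = stats::runif(m, freq_range[1], freq_range[2]),
              fixed = rep(fixed_p, m))
  h <- matrix(stats::rbinom(n_parents * m, 1, rep(p, each = n_parents)),
              nrow = n_parents, ncol = m,
              dimnames = list(paste0("P", seq_len(n_parents)), map$marker))
  structure(list(haplotypes = h, map = map, freqs = p), class = "founder_pop")
}

#' @export
print.founder_pop <- function(x, ...) {
  cat(sprintf("founder_pop: %d inbred founders, %d markers\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}
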