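#' VanRaden genomic relationship matrix
#'
#' Computes \eqn{G = WW' / (2 \sum_i p_i (1 - p_i))} where `W` is the
#' column-centred dosage matrix (`dosage - 2 p_i`) and `p_i` are allele
#' frequencies either estimated from the data (`colMeans(dosage)/2`) or
#' supplied.  Markers with zero dosage variance across lines are
#' monomorphic here: they contribute nothing to the numerator and are
#' excluded from the denominator and the marker count.
#'
#' @param geno dosage matrix, lines x markers, values in \[0, 2\]
#'   (continuous dosages from bulked genotyping are accepted).
#' @param freqs optional numeric vector of allele frequencies (one per
#'   marker column); default estimates them from `geno`.
#' @return a `grmatrix`: the symmetric G matrix with attributes `freqs`
#'   (frequencies of the markers used), `denominator`, `n_markers` (markers
#'   used) and `dropped` (monomorphic markers removed).
#' @examples
#' G <- compute_grm(rbind(A = c(0, 2), B = c(2, 0)))
#' @export
compute_grm <- function(geno, freqs = NULL) {
  stopifnot(is.matrix(geno))
  if (any(geno < 0 | geno > 2)) stop_fmt("dosages must lie in [0, 2]")
  v <- apply(geno, 2, stats::var)
  keep <- v > 0
  if (!any(keep))
    stop_fmt("all markers are monomorphic: VanRaden denominator is zero")
  Wg <- geno[, keep, drop = FALSE]
  p <- if (is.null(freqs)) colMeans(Wg) / 2 else {
    stopifnot(length(freqs) == ncol(geno))
    freqs[keep]
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop_fmt("VanRaden denominator is zero for the supplied frequencies")
  W <- sweep(Wg, 2, 2 * p)
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  structure(G, class = c("grmatrix", "matrix"),
            freqs = p, denominator = denom,
            n_markers = sum(keep), dropped = sum(!keep))
}

#' Add a ridge to a relationship matrix
#'
#' REML and the mixed-model equations need an invertible G; `stabilize`
#' returns `G + epsilon * I` and records the epsilon used.
#'
#' @param G a `grmatrix` (or plain symmetric matrix).
#' @param epsilon small positive ridge, default 1e-6.
#' @return the stabilized matrix, attribute `stabilized` = epsilon.
#' @export
stabilize <- function(G, epsilon = 1e-6) {
  if (epsilon <= 0) stop_fmt("epsilon must be > 0")
  out <- unclass(G)
  diag(out) <- diag(out) + epsilon
  attributes(out) <- c(attributes(out),
                       attributes(G)[setdiff(names(attributes(G)), names(attributes(out)))])
  class(out) <- class(G)
  attr(out, "stabilized") <- epsilon + (attr(G, "stabilized") %||% 0)
  out
}

#' Drop non-segregating markers
#'
#' Removes marker columns with zero dosage variance across all lines.
#'
#' @param geno dosage matrix, lines x markers.
#' @return the filtered matrix; attributes `n_kept` and `n_dropped`.
#' @export
filter_segregating <- function(geno) {
  stopifnot(is.matrix(geno))
  v <- apply(geno, 2, stats::var)
  keep <- v > 0
  out <- geno[, keep, drop = FALSE]
  for (a in c("cross", "map")) {
    at <- attr(geno, a)
    if (!is.null(at)) attr(out, a) <- if (a == "map" && is.data.frame(at))
      at[keep, , drop = FALSE] else at
  }
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' @export
print.grmatrix <- function(x, ...) {
  cat(sprintf("grmatrix: %d lines, %d markers used (%d monomorphic dropped), mean diag %.3f\n",
              nrow(x), attr(x, "n_markers") %||% NA_integer_,
              attr(x, "dropped") %||% 0, mean(diag(unclass(x)))))
  invisible(x)
}
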