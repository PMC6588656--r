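#' Combine spatially adjusted plot values into one BLUE per line
#'
#' Fits the fixed-effects model `value = trial mean + line effect` to the
#' adjusted plot values of all trials jointly and solves the normal
#' equations exactly (sparse), with identifiability fixed by constraining
#' the line effects to sum to zero.  Reported BLUEs are the line effects
#' re-centred on the grand mean, so differences between lines are exact
#' generalized-least-squares contrasts and the values live on the yield
#' scale.
#'
#' @param plots a `plot_table` (or plain data.frame) with columns `trial`,
#'   `id` and the response in `value_col`.
#' @param value_col response column, default `"adjusted"`.
#' @return data.frame of class `blue_table`: `id`, `blue`, `n_plots`,
#'   `trials` (comma-separated), `is_check` if available.  Attribute
#'   `trial_means` holds the fitted per-trial means.
#' @export
estimate_blues <- function(plots, value_col = "adjusted") {
  stopifnot(is.data.frame(plots), value_col %in% names(plots),
            all(c("trial", "id") %in% names(plots)))
  pf <- as.data.frame(plots)
  y <- pf[[value_col]]
  if (anyNA(y)) stop_fmt("missing values in '%s'", value_col)
  tf <- factor(pf$trial)
  lf <- factor(pf$id)
  Tn <- nlevels(tf); Ln <- nlevels(lf)
  .check_connected(tf, lf)

  n <- length(y)
  X <- Matrix::sparseMatrix(i = rep(seq_len(n), 2),
                            j = c(as.integer(tf), Tn + as.integer(lf)),
                            x = 1, dims = c(n, Tn + Ln))
  A <- Matrix::crossprod(X)
  rhs <- Matrix::crossprod(X, y)
  # append the sum-to-zero constraint on line effects (Lagrange multiplier)
  cvec <- c(rep(0, Tn), rep(1, Ln))
  M <- rbind(cbind(A, cvec), c(cvec, 0))
  sol <- tryCatch(Matrix::solve(M, c(as.numeric(rhs), 0)),
                  error = function(e)
                    stop_fmt("singular normal equations: %s", conditionMessage(e)))
  sol <- as.numeric(sol)
  b <- sol[seq_len(Tn)]
  u <- sol[Tn + seq_len(Ln)]
  grand <- mean(y)

  n_plots <- as.integer(table(lf))
  trials_of <- vapply(split(as.character(tf), lf),
                      function(x) paste(sort(unique(x)), collapse = ","), "")
  out <- data.frame(id = levels(lf), blue = u + grand, n_plots = n_plots,
                    trials = as.character(trials_of), stringsAsFactors = FALSE)
  if ("is_check" %in% names(pf))
    out$is_check <- as.logical(tapply(pf$is_check, lf, any))
  class(out) <- c("blue_table", "data.frame")
  attr(out, "trial_means") <- stats::setNames(b, levels(tf))
  out
}

# error if the line-trial incidence graph is disconnected
.check_connected <- function(tf, lf) {
  Tn <- nlevels(tf); Ln <- nlevels(lf)
  edges <- unique(data.frame(t = as.integer(tf), l = as.integer(lf)))
  by_trial <- split(edges$l, edges$t)
  by_line <- split(edges$t, edges$l)
  comp <- rep(NA_integer_, Tn)
  k <- 0
  for (s in seq_len(Tn)) {
    if (!is.na(comp[s])) next
    k <- k + 1
    queue <- s
    while (length(queue)) {
      t0 <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[t0])) next
      comp[t0] <- k
      nbr <- unique(unlist(by_line[as.character(by_trial[[as.character(t0)]])]))
      queue <- c(queue, nbr[is.na(comp[nbr])])
    }
  }
  if (k > 1) {
    groups <- split(levels(tf), comp)
    stop_fmt("design is disconnected: trial groups {%s} share no lines",
             paste(vapply(groups, paste, "", collapse = ","), collapse = "} {"))
  }
  invisible(TRUE)
}
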