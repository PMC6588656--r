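# GBLUP:  y = mu + g + e,  g ~ N(0, G sigma2_g),  e ~ N(0, I sigma2_e)
# Variance components by AI-REML with EM-REML fallback; all per-iteration
# quantities are O(n) in the eigenbasis of the training block of G.

.reml_parts <- function(sg, se, lam, yt, xt) {
  d <- sg * lam + se
  if (any(d <= 0)) return(NULL)
  sxx <- sum(xt^2 / d)
  sxy <- sum(xt * yt / d)
  beta <- sxy / sxx
  rt <- yt - beta * xt
  ut <- rt / d
  yPy <- sum(rt^2 / d)
  ll <- -0.5 * (sum(log(d)) + log(sxx) + yPy)
  list(d = d, sxx = sxx, ut = ut, yPy = yPy, loglik = ll)
}

#' Restricted log-likelihood of the GBLUP model
#'
#' Evaluates the REML log-likelihood (up to an additive constant) of
#' `y = mu + g + e` with `g ~ N(0, K sigma2_g)` and `e ~ N(0, I sigma2_e)`.
#' Used by [fit_aireml()] internally and handy for independent checks.
#'
#' @param y numeric response (training lines).
#' @param K relationship matrix over the same lines (or its `eigen()`).
#' @param sigma2_g,sigma2_e variance components (>= 0, not both 0).
#' @return scalar log-likelihood.
#' @export
gblup_loglik <- function(y, K, sigma2_g, sigma2_e) {
  eg <- if (is.list(K) && !is.null(K$values)) K else eigen(unclass(K), symmetric = TRUE)
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, length(y))))
  p <- .reml_parts(sigma2_g, sigma2_e, eg$values, yt, xt)
  if (is.null(p)) return(-Inf)
  p$loglik
}

#' Estimate GBLUP variance components by AI-REML
#'
#' Average-information REML for the two-component model, with a fallback to
#' an EM-REML step whenever the AI update would push a component below its
#' floor or decrease the restricted likelihood (with step-halving as a last
#' resort).  Convergence is declared when the largest absolute change of
#' the normalized variance components (components divided by their sum)
#' drops below `tol`.  Components are floored at `1e-8` times the total
#' variance rather than being allowed to go negative.
#'
#' @param y named numeric vector of training BLUEs (length >= 3).
#' @param G relationship matrix whose row/col names cover `names(y)`; only
#'   the training block is used here.
#' @param start optional `c(sigma2_g, sigma2_e)` start values; default is
#'   half the sample variance of `y` each.
#' @param maxit maximum iterations (default 100).
#' @param tol convergence tolerance on normalized components (default 1e-5).
#' @return object of class `varcomp`: `sigma2_g`, `sigma2_e`, `theta`
#'   (normalized components), `loglik`, `converged`, `iterations`, `trace`
#'   (one row per iteration).
#' @export
fit_aireml <- function(y, G, start = NULL, maxit = 100, tol = 1e-5) {
  ids <- names(y)
  if (!is.null(ids)) {
    if (!all(ids %in% rownames(G)))
      stop_fmt("training line(s) absent from G: %s",
               paste(utils::head(setdiff(ids, rownames(G)), 5), collapse = ", "))
    K <- unclass(G)[ids, ids, drop = FALSE]
  } else K <- unclass(G)
  n <- length(y)
  if (n < 3) stop_fmt("need at least 3 training lines, got %d", n)
  vy <- stats::var(y)
  if (vy == 0) {
    warn_fmt("response is constant: returning boundary estimate sigma2_g = 0")
    return(structure(list(sigma2_g = 0, sigma2_e = 0, theta = c(g = 0, e = 1),
                          loglik = NA_real_, converged = TRUE, iterations = 0L,
                          trace = NULL), class = "varcomp"))
  }
  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, n)))

  th <- start %||% c(vy / 2, vy / 2)
  parts <- .reml_parts(th[1], th[2], lam, yt, xt)
  trace <- list()
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    d <- parts$d; ut <- parts$ut; sxx <- parts$sxx
    trPK <- sum(lam / d) - sum(xt^2 * lam / d^2) / sxx
    trP <- sum(1 / d) - sum(xt^2 / d^2) / sxx
    uKu <- sum(lam * ut^2)
    uu <- sum(ut^2)
    sc <- c(-0.5 * (trPK - uKu), -0.5 * (trP - uu))
    Pv <- function(wt) wt / d - (xt / d) * (sum(xt * wt / d) / sxx)
    p1 <- Pv(lam * ut); p2 <- Pv(ut)
    AI <- 0.5 * matrix(c(sum(lam * ut * p1), sum(lam * ut * p2),
                         sum(ut * p1), sum(ut * p2)), 2, 2)
    floor_v <- 1e-8 * sum(th)

    step_ai <- tryCatch(solve(AI, sc), error = function(e) NULL)
    cand <- NULL; how <- ""
    if (!is.null(step_ai)) {
      prop <- pmax(th + step_ai, floor_v)
      pp <- .reml_parts(prop[1], prop[2], lam, yt, xt)
      if (!is.null(pp) && pp$loglik >= parts$loglik - 1e-10) {
        cand <- prop; cand_parts <- pp; how <- "AI"
      }
    }
    if (is.null(cand)) {
      # EM-REML step (Johnson & Thompson form), guaranteed inside the
      # parameter space
      prop <- pmax(c(th[1] + th[1]^2 * (uKu - trPK) / n,
                     th[2] + th[2]^2 * (uu - trP) / n), floor_v)
      pp <- .reml_parts(prop[1], prop[2], lam, yt, xt)
      if (!is.null(pp) && pp$loglik >= parts$loglik - 1e-10) {
        cand <- prop; cand_parts <- pp; how <- "EM"
      }
    }
    if (is.null(cand) && !is.null(step_ai)) {
      # step-halving on the AI direction
      step <- step_ai
      for (h in 1:20) {
        step <- step / 2
        prop <- pmax(th + step, floor_v)
        pp <- .reml_parts(prop[1], prop[2], lam, yt, xt)
        if (!is.null(pp) && pp$loglik >= parts$loglik - 1e-10) {
          cand <- prop; cand_parts <- pp; how <- sprintf("AI/2^%d", h); break
        }
      }
    }
    if (is.null(cand)) { cand <- th; cand_parts <- parts; how <- "stuck" }

    dtheta <- max(abs(cand / sum(cand) - th / sum(th)))
    trace[[it]] <- data.frame(iter = it, sigma2_g = cand[1], sigma2_e = cand[2],
                              loglik = cand_parts$loglik, step = how,
                              dtheta = dtheta)
    th <- cand; parts <- cand_parts
    if (dtheta < tol) { converged <- TRUE; break }
    if (how == "stuck") break
  }
  if (!converged)
    warn_fmt("AI-REML did not converge in %d iterations (last dtheta %.2g)",
             it, trace[[length(trace)]]$dtheta)
  structure(list(sigma2_g = th[1], sigma2_e = th[2],
                 theta = c(g = th[1], e = th[2]) / sum(th),
                 loglik = parts$loglik, converged = converged,
                 iterations = it, trace = do.call(rbind, trace)),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("varcomp: sigma2_g=%.5g sigma2_e=%.5g (theta %.4f/%.4f) %s after %d it\n",
              x$sigma2_g, x$sigma2_e, x$theta[1], x$theta[2],
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Predict genetic values of all lines from training phenotypes
#'
#' Solves the GBLUP prediction problem for every line in `G`, using either
#' the conditional-mean formula
#' \eqn{\hat g = \sigma^2_g G_{\cdot t} V_t^{-1} (y - \hat\mu)} (default,
#' fast) or the full mixed-model equations (`method = "mme"`, needs an
#' invertible G -- see [stabilize()]).  Both routes give identical results.
#'
#' @param vc a [fit_aireml()] result (or list with `sigma2_g`, `sigma2_e`).
#' @param y named numeric vector of training BLUEs.
#' @param G relationship matrix over all lines (training and validation).
#' @param method `"conditional"` or `"mme"`.
#' @return data.frame of class `prediction`: `id`, `ghat`, `in_training`;
#'   attribute `mu` is the fitted intercept.
#' @export
predict_lines <- function(vc, y, G, method = c("conditional", "mme")) {
  method <- match.arg(method)
  ids_all <- rownames(G)
  t_ids <- names(y)
  if (is.null(ids_all) || is.null(t_ids))
    stop_fmt("G and y must carry line ids in their names")
  miss <- setdiff(t_ids, ids_all)
  if (length(miss))
    stop_fmt("line(s) absent from G: %s", paste(utils::head(miss, 5), collapse = ", "))
  sg <- vc$sigma2_g; se <- vc$sigma2_e
  Gm <- unclass(G)
  n <- length(y); N <- nrow(Gm)
  tiny <- 1e-12 * (sg + se)
  if (sg <= tiny) {                       # shrinkage limit: all ghat -> 0
    mu <- mean(y)
    out <- data.frame(id = ids_all, ghat = 0, in_training = ids_all %in% t_ids,
                      stringsAsFactors = FALSE)
    attr(out, "mu") <- mu
    class(out) <- c("prediction", "data.frame")
    return(out)
  }
  if (method == "conditional") {
    V <- sg * Gm[t_ids, t_ids, drop = FALSE]
    diag(V) <- diag(V) + se
    ch <- chol(V)
    sol <- backsolve(ch, forwardsolve(t(ch), cbind(rep(1, n), y)))
    a <- sol[, 1]
    mu <- sum(a * y) / sum(a)
    w <- backsolve(ch, forwardsolve(t(ch), y - mu))
    ghat <- sg * drop(Gm[, t_ids, drop = FALSE] %*% w)
  } else {
    Ginv <- tryCatch(chol2inv(chol(Gm)), error = function(e)
      stop_fmt("G is not invertible; stabilize() it first (%s)", conditionMessage(e)))
    Z <- matrix(0, n, N)
    Z[cbind(seq_len(n), match(t_ids, ids_all))] <- 1
    C <- rbind(c(n / se, colSums(Z) / se),
               cbind(colSums(Z) / se, crossprod(Z) / se + Ginv / sg))
    rhs <- c(sum(y) / se, drop(crossprod(Z, y)) / se)
    sol <- solve(C, rhs)
    mu <- sol[1]
    ghat <- stats::setNames(sol[-1], ids_all)
  }
  out <- data.frame(id = ids_all, ghat = as.numeric(ghat),
                    in_training = ids_all %in% t_ids, stringsAsFactors = FALSE)
  attr(out, "mu") <- mu
  class(out) <- c("prediction", "data.frame")
  out
}

#' Line-mean (Piepho-Mohring) heritability
#'
#' \eqn{\bar H^2 = \sigma^2_g / (\sigma^2_g + v / n)} with `v` the
#' non-genetic plot-level variance and `n` the number of locations a line
#' was observed in.  With a vector `n` the per-line values are averaged.
#'
#' @param sigma2_g genetic variance (>= 0).
#' @param v plot-level residual variance (>= 0); see
#'   [plot_residual_variance()].
#' @param n number of locations per line (scalar or vector).
#' @return scalar heritability (NA with a warning if `sigma2_g = v = 0`).
#' @export
heritability <- function(sigma2_g, v, n) {
  stopifnot(sigma2_g >= 0, v >= 0, all(n >= 1))
  if (sigma2_g == 0 && v == 0) {
    warn_fmt("sigma2_g and v are both zero: heritability undefined")
    return(NA_real_)
  }
  mean(sigma2_g / (sigma2_g + v / n))
}

#' Plot-level residual variance from the spatial-stage fits
#'
#' The non-genetic plot variance `v` entering [heritability()] is taken as
#' spatial + nugget variance of each trial's AR1 x AR1 fit, averaged across
#' trials with plot-count weights.
#'
#' @param fits list of [fit_ar1ar1()] results (e.g. `adjust_trials()$fits`).
#' @return scalar variance.
#' @export
plot_residual_variance <- function(fits) {
  v <- vapply(fits, function(f) f$sigma2_spatial + f$sigma2_nugget, 0)
  w <- vapply(fits, function(f) f$n_plots, 0)
  sum(v * w) / sum(w)
}
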