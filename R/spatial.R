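# Per-trial spatial adjustment with a separable AR1 x AR1 residual model.
#
# Model for one trial:  y = 1*mu + Z g + s + eps
#   g   ~ N(0, sigma2_geno * I)        (iid line effects, random)
#   s   ~ N(0, sigma2_spatial * AR1(rho_row) (x) AR1(rho_col))
#   eps ~ N(0, sigma2_nugget * I)
# The restricted likelihood is maximized over (rho_row, rho_col) and the two
# variance ratios, with the overall scale profiled out.  Two equivalent
# computational routes are used: a dense route on the covariance of the
# observed plots (works for ragged layouts), and a fast eigen/Woodbury route
# when the trial covers a complete grid and lines are few relative to plots.

.reml_dense_obj <- function(par, env) {
  rho_r <- if (env$active["zr"]) env$bound * tanh(par[["zr"]]) else 0
  rho_c <- if (env$active["zc"]) env$bound * tanh(par[["zc"]]) else 0
  gg <- exp(min(max(par[["lgg"]], -25), 10))
  gs <- exp(min(max(par[["lgs"]], -25), 10))
  n <- length(env$y)
  rv <- rho_r^(0:(env$nr - 1)); cv <- rho_c^(0:(env$nc - 1))
  K <- matrix(rv[env$Dr + 1L] * cv[env$Dc + 1L], n, n)
  V0 <- gs * K + gg * env$ZZt
  diag(V0) <- diag(V0) + 1
  ch <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  sol <- backsolve(ch, forwardsolve(t(ch), cbind(env$y, 1)))
  yv <- sol[, 1]; xv <- sol[, 2]
  sxx <- sum(xv); sxy <- sum(yv * env$y) # x'V0inv x with x=1 is sum(xv)
  yVy <- sum(env$y * yv)
  xVy <- sum(xv * env$y)
  quad <- yVy - xVy^2 / sxx
  if (quad <= 0 || sxx <= 0) return(1e10)
  (n - 1) * log(quad / (n - 1)) + logdet + log(sxx)
}

.reml_eigen_obj <- function(par, env) {
  rho_r <- if (env$active["zr"]) env$bound * tanh(par[["zr"]]) else 0
  rho_c <- if (env$active["zc"]) env$bound * tanh(par[["zc"]]) else 0
  gg <- exp(min(max(par[["lgg"]], -25), 10))
  gs <- exp(min(max(par[["lgs"]], -25), 10))
  er <- eigen(ar1_cor(env$nr, rho_r), symmetric = TRUE)
  ec <- eigen(ar1_cor(env$nc, rho_c), symmetric = TRUE)
  lam <- as.vector(outer(er$values, ec$values))
  rot <- function(v) as.vector(crossprod(er$vectors,
                                         matrix(v, env$nr, env$nc) %*% ec$vectors))
  n <- length(env$y); L <- ncol(env$Zd)
  Zs <- matrix(0, n, L)
  for (j in seq_len(L)) Zs[, j] <- rot(env$Zd[, j])
  yt <- rot(env$y); xt <- rot(rep(1, n))
  d <- gs * lam + 1
  A <- crossprod(Zs, Zs / d)
  M <- A + diag(1 / gg, L)
  cM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(cM)) return(1e10)
  vinv <- function(u) {
    u_d <- u / d
    u_d - (Zs %*% backsolve(cM, backsolve(cM, crossprod(Zs, u_d),
                                          transpose = TRUE))) / d
  }
  yv <- vinv(yt); xv <- vinv(xt)
  sxx <- sum(xt * xv); xVy <- sum(xt * yv); yVy <- sum(yt * yv)
  quad <- yVy - xVy^2 / sxx
  if (quad <= 0 || sxx <= 0) return(1e10)
  logdet <- sum(log(d)) + 2 * sum(log(diag(cM))) + L * log(gg)
  (n - 1) * log(quad / (n - 1)) + logdet + log(sxx)
}

#' Fit the AR1 x AR1 spatial model to one trial
#'
#' Maximizes the restricted likelihood of a model with an overall mean, iid
#' random line effects, a separable AR1 row x AR1 column spatial component,
#' and a nugget.  Autocorrelations are searched inside `(-bound, bound)`
#' (coarse grid, then Nelder-Mead refinement of the transformed parameters
#' with the overall scale profiled out).  The adjusted plot value is the raw
#' value minus the predicted spatial component only, so the genetic signal
#' stays in the data passed downstream.
#'
#' @param plots `plot_table` rows of a single trial, with a `yield` column
#'   (or `value_col`).
#' @param include_checks include check plots in the fit (default TRUE).
#' @param value_col name of the response column.
#' @param bound autocorrelation search bound (default 0.95).
#' @param trend_method how the removed spatial trend is computed once the
#'   variance parameters are estimated.  `"gls"` (default) holds line
#'   effects fixed at their generalized-least-squares estimates and predicts
#'   the field from the residuals, so the adjustment provably cannot absorb
#'   genetic contrasts; `"blup"` predicts the field with line effects random
#'   (stronger smoothing, but at one plot per line part of each line's
#'   deviation is attributed to the field and the genetic signal is
#'   attenuated downstream).
#' @param control list with `maxit` (default 200), `reltol` (default 1e-8)
#'   for the refinement stage, and optionally `route` (`"auto"`, `"dense"`
#'   or `"eigen"`) to override the automatic route choice.
#' @return object of class `spatial_fit`: trial id, `rho_row`, `rho_col`,
#'   variance components, restricted log-likelihood (up to a constant),
#'   convergence flag, the plot table with `adjusted` and `trend` columns,
#'   and per-line raw/adjusted means.
#' @export
fit_ar1ar1 <- function(plots, include_checks = TRUE, value_col = "yield",
                       bound = 0.95, trend_method = c("gls", "blup"),
                       control = list()) {
  trend_method <- match.arg(trend_method)
  stopifnot(is.data.frame(plots), value_col %in% names(plots))
  trial <- unique(plots$trial)
  if (length(trial) != 1)
    stop_fmt("fit_ar1ar1 expects the plots of a single trial, got %d", length(trial))
  pf <- as.data.frame(plots)
  if (!include_checks && "is_check" %in% names(pf)) pf <- pf[!pf$is_check, ]
  if (anyDuplicated(pf[, c("row", "col")]))
    stop_fmt("duplicated (row, col) plot positions in trial %s", trial)
  maxit <- control$maxit %||% 200
  reltol <- control$reltol %||% 1e-8

  nr <- max(pf$row); nc <- max(pf$col)
  n <- nrow(pf)
  active <- c(zr = nr >= 2, zc = nc >= 2)
  if (!active["zr"] || !active["zc"])
    warn_fmt("trial %s has a single %s: fitting AR1 in one dimension only",
             trial, if (!active["zr"]) "row" else "column")
  if (n < 4) stop_fmt("too few plots (%d) to fit the spatial model", n)

  line_f <- factor(pf$id)
  L <- nlevels(line_f)
  full_grid <- (n == nr * nc)
  route <- control$route %||% "auto"
  use_eigen <- switch(route,
    auto = full_grid && L <= n / 3 && all(active),
    eigen = {
      if (!full_grid || !all(active))
        stop_fmt("eigen route needs a complete grid with >= 2 rows and columns")
      TRUE
    },
    dense = FALSE,
    stop_fmt("unknown route '%s'", route))

  env <- new.env(parent = emptyenv())
  env$bound <- bound; env$active <- active
  env$nr <- nr; env$nc <- nc
  if (use_eigen) {
    ord <- order(pf$col, pf$row)
    pf <- pf[ord, , drop = FALSE]
    line_f <- factor(pf$id)
    env$y <- pf[[value_col]]
    env$Zd <- matrix(0, n, L)
    env$Zd[cbind(seq_len(n), as.integer(line_f))] <- 1
    obj <- .reml_eigen_obj
  } else {
    env$y <- pf[[value_col]]
    env$Dr <- abs(outer(pf$row, pf$row, "-"))
    env$Dc <- abs(outer(pf$col, pf$col, "-"))
    Zi <- matrix(0, n, L)
    Zi[cbind(seq_len(n), as.integer(line_f))] <- 1
    env$ZZt <- tcrossprod(Zi)
    obj <- .reml_dense_obj
  }

  par0 <- c(zr = 0, zc = 0, lgg = 0, lgs = 0)
  # coarse grid over the autocorrelations, robust to multimodality
  grid_rho <- c(-0.5, 0, 0.5)
  best <- Inf; best_par <- par0
  for (rr in (if (active["zr"]) grid_rho else 0))
    for (cc in (if (active["zc"]) grid_rho else 0)) {
      p <- par0
      p["zr"] <- atanh(max(min(rr / bound, 0.999), -0.999))
      p["zc"] <- atanh(max(min(cc / bound, 0.999), -0.999))
      v <- obj(p, env)
      if (v < best) { best <- v; best_par <- p }
    }
  free <- c(active, lgg = TRUE, lgs = TRUE)
  fn <- function(p_free) {
    p <- best_par; p[names(p_free)] <- p_free
    obj(p, env)
  }
  opt <- stats::optim(best_par[free], fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  p_hat <- best_par; p_hat[names(opt$par)] <- opt$par
  converged <- opt$convergence == 0

  rho_row <- if (active["zr"]) bound * tanh(p_hat[["zr"]]) else NA_real_
  rho_col <- if (active["zc"]) bound * tanh(p_hat[["zc"]]) else NA_real_
  gg <- exp(min(max(p_hat[["lgg"]], -25), 10))
  gs <- exp(min(max(p_hat[["lgs"]], -25), 10))

  # final pass: variances, trend, adjusted values (dense algebra, any route)
  rr0 <- if (is.na(rho_row)) 0 else rho_row
  cc0 <- if (is.na(rho_col)) 0 else rho_col
  rv <- rr0^(0:(nr - 1)); cv <- cc0^(0:(nc - 1))
  Dr <- abs(outer(pf$row, pf$row, "-")); Dc <- abs(outer(pf$col, pf$col, "-"))
  K <- matrix(rv[Dr + 1L] * cv[Dc + 1L], n, n)
  Zi <- matrix(0, n, L); Zi[cbind(seq_len(n), as.integer(line_f))] <- 1
  V0 <- gs * K + gg * tcrossprod(Zi); diag(V0) <- diag(V0) + 1
  ch <- chol(V0)
  y <- pf[[value_col]]
  sol <- backsolve(ch, forwardsolve(t(ch), cbind(y, 1)))
  sxx <- sum(sol[, 2]); xVy <- sum(sol[, 2] * y)
  mu <- xVy / sxx
  resid <- y - mu
  v0inv_r <- backsolve(ch, forwardsolve(t(ch), resid))
  quad <- sum(resid * v0inv_r)
  sigma2 <- quad / (n - 1)
  if (trend_method == "blup" || n <= L) {
    trend <- gs * as.vector(K %*% v0inv_r)
  } else {
    # line effects fixed at their GLS estimates under Sigma0 = gs K + I;
    # the field is predicted from the genotype-free residuals only
    Sig0 <- gs * K
    diag(Sig0) <- diag(Sig0) + 1
    chS <- chol(Sig0)
    SiYZ <- backsolve(chS, forwardsolve(t(chS), cbind(y, Zi)))
    A <- crossprod(Zi, SiYZ[, -1, drop = FALSE])
    uhat <- solve(A, crossprod(Zi, SiYZ[, 1]))
    r0 <- y - as.vector(Zi %*% uhat)
    trend <- gs * as.vector(K %*% backsolve(chS, forwardsolve(t(chS), r0)))
  }
  adjusted <- y - trend
  loglik <- -0.5 * ((n - 1) * log(sigma2) + 2 * sum(log(diag(ch))) +
                      log(sxx) + (n - 1))

  pf$trend <- trend
  pf$adjusted <- adjusted
  raw_means <- tapply(y, line_f, mean)
  adj_means <- tapply(adjusted, line_f, mean)
  is_chk <- if ("is_check" %in% names(pf))
    tapply(pf$is_check, line_f, any) else rep(FALSE, L)
  line_means <- data.frame(id = levels(line_f),
                           raw_mean = as.numeric(raw_means),
                           adj_mean = as.numeric(adj_means),
                           is_check = as.logical(is_chk),
                           stringsAsFactors = FALSE)

  structure(list(trial = trial, rho_row = rho_row, rho_col = rho_col,
                 sigma2_spatial = sigma2 * gs, sigma2_nugget = sigma2,
                 sigma2_geno = sigma2 * gg, loglik = loglik,
                 converged = converged, route = if (use_eigen) "eigen" else "dense",
                 n_plots = n, plots = pf, line_means = line_means),
            class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf(paste0("spatial_fit [%s, %s route]: rho_row=%.3f rho_col=%.3f  ",
                     "s2_spatial=%.4g s2_nugget=%.4g s2_geno=%.4g%s\n"),
              x$trial, x$route, x$rho_row, x$rho_col, x$sigma2_spatial,
              x$sigma2_nugget, x$sigma2_geno,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Spatially adjust all trials of a plot table
#'
#' Applies [fit_ar1ar1()] to each trial separately and returns the adjusted
#' plot table together with the per-trial fits and a summary table.
#'
#' @inheritParams fit_ar1ar1
#' @param plots a `plot_table` with a yield column covering one or more
#'   trials.
#' @return list with `fits` (named list of `spatial_fit`), `plots` (the
#'   adjusted table), and `summary` (one [trial_summary()] row per trial).
#' @export
adjust_trials <- function(plots, include_checks = TRUE, value_col = "yield",
                          trend_method = c("gls", "blup"), control = list()) {
  trend_method <- match.arg(trend_method)
  trials <- unique(plots$trial)
  fits <- lapply(trials, function(t)
    fit_ar1ar1(plots[plots$trial == t, , drop = FALSE],
               include_checks = include_checks, value_col = value_col,
               trend_method = trend_method, control = control))
  names(fits) <- trials
  adj <- do.call(rbind, lapply(fits, function(f) f$plots))
  rownames(adj) <- NULL
  class(adj) <- c("plot_table", "data.frame")
  summ <- do.call(rbind, lapply(fits, trial_summary))
  rownames(summ) <- NULL
  list(fits = fits, plots = adj, summary = summ)
}

#' Per-trial summary of line means after spatial adjustment
#'
#' @param fit a [fit_ar1ar1()] result.
#' @return one-row data.frame: trial, number of (non-check) lines, mean of
#'   adjusted line means, coefficient of variation in percent, and the
#'   Pearson correlation between raw and adjusted line means.
#' @export
trial_summary <- function(fit) {
  stopifnot(inherits(fit, "spatial_fit"))
  lm <- fit$line_means[!fit$line_means$is_check, , drop = FALSE]
  mu <- mean(lm$adj_mean)
  cv <- if (abs(mu) < .Machine$double.eps^0.5) NA_real_
        else 100 * stats::sd(lm$adj_mean) / mu
  r <- if (stats::sd(lm$raw_mean) == 0 || stats::sd(lm$adj_mean) == 0) NA_real_
       else stats::cor(lm$raw_mean, lm$adj_mean)
  data.frame(trial = fit$trial, n_lines = nrow(lm), mean = mu,
             cv_pct = cv, cor_raw_adj = r, stringsAsFactors = FALSE)
}
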