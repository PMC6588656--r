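#' Trait model parameters
#'
#' Collects the parameters of the simulated yield trait and its field-trial
#' noise.  The heritability target is interpreted on the scale the analysis
#' reports it: the line-mean (Piepho-Mohring) heritability
#' \eqn{H^2 = \sigma^2_g / (\sigma^2_g + v/n)} with `n` the number of
#' locations a line is observed in, averaged over lines (`h2_basis =
#' "pm-locations"`, the default).  Alternatives: `"line-mean"` uses the
#' constant number of plots per line for `n`; `"plot"` targets the
#' single-plot variance ratio.  `spatial_var` and `nugget` act as relative
#' weights that split the non-genetic plot variance between the AR1xAR1
#' spatial field and iid nugget noise when `scale_to_h2 = TRUE`, and as
#' absolute variances otherwise.
#'
#' @param n_qtl number of additive QTL (sampled among the markers), or NULL
#'   (default) for a polygenic trait with effects at every marker.  With the
#'   polygenic default the genetic covariance is exactly proportional to the
#'   VanRaden G built on the same data, so GBLUP is well-specified; with a
#'   sparse QTL subset part of the genetic variance is invisible to a
#'   G-based model and estimated heritabilities are attenuated accordingly.
#' @param var_g realized variance of the genetic values across lines when
#'   QTL effects are drawn (yield units squared; default 0.5, a typical
#'   genetic variance for wheat yield around site means of 5-11 t/ha).
#'   Ignored when effects are supplied explicitly.
#' @param h2 target heritability in (0, 1).
#' @param h2_basis heritability definition used for noise scaling.
#' @param scale_to_h2 if TRUE (default), total non-genetic variance is set
#'   from `h2`; if FALSE, `spatial_var`/`nugget` are used as-is.
#' @param rho_row,rho_col AR1 autocorrelations of the spatial field, in
#'   (-1, 1).
#' @param spatial_var,nugget spatial and nugget variance (weights when
#'   `scale_to_h2 = TRUE`).
#' @param site_means per-trial mean yields; recycled/named by trial id.
#'   Defaults follow the rank order of typical UK site-season means
#'   (t/ha-like units).
#' @return list of class `trait_model`.
#' @export
trait_model <- function(n_qtl = NULL, var_g = 0.5, h2 = 0.65,
                        h2_basis = c("pm-locations", "line-mean", "plot"),
                        scale_to_h2 = TRUE,
                        rho_row = 0.4, rho_col = 0.4,
                        spatial_var = 1, nugget = 1,
                        site_means = c(8.58, 10.82, 8.24, 4.64)) {
  h2_basis <- match.arg(h2_basis)
  if (scale_to_h2 && (h2 <= 0 || h2 >= 1))
    stop_fmt("target heritability must be strictly inside (0, 1)")
  if (abs(rho_row) >= 1 || abs(rho_col) >= 1)
    stop_fmt("spatial autocorrelations must be strictly inside (-1, 1)")
  if (spatial_var < 0 || nugget < 0)
    stop_fmt("variances must be >= 0")
  if (var_g <= 0) stop_fmt("var_g must be > 0")
  structure(list(n_qtl = n_qtl, var_g = var_g, h2 = h2, h2_basis = h2_basis,
                 scale_to_h2 = scale_to_h2, rho_row = rho_row,
                 rho_col = rho_col, spatial_var = spatial_var,
                 nugget = nugget, site_means = site_means),
            class = "trait_model")
}

#' Simulate true additive genetic values
#'
#' Picks `n_qtl` QTL among the marker columns (or uses the supplied ones),
#' draws standard normal additive effects (or uses the supplied ones), and
#' returns centred genetic values \eqn{g = W_q a - \bar{g}}.
#'
#' @param geno dosage matrix (lines x markers), e.g. from
#'   [simulate_population()].
#' @param model a [trait_model()] (supplies `n_qtl`).
#' @param qtl optional integer vector of QTL column indices.
#' @param effects optional numeric vector of additive effects (same length
#'   as the QTL set).
#' @param seed optional integer seed.
#' @return named numeric vector of centred genetic values with attributes
#'   `qtl` and `effects`.
#' @export
simulate_trait <- function(geno, model = trait_model(), qtl = NULL,
                           effects = NULL, seed = NULL) {
  stopifnot(is.matrix(geno))
  local_seed(seed)
  m <- ncol(geno)
  if (is.null(qtl)) {
    qtl <- if (is.null(model$n_qtl)) seq_len(m)
           else sort(sample.int(m, min(model$n_qtl, m)))
  }
  if (any(qtl < 1 | qtl > m)) stop_fmt("QTL indices outside marker columns")
  drawn <- is.null(effects)
  effects <- effects %||% stats::rnorm(length(qtl))
  if (length(effects) != length(qtl))
    stop_fmt("need one effect per QTL (%d vs %d)", length(effects), length(qtl))
  g <- drop(geno[, qtl, drop = FALSE] %*% effects)
  g <- g - mean(g)
  if (drawn && stats::var(g) > 0) {   # put drawn traits on the stated scale
    sc <- sqrt(model$var_g / stats::var(g))
    g <- g * sc
    effects <- effects * sc
  }
  names(g) <- rownames(geno)
  attr(g, "qtl") <- qtl
  attr(g, "effects") <- effects
  g
}

#' Genetic variance on the scale of a relationship matrix
#'
#' Two ways of expressing the variance of simulated genetic values on the
#' scale the GBLUP model uses (\eqn{g \sim N(0, G\sigma^2_g)}).
#' `gscale_variance` is the closed-form maximum-likelihood value
#' \eqn{g' G^{-1} g / N}; it is exact when `g` truly has covariance
#' proportional to `G`.  `genetic_variance_reml` instead runs the package's
#' own REML machinery on the noiseless genetic values: when the trait is
#' driven by a QTL subset, `cov(g)` is not exactly proportional to `G` and
#' part of the genetic variance is invisible to a G-based model; the REML
#' value is the genetic variance *as the analysis defines it* and is what
#' the trial simulator uses to calibrate noise against the heritability
#' target, so that the heritability later estimated through the pipeline is
#' centred on the target.
#'
#' @param g numeric vector of genetic values (named when `G` has dimnames).
#' @param G relationship matrix over the same lines.
#' @param epsilon ridge added to G before solving.
#' @return scalar variance.
#' @export
gscale_variance <- function(g, G, epsilon = 1e-6) {
  stopifnot(length(g) == nrow(G))
  G2 <- unclass(G) + diag(epsilon, nrow(G))
  as.numeric(crossprod(g, solve(G2, g))) / length(g)
}

#' @rdname gscale_variance
#' @export
genetic_variance_reml <- function(g, G, epsilon = 1e-6) {
  ids <- intersect(names(g) %||% rownames(G), rownames(G))
  y <- if (is.null(names(g))) stats::setNames(g, rownames(G)) else g
  vc <- suppressWarnings(fit_aireml(y[ids], stabilize(G, epsilon)))
  vc$sigma2_g
}
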