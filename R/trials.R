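#' Trial allocation specification
#'
#' Describes how lines are allocated to the four yield trials (2 sites x
#' 2 seasons).  The `"unbalanced"` scheme emulates a highly unbalanced
#' multi-season series: crosses are split into three groups, A (present in
#' season 1 with one location replicated), B (present in season 1
#' unreplicated), and C (absent in season 1, replicated in season 2).
#' Per-line plot counts over the trials (Cambridge-16, Duxford-16,
#' Duxford-17, Hinxton-17 by default) are:
#' group A one of (2,1,1,0), (2,1,0,1), (1,2,1,0), (1,2,0,1) in balanced
#' proportions; group B (1,1,1,1); group C (0,0,2,2).  Every line totals
#' exactly 4 plots.  The `"balanced"` scheme gives every line one plot in
#' every trial.
#'
#' @param scheme `"unbalanced"` or `"balanced"`.
#' @param trials data.frame with columns `trial`, `site`, `year`, `season`
#'   (season 1 rows first).  Defaults to the 2-site x 2-season series.
#' @param group_fractions for the unbalanced scheme, fractions of crosses in
#'   groups A/B/C (defaults 22/44, 11/44, 11/44).
#' @param n_checks number of repeated check entries used to fill the grid.
#' @param plots_per_line total plots per line (fixed at 4 for the
#'   unbalanced scheme).
#' @return list of class `allocation_spec`.
#' @export
allocation_spec <- function(scheme = c("unbalanced", "balanced"),
                            trials = NULL,
                            group_fractions = c(A = 0.5, B = 0.25, C = 0.25),
                            n_checks = 2, plots_per_line = 4) {
  scheme <- match.arg(scheme)
  if (is.null(trials)) {
    trials <- data.frame(
      trial = c("T16_CAM", "T16_DUX", "T17_DUX", "T17_HIN"),
      site = c("Cambridge", "Duxford", "Duxford", "Hinxton"),
      year = c(2016L, 2016L, 2017L, 2017L),
      season = c(1L, 1L, 2L, 2L),
      stringsAsFactors = FALSE)
  }
  if (scheme == "unbalanced") {
    if (sum(trials$season == 1) != 2 || sum(trials$season == 2) != 2)
      stop_fmt("unbalanced scheme needs exactly 2 trials per season")
    if (plots_per_line != 4)
      stop_fmt("unbalanced scheme fixes plots_per_line at 4")
  }
  structure(list(scheme = scheme, trials = trials,
                 group_fractions = group_fractions,
                 n_checks = n_checks, plots_per_line = plots_per_line),
            class = "allocation_spec")
}

# Per-line plot-count patterns over the 4 trials for each group.
.group_patterns <- list(
  A = rbind(c(2, 1, 1, 0), c(2, 1, 0, 1), c(1, 2, 1, 0), c(1, 2, 0, 1)),
  B = rbind(c(1, 1, 1, 1)),
  C = rbind(c(0, 0, 2, 2))
)

#' Allocate lines of a crossing design to field plots
#'
#' Implements the allocation of [allocation_spec()]: every line receives its
#' group's plot-count pattern (patterns within group A assigned in balanced
#' proportions after a random shuffle), entries are randomly grouped into
#' contiguous sub-blocks within each trial (emulating an alpha-lattice
#' randomization), and check plots fill the grid to a full rectangle.
#'
#' @param design a [design_crosses()] result.
#' @param spec an [allocation_spec()].
#' @param seed optional integer seed.
#' @return data.frame of class `plot_table` with columns `trial`, `site`,
#'   `year`, `row`, `col`, `id`, `is_check`; attribute `grid` holds per-trial
#'   dimensions.
#' @export
allocate_trials <- function(design, spec = allocation_spec(), seed = NULL) {
  stopifnot(inherits(design, "cross_design"), inherits(spec, "allocation_spec"))
  local_seed(seed)
  cr <- design$crosses
  line_ids <- names(line_cross_map(design))
  cross_of <- line_cross_map(design)
  tr <- spec$trials
  nt <- nrow(tr)

  if (spec$scheme == "balanced") {
    if (spec$plots_per_line != nt)
      stop_fmt("balanced scheme needs plots_per_line == number of trials (%d)", nt)
    counts <- matrix(1L, nrow = length(line_ids), ncol = nt,
                     dimnames = list(line_ids, tr$trial))
  } else {
    nc <- nrow(cr)
    nB <- max(1L, round(nc * spec$group_fractions[["B"]]))
    nC <- max(1L, round(nc * spec$group_fractions[["C"]]))
    nA <- nc - nB - nC
    if (nA < 1) stop_fmt("too few crosses (%d) for the unbalanced scheme", nc)
    grp_cross <- sample(rep(c("A", "B", "C"), c(nA, nB, nC)))
    names(grp_cross) <- cr$cross
    counts <- matrix(0L, nrow = length(line_ids), ncol = nt,
                     dimnames = list(line_ids, tr$trial))
    for (g in c("A", "B", "C")) {
      ids <- line_ids[grp_cross[cross_of] == g]
      if (!length(ids)) next
      pats <- .group_patterns[[g]]
      # balanced assignment of patterns after a random shuffle
      ids <- sample(ids)
      pat_idx <- rep_len(seq_len(nrow(pats)), length(ids))
      counts[ids, ] <- pats[pat_idx, , drop = FALSE]
    }
    if (!all(rowSums(counts) == spec$plots_per_line))
      stop_fmt("internal error: allocation does not give %d plots per line",
               spec$plots_per_line)
    attr(counts, "groups") <- grp_cross
  }

  check_ids <- if (spec$n_checks > 0) paste0("CHK", seq_len(spec$n_checks)) else character(0)
  out <- vector("list", nt)
  grid <- data.frame(trial = tr$trial, n_rows = 0L, n_cols = 0L)
  for (t in seq_len(nt)) {
    entries <- rep(line_ids, counts[, t])
    n_entry <- length(entries)
    total_min <- n_entry + length(check_ids)     # every check at least once
    ncol_t <- max(1L, floor(sqrt(total_min)))
    nrow_t <- ceiling(total_min / ncol_t)
    fill <- nrow_t * ncol_t - n_entry
    checks <- if (length(check_ids)) rep_len(check_ids, fill) else character(0)
    if (!length(check_ids) && fill > 0) {        # no checks: shrink last column
      nrow_t <- ceiling(n_entry / ncol_t)
      fill <- 0
    }
    all_entries <- sample(c(entries, checks))    # sub-block randomization
    n_tot <- length(all_entries)
    idx <- seq_len(n_tot)
    out[[t]] <- data.frame(
      trial = tr$trial[t], site = tr$site[t], year = tr$year[t],
      row = ((idx - 1L) %% nrow_t) + 1L,
      col = ((idx - 1L) %/% nrow_t) + 1L,
      id = all_entries,
      is_check = all_entries %in% check_ids,
      stringsAsFactors = FALSE)
    grid$n_rows[t] <- nrow_t; grid$n_cols[t] <- ncol_t
  }
  pt <- do.call(rbind, out)
  rownames(pt) <- NULL
  class(pt) <- c("plot_table", "data.frame")
  attr(pt, "grid") <- grid
  attr(pt, "groups") <- attr(counts, "groups")
  pt
}

ar1_cor <- function(n, rho) {
  if (abs(rho) >= 1) stop_fmt("AR1 autocorrelation must satisfy |rho| < 1")
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

#' Simulate plot yields on allocated trials
#'
#' Plot yield = trial mean + line genetic value + spatial field + nugget.
#' The spatial field of each trial is a separable AR1(`rho_row`) x
#' AR1(`rho_col`) Gaussian process with unit marginal variance, scaled by
#' the spatial variance.  When `model$scale_to_h2` is TRUE the total
#' non-genetic plot variance `v` is calibrated so the heritability on the
#' model's `h2_basis` equals the target (see [trait_model()]), and is split
#' between spatial and nugget according to their relative weights.  Checks
#' absent from `g` receive their own genetic values drawn from the line
#' distribution.
#'
#' @param assignments a `plot_table` from [allocate_trials()].
#' @param g named vector of genetic values from [simulate_trait()].
#' @param model a [trait_model()].
#' @param sigma2_g genetic variance used for heritability calibration;
#'   defaults to the G-scale variance if `G` is given, else `var(g)`.
#' @param G optional relationship matrix for [gscale_variance()].
#' @param seed optional integer seed.
#' @return the `plot_table` with a `yield` column; attributes `true_g`,
#'   `sigma2_spatial`, `sigma2_nugget`, `v_plot` record generator internals.
#' @export
simulate_trials <- function(assignments, g, model = trait_model(),
                            sigma2_g = NULL, G = NULL, seed = NULL) {
  stopifnot(inherits(assignments, "plot_table"))
  if (abs(model$rho_row) >= 1 || abs(model$rho_col) >= 1)
    stop_fmt("AR1 autocorrelation must satisfy |rho| < 1")
  local_seed(seed)
  pt <- as.data.frame(assignments)
  lines_needed <- unique(pt$id)
  missing_g <- setdiff(lines_needed, names(g))
  non_check_missing <- setdiff(missing_g, unique(pt$id[pt$is_check]))
  if (length(non_check_missing))
    stop_fmt("no genetic value for line(s): %s",
             paste(utils::head(non_check_missing, 5), collapse = ", "))
  gg <- g
  if (length(missing_g)) {     # checks get their own genetic values
    sdg <- stats::sd(g)
    if (!is.finite(sdg)) sdg <- 0
    gg <- c(g, stats::setNames(stats::rnorm(length(missing_g), 0, sdg), missing_g))
  }

  w_tot <- model$spatial_var + model$nugget
  if (model$scale_to_h2 && w_tot > 0) {
    if (is.null(sigma2_g))
      sigma2_g <- if (!is.null(G)) genetic_variance_reml(g, G) else stats::var(g)
    if (sigma2_g <= 0)
      stop_fmt("zero genetic variance with a heritability target > 0")
    v <- .calibrate_v(sigma2_g, model, pt)
    s2_spatial <- v * model$spatial_var / w_tot
    s2_nugget <- v * model$nugget / w_tot
  } else {
    s2_spatial <- model$spatial_var
    s2_nugget <- model$nugget
  }

  trials <- unique(pt$trial)
  mu <- rep_len(model$site_means, length(trials))
  if (!is.null(names(model$site_means)) &&
      all(trials %in% names(model$site_means)))
    mu <- model$site_means[trials]
  names(mu) <- trials

  pt$yield <- NA_real_
  for (t in trials) {
    sel <- pt$trial == t
    r <- pt$row[sel]; cc <- pt$col[sel]
    nr <- max(r); nc <- max(cc)
    fld <- 0
    if (s2_spatial > 0) {
      Ur <- chol(ar1_cor(nr, model$rho_row))
      Uc <- chol(ar1_cor(nc, model$rho_col))
      Fm <- t(Ur) %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% Uc
      fld <- sqrt(s2_spatial) * Fm[cbind(r, cc)]
    }
    pt$yield[sel] <- mu[[t]] + gg[pt$id[sel]] + fld +
      stats::rnorm(sum(sel), 0, sqrt(s2_nugget))
  }
  class(pt) <- c("plot_table", "data.frame")
  attr(pt, "grid") <- attr(assignments, "grid")
  attr(pt, "true_g") <- gg
  attr(pt, "sigma2_spatial") <- s2_spatial
  attr(pt, "sigma2_nugget") <- s2_nugget
  attr(pt, "v_plot") <- s2_spatial + s2_nugget
  pt
}

# Total non-genetic plot variance v meeting the heritability target on the
# model's basis.  For "pm-locations" the target is the mean over lines of
# s2g / (s2g + v / n_loc), solved by uniroot (monotone in v).
.calibrate_v <- function(sigma2_g, model, pt) {
  h2 <- model$h2
  lines_only <- pt[!pt$is_check, ]
  n_plots <- table(lines_only$id)
  npl <- as.numeric(n_plots)[1]
  switch(model$h2_basis,
    "plot" = sigma2_g * (1 - h2) / h2,
    "line-mean" = npl * sigma2_g * (1 - h2) / h2,
    "pm-locations" = {
      n_loc <- tapply(lines_only$trial, lines_only$id,
                      function(x) length(unique(x)))
      n_loc <- as.numeric(n_loc)
      f <- function(v) mean(sigma2_g / (sigma2_g + v / n_loc)) - h2
      upper <- 1000 * npl * sigma2_g
      if (f(upper) > 0) return(upper)
      stats::uniroot(f, c(0, upper), tol = 1e-10)$root
    })
}
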