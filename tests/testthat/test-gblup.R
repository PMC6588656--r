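# Independent REML oracle: dense restricted log-likelihood evaluated from
# first principles (determinants and solves), maximized by grid + refinement.
dense_reml_ll <- function(y, K, sg, se) {
  n <- length(y)
  V <- sg * K + diag(se, n)
  x <- rep(1, n)
  Vi <- solve(V)
  sxx <- drop(crossprod(x, Vi %*% x))
  beta <- drop(crossprod(x, Vi %*% y)) / sxx
  r <- y - beta
  -0.5 * (determinant(V)$modulus + log(sxx) + drop(crossprod(r, Vi %*% r)))
}

grid_reml <- function(y, K) {
  vy <- stats::var(y)
  lams <- exp(seq(log(1e-4), log(1e4), length.out = 120))
  best <- c(NA, NA); best_ll <- -Inf
  for (lam in lams) {      # sg = lam * se; profile se on a fine inner grid
    for (se in vy * exp(seq(-3, 1.5, length.out = 60))) {
      ll <- dense_reml_ll(y, K, lam * se, se)
      if (ll > best_ll) { best_ll <- ll; best <- c(lam * se, se) }
    }
  }
  # local refinement
  o <- stats::optim(log(best), function(p)
    -dense_reml_ll(y, K, exp(p[1]), exp(p[2])), method = "Nelder-Mead",
    control = list(reltol = 1e-12, maxit = 2000))
  exp(o$par)
}

test_that("AI-REML matches the closed-form ANOVA REML on a clone design", {
  set.seed(20)
  a <- 50; r <- 4
  sg <- 2; se <- 1
  group <- rep(seq_len(a), each = r)
  y <- stats::rnorm(a)[group] * sqrt(sg) + stats::rnorm(a * r, 0, sqrt(se))
  names(y) <- paste0("L", seq_along(y))
  K <- (outer(group, group, "==")) * 1      # clones: block of ones
  dimnames(K) <- list(names(y), names(y))
  vc <- fit_aireml(y, stabilize(K, 1e-8))
  # one-way balanced ANOVA: REML equals the method-of-moments estimators
  ybar <- tapply(y, group, mean)
  msb <- r * sum((ybar - mean(y))^2) / (a - 1)
  mse <- sum((y - ybar[group])^2) / (a * (r - 1))
  expect_equal(vc$sigma2_e, mse, tolerance = 1e-4)
  expect_equal(vc$sigma2_g, (msb - mse) / r, tolerance = 1e-4)
  expect_true(vc$converged)
})

test_that("AI-REML agrees with a brute-force likelihood maximizer on toys", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 30
    M <- matrix(sample(0:2, n * 60, replace = TRUE), n, 60,
                dimnames = list(paste0("L", 1:n), NULL))
    K <- unclass(stabilize(compute_grm(M), 1e-6))
    L <- chol(K)
    y <- drop(crossprod(L, stats::rnorm(n))) * 0.8 + stats::rnorm(n, 0, 0.9)
    names(y) <- rownames(M)
    vc <- fit_aireml(y, K)
    oracle <- grid_reml(y, K[names(y), names(y)])
    expect_equal(vc$sigma2_g, oracle[1], tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(vc$sigma2_e, oracle[2], tolerance = 1e-3, ignore_attr = TRUE)
    # likelihood at the estimate is no worse than at the start point
    expect_gte(gblup_loglik(y, K, vc$sigma2_g, vc$sigma2_e),
               gblup_loglik(y, K, stats::var(y) / 2, stats::var(y) / 2) - 1e-8)
  }
})

test_that("pure-noise data drives the genetic component to the floor", {
  set.seed(22)
  # n and m chosen so the eigenvalue spread of G identifies the variance
  # split; with m >> n, G ~ I and sigma2_g is barely identifiable from noise
  h2s <- vapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 300; m <- 500
    p <- stats::runif(m, 0.2, 0.8)
    M <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m,
                dimnames = list(paste0("L", 1:n), NULL))
    K <- stabilize(compute_grm(M))
    y <- stats::setNames(stats::rnorm(n), rownames(M))
    vc <- suppressWarnings(fit_aireml(y, K))
    vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e)
  }, 0)
  expect_lt(mean(h2s), 0.05)
})

test_that("constant response returns the boundary estimate with a warning", {
  y <- stats::setNames(rep(1, 10), paste0("L", 1:10))
  K <- diag(10); dimnames(K) <- list(names(y), names(y))
  expect_warning(vc <- fit_aireml(y, K), "constant")
  expect_identical(vc$sigma2_g, 0)
})

test_that("variance recovery is nearly unbiased over simulated data sets", {
  set.seed(23)
  est <- vapply(1:10, function(s) {
    set.seed(500 + s)
    n <- 500; m <- 1200
    p <- stats::runif(m, 0.1, 0.9)
    M <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m,
                dimnames = list(paste0("L", 1:n), NULL))
    K <- unclass(stabilize(compute_grm(M)))
    gtrue <- drop(crossprod(chol(K), stats::rnorm(n)))
    y <- stats::setNames(gtrue + stats::rnorm(n), rownames(M))
    suppressWarnings(fit_aireml(y, K))$sigma2_g
  }, 0)
  expect_lt(abs(mean(est) - 1), 0.1)
})

test_that("MME and conditional-mean prediction routes agree to 1e-8", {
  set.seed(24)
  n <- 10
  M <- matrix(stats::runif(n * 40, 0, 2), n, 40,
              dimnames = list(paste0("L", 1:n), NULL))
  G <- stabilize(compute_grm(M), 1e-4)
  y <- stats::setNames(stats::rnorm(6), rownames(M)[1:6])
  vc <- list(sigma2_g = 0.7, sigma2_e = 0.4)
  p1 <- predict_lines(vc, y, G, method = "conditional")
  p2 <- predict_lines(vc, y, G, method = "mme")
  expect_equal(p1$ghat, p2$ghat, tolerance = 1e-8)
  expect_equal(attr(p1, "mu"), attr(p2, "mu"), tolerance = 1e-8)
  expect_identical(p1$in_training, c(rep(TRUE, 6), rep(FALSE, 4)))
})

test_that("prediction limits behave: exchangeability, shrinkage, shifts", {
  set.seed(25)
  M <- matrix(sample(0:2, 8 * 30, replace = TRUE), 8, 30,
              dimnames = list(paste0("L", 1:8), NULL))
  M[8, ] <- M[1, ]       # validation clone of training line 1
  G <- stabilize(compute_grm(M), 1e-6)
  y <- stats::setNames(stats::rnorm(6), rownames(M)[1:6])
  vc <- list(sigma2_g = 1, sigma2_e = 0.5)
  pr <- predict_lines(vc, y, G)
  # equality up to the 1e-6 ridge that separates the clone rows of G
  expect_equal(pr$ghat[8], pr$ghat[1], tolerance = 1e-5)
  # sigma2_g -> 0: everything shrinks to zero
  pr0 <- predict_lines(list(sigma2_g = 0, sigma2_e = 1), y, G)
  expect_true(all(pr0$ghat == 0))
  # adding a constant to y is absorbed by the intercept
  pr_shift <- predict_lines(vc, y + 100, G)
  expect_equal(pr_shift$ghat, pr$ghat, tolerance = 1e-8)
  expect_equal(attr(pr_shift, "mu"), attr(pr, "mu") + 100, tolerance = 1e-6)
  expect_error(predict_lines(vc, stats::setNames(1:6, paste0("X", 1:6)), G),
               "absent from G")
})

test_that("heritability follows the closed form and averages over lines", {
  expect_equal(heritability(1, 1, 1), 0.5)
  expect_equal(heritability(2, 0, 1), 1)
  expect_equal(heritability(1, 1, c(1, 1, 4)),
               mean(c(0.5, 0.5, 0.8)), tolerance = 1e-12)
  expect_warning(h <- heritability(0, 0, 4), "undefined")
  expect_true(is.na(h))
})
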