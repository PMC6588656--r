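test_that("accuracy matches hand-computed Pearson cases", {
  b <- stats::setNames(c(1, 2, 3, 4), paste0("L", 1:4))
  expect_equal(accuracy(b, b, "across-all"), 1)
  expect_equal(accuracy(b, -b, "across-all"), -1)
  p <- stats::setNames(c(1, 3, 2, 4), paste0("L", 1:4))
  expect_equal(accuracy(b, p, "across-all"), 0.8, tolerance = 1e-12)
  cmap <- stats::setNames(rep(c("C1", "C2"), each = 2), paste0("L", 1:4))
  out <- accuracy(b, p, "by-cross", cmap, min_n = 2)
  expect_identical(out$cross, c("C1", "C2"))
  expect_equal(out$r, c(1, 1))
  # zero variance -> NA
  expect_true(is.na(accuracy(stats::setNames(rep(1, 4), names(b)), p, "across-all")))
})

test_that("tenfold-by-cross folds partition crosses and keep them intact", {
  d <- design_crosses(27, default_usage_spec(), 39, 5, n_lines = 3, seed = 2)
  cmap <- line_cross_map(d)
  ds <- tenfold_by_cross(d, k = 10, reps = 2, seed = 3)
  expect_length(ds, 20)
  for (r in 1:2) {
    folds <- ds[vapply(ds, function(x) x$rep == r, TRUE)]
    val_crosses <- lapply(folds, function(x) unique(cmap[x$validation]))
    expect_true(all(lengths(val_crosses) %in% 4:5))     # 44 crosses, 10 folds
    expect_setequal(unlist(val_crosses), d$crosses$cross)
    expect_identical(anyDuplicated(unlist(val_crosses)), 0L)
    for (f in folds) {
      expect_length(intersect(f$train, f$validation), 0)
      # no cross split between training and validation
      expect_length(intersect(unique(cmap[f$train]), unique(cmap[f$validation])), 0)
    }
  }
  ds2 <- tenfold_by_cross(d, k = 10, reps = 2, seed = 3)
  expect_identical(lapply(ds, `[[`, "validation"), lapply(ds2, `[[`, "validation"))
  expect_error(tenfold_by_cross(d, k = 45), "exceeds")
})

test_that("k = number of crosses reduces tenfold to leave-one-cross-out", {
  d <- design_crosses(6, usage_spec(c(2, 4), c(2, 1), c(3, 1)),
                      n_bi = 4, n_tri = 0, n_lines = 5, seed = 4)
  loco <- leave_one_cross_out(d)
  expect_length(loco, 4)
  folds <- tenfold_by_cross(d, k = 4, reps = 1, seed = 5)
  val_sets <- lapply(folds, function(x) sort(x$validation))
  expect_setequal(vapply(val_sets, paste, "", collapse = "|"),
                  vapply(lapply(loco, function(x) sort(x$validation)),
                         paste, "", collapse = "|"))
  # training size at full scale: total - 68
  dp <- design_crosses(27, default_usage_spec(), 39, 5, n_lines = 68, seed = 6)
  lp <- leave_one_cross_out(dp)
  expect_length(lp, 44)
  expect_true(all(vapply(lp, function(x) length(x$train), 0L) == 2992L - 68L))
  expect_error(leave_one_cross_out(
    design_crosses(2, usage_spec(2, 1, 1), 1, 0, seed = 1)[]), "at least 2")
})

test_that("masking removes the requested rounded fraction, reproducibly", {
  d <- design_crosses(27, default_usage_spec(), 39, 5, n_lines = 68, seed = 7)
  base <- leave_one_cross_out(d)[[1]]
  ds <- mask_training_fraction(base, fractions = c(0.5, 0.9), reps = 3, seed = 8)
  n_tr <- vapply(ds, function(x) length(x$train), 0L)
  expect_identical(n_tr[1:3], rep(2924L - 1462L, 3))
  expect_identical(n_tr[4:6], rep(2924L - as.integer(round(0.9 * 2924)), 3))
  for (x in ds) expect_length(intersect(x$train, x$validation), 0)
  # distinct repetitions differ, reruns reproduce
  expect_false(identical(sort(ds[[1]]$train), sort(ds[[2]]$train)))
  ds2 <- mask_training_fraction(base, fractions = c(0.5, 0.9), reps = 3, seed = 8)
  expect_identical(ds[[2]]$train, ds2[[2]]$train)
  expect_error(mask_training_fraction(base, fractions = 1.2), "inside")
})

test_that("crosses-by-lines grid cells have the exact product size", {
  d <- design_crosses(27, default_usage_spec(), 39, 5, n_lines = 68, seed = 9)
  vc1 <- d$crosses$cross[1]
  ds <- crosses_by_lines_grid(d, n_crosses_list = c(10, 40),
                              n_lines_list = c(10, 40),
                              validation_crosses = vc1, reps = 2, seed = 10)
  sizes <- vapply(ds, function(x) length(x$train), 0L)
  descr <- t(vapply(ds, function(x)
    c(x$descriptors$n_crosses, x$descriptors$n_lines), c(0, 0)))
  expect_identical(sizes, as.integer(descr[, 1] * descr[, 2]))
  expect_true(any(descr[, 1] == 10 & descr[, 2] == 40))
  expect_true(any(descr[, 1] == 40 & descr[, 2] == 10))
  cmap <- line_cross_map(d)
  for (x in ds) expect_false(vc1 %in% cmap[x$train])
  # infeasible cells are skipped with a message
  expect_message(
    out <- crosses_by_lines_grid(d, n_crosses_list = 50, n_lines_list = 10,
                                 validation_crosses = vc1, reps = 1, seed = 1),
    "skipped")
  expect_length(out, 0)
})

test_that("relatedness classification follows shared pedigree parents", {
  d <- design_crosses(6, usage_spec(c(2, 4), c(2, 1), c(2, 1)),
                      n_bi = 4, n_tri = 0, n_lines = 4, seed = 11)
  cr <- d$crosses
  rel <- classify_relatedness(d, cr$cross[1])
  vp <- cross_parents(d, cr$cross[1])
  for (other in names(rel)) {
    shared <- length(intersect(cross_parents(d, other), vp)) > 0
    expect_identical(unname(rel[other]), if (shared) "related" else "unrelated")
  }
  expect_false(cr$cross[1] %in% names(rel))
  # tri-parental sharing through the third parent counts as related
  d3 <- design_crosses(5, usage_spec(5, 1, 1),
                       n_bi = 1, n_tri = 1, n_lines = 4, seed = 12)
  tri <- d3$crosses$cross[d3$crosses$type == "tri"]
  bi <- d3$crosses$cross[d3$crosses$type == "bi"]
  rel3 <- classify_relatedness(d3, tri)
  shared <- length(intersect(cross_parents(d3, bi), cross_parents(d3, tri))) > 0
  expect_identical(unname(rel3[bi]), if (shared) "related" else "unrelated")
})

test_that("relatedness designs respect quarters and composition", {
  d <- design_crosses(8, usage_spec(c(2, 2, 4), c(4, 2, 1), c(Inf, 3, 1)),
                      n_bi = 8, n_tri = 0, n_lines = 68, seed = 13)
  u <- parent_usage(d)
  vc <- d$crosses$cross[d$crosses$p1 == names(which.max(u)) |
                        d$crosses$p2 == names(which.max(u))][1]
  ds <- relatedness_designs(d, vc, "mixed", sizes = 6, n_combinations = 3,
                            quarters_in_training = c(0, 3), reps = 4, seed = 14)
  rel <- classify_relatedness(d, vc)
  cmap <- line_cross_map(d)
  qp <- quarter_partition(d, seed = child_seed(14, 999))[[vc]]
  expect_gt(length(ds), 0)
  for (x in ds) {
    expect_length(intersect(x$train, x$validation), 0)
    q <- x$descriptors$quarters_in_training
    own <- intersect(x$train, names(cmap)[cmap == vc])
    expect_identical(length(own), as.integer(q * 17))
    tr_crosses <- setdiff(unique(cmap[x$train]), vc)
    expect_identical(sum(rel[tr_crosses] == "related"), 3L)
    expect_identical(sum(rel[tr_crosses] == "unrelated"), 3L)
    expect_identical(sort(x$validation), sort(qp[[x$descriptors$eval_quarter]]))
    expect_length(x$validation, 17)
  }
})

test_that("one-sided Wald test behaves at the null, tail and boundaries", {
  expect_equal(wald_significance(0, 30), 0.5)
  expect_lt(wald_significance(0.45, 68), 0.05)
  expect_gt(wald_significance(-0.20, 68), 0.5)
  expect_equal(wald_significance(1, 10), 0)
  # oracle: direct numeric tail integral of the t density
  r <- 0.45; n <- 68
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tail <- stats::integrate(function(x) stats::dt(x, n - 2), tstat, Inf)$value
  expect_equal(wald_significance(r, n), tail, tolerance = 1e-6)
})

test_that("paired increment t test matches the textbook formula", {
  x <- c(0.30, 0.31, 0.29, 0.32)
  y <- x + c(0.01, 0.02, 0.015, 0.012)
  out <- increment_ttest(x, y)
  d <- y - x
  tstat <- mean(d) / (stats::sd(d) / sqrt(4))
  expect_equal(out$statistic, tstat, tolerance = 1e-10)
  expect_equal(out$p_value, 2 * stats::pt(-abs(tstat), 3), tolerance = 1e-10)
  # symmetry: swapping groups flips the sign, keeps p
  out2 <- increment_ttest(y, x)
  expect_equal(out2$statistic, -out$statistic, tolerance = 1e-10)
  expect_equal(out2$p_value, out$p_value, tolerance = 1e-12)
  # identical pairs -> p = 1 by convention
  expect_equal(increment_ttest(x, x)$p_value, 1)
})

test_that("top-k accuracy truncates within cross and degenerates correctly", {
  set.seed(15)
  ids <- paste0("L", 1:40)
  cmap <- stats::setNames(rep(c("C1", "C2"), each = 20), ids)
  b <- stats::setNames(stats::rnorm(40), ids)
  p <- b + stats::rnorm(40, 0, 0.5)
  full <- top_fraction_accuracy(b, p, cmap, k = 20)
  ref <- accuracy(b, p, "by-cross", cmap)
  expect_equal(full$r, ref$r, tolerance = 1e-12)
  perfect <- top_fraction_accuracy(b, b, cmap, k = 5)
  expect_equal(perfect$r, c(1, 1))
  expect_error(top_fraction_accuracy(b, p, cmap, k = 25), "fewer than")
  trunc5 <- top_fraction_accuracy(b, p, cmap, k = 5)
  for (cr in c("C1", "C2")) {
    top_ids <- names(sort(b[cmap == cr], decreasing = TRUE))[1:5]
    expect_equal(trunc5$r[trunc5$cross == cr],
                 stats::cor(b[top_ids], p[top_ids]), tolerance = 1e-12)
  }
})

test_that("run_designs refits per design and returns tidy accuracies", {
  w <- small_world()
  ds <- leave_one_cross_out(w$design)[1:3]
  res <- run_designs(ds, w$yb, w$Gs, w$cmap)
  expect_s3_class(res, "cv_result")
  expect_identical(nrow(res), 6L)              # per-cross + pooled rows
  expect_true(all(res$r >= -1 & res$r <= 1, na.rm = TRUE))
  expect_true(all(res$n_train == length(w$yb) - 20))
  expect_true(all(c("sigma2_g", "cross", "r") %in% names(res)))
})
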