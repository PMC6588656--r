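test_that("genetic map validates ordering and emptiness", {
  expect_error(genetic_map(character(0), numeric(0)), "at least one marker")
  expect_error(genetic_map(c(1, 1), c(5, 5)), "strictly increasing")
  expect_error(genetic_map(1, -2), ">= 0")
  gm <- sim_genetic_map(100, 5, 80, seed = 3)
  expect_s3_class(gm, "genetic_map")
  expect_identical(nrow(gm), 100L)
  for (p in split(gm$pos_cM, gm$chr)) expect_true(all(diff(p) > 0))
})

test_that("founders are fully inbred and deterministic under a seed", {
  map <- toy_map(40)
  f1 <- generate_founders(6, map, seed = 11)
  f2 <- generate_founders(6, map, seed = 11)
  expect_identical(f1$haplotypes, f2$haplotypes)
  expect_true(all(f1$haplotypes %in% c(0L, 1L)))
  one <- generate_founders(1, map, seed = 2)
  expect_identical(dim(one$haplotypes), c(1L, 40L))
  expect_error(generate_founders(3, structure(list(), class = "genetic_map")),
               "non-empty")
})

test_that("uniform-spectrum founder allele frequencies average near 0.5", {
  map <- sim_genetic_map(2000, 10, 100, seed = 21)
  f <- generate_founders(27, map, seed = 22)
  freqs <- colMeans(f$haplotypes)
  # mean over markers of Binomial(27, p)/27 draws, p ~ U(0.05, 0.95):
  # SE ~ sqrt(var(p)/m + mean(p(1-p))/(27 m)) ~ 0.006; allow 4 SE
  expect_lt(abs(mean(freqs) - 0.5), 0.025)
})

test_that("identical homozygous parents segregate nothing", {
  map <- toy_map(30)
  f <- generate_founders(1, map, seed = 4)
  par2 <- rbind(f$haplotypes, f$haplotypes)
  g <- simulate_cross(par2, n_lines = 12, map = map, seed = 5)
  expect_true(all(g == rep(2 * as.numeric(f$haplotypes[1, ]), each = 12)))
})

test_that("parent-count validation and dosage bounds hold", {
  map <- toy_map(20)
  f <- generate_founders(4, map, seed = 6)
  expect_error(simulate_cross(f$haplotypes[1, , drop = FALSE], 5, map), "2 or 3")
  expect_error(simulate_cross(f$haplotypes, 5, map), "2 or 3")
  for (s in 1:5) {
    g <- simulate_cross(f$haplotypes[1:3, ], 15, map, seed = s)
    expect_true(all(g >= 0 & g <= 2))
  }
})

test_that("zero-distance markers never recombine", {
  map <- genetic_map(chr = c(1, 1), pos_cM = c(10, 10 + 1e-9))
  parents <- rbind(c(1L, 0L), c(0L, 1L))   # repulsion-phase parents
  g <- simulate_cross(parents, 300, map, bulk_size = 1, seed = 8)
  # recombinant gametes would create dosage pairs other than (x, 2 - x)
  expect_true(all(abs(g[, 1] + g[, 2] - 2) < 1e-12))
})

test_that("F4 heterozygosity matches the (1/2)^3 closed form", {
  # independent brute-force oracle: single locus, transmission only.
  # F1 is Aa; each selfing generation halves the heterozygosity, so the
  # F4 plants of an F2:4 line are heterozygous with probability 1/8.
  set.seed(99)
  n <- 2e5
  het <- rep(TRUE, n)                     # F1 -> F2 -> F3 -> F4: 3 selfings
  for (gen in 1:3) {
    child_het <- ifelse(het, stats::runif(n) < 0.5, FALSE)
    # homozygous parents breed true; heterozygous parents give Aa w.p. 1/2
    het <- child_het
  }
  oracle_rate <- mean(het)
  expect_lt(abs(oracle_rate - 1 / 8), 3 * sqrt(0.125 * 0.875 / n))

  # implementation: one marker, parents fixed for opposite alleles,
  # bulk_size 1 so each line is a single F4 plant (dosage 1 <=> heterozygous)
  map <- one_marker_map()
  parents <- rbind(0L, 1L)
  nl <- 3e4
  g <- simulate_cross(parents, nl, map, bulk_size = 1, seed = 17)
  expect_lt(abs(mean(g) - 1), 4 * sqrt(0.5 / nl) * 2)  # expected dosage 1
  het_rate <- mean(g == 1)
  expect_lt(abs(het_rate - 1 / 8), 3 * sqrt(0.125 * 0.875 / nl))
})

test_that("within-cross allele frequency equals the parental mean dosage / 2", {
  map <- genetic_map(chr = c(1, 1, 2, 2), pos_cM = c(0, 60, 0, 60))
  parents <- rbind(c(1L, 0L, 1L, 1L), c(0L, 0L, 1L, 0L))
  nl <- 1e4
  g <- simulate_cross(parents, nl, map, bulk_size = 2, seed = 23)
  expected <- colMeans(rbind(2 * parents[1, ], 2 * parents[2, ]))
  for (j in 1:4) {
    tol <- 3 * stats::sd(g[, j]) / sqrt(nl) + 1e-12
    expect_lt(abs(mean(g[, j]) - expected[j]), tol + 1e-9)
  }
})

test_that("population simulation is reproducible and tracks crosses", {
  w <- small_world()
  expect_identical(nrow(w$geno), sum(w$design$crosses$n_lines))
  expect_true(all(w$geno >= 0 & w$geno <= 2))
  g2 <- simulate_population(w$design, w$founders, seed = 104)
  expect_identical(w$geno[, ], g2[, ])
  expect_identical(attr(w$geno, "cross")[rownames(w$geno)[1]],
                   stats::setNames("C01", "C01_1"))
})

test_that("trait values are centred, linear in dosage, and scale as stated", {
  geno <- rbind(A = c(0, 1), B = c(2, 1))
  g <- simulate_trait(geno, qtl = 1L, effects = 1, seed = 1)
  expect_equal(as.vector(g), c(-1, 1))
  g0 <- simulate_trait(geno, qtl = 1:2, effects = c(0, 0))
  expect_true(all(g0 == 0))
  w <- small_world()
  expect_equal(stats::var(w$g), trait_model()$var_g, tolerance = 1e-10)
  expect_error(simulate_trait(geno, qtl = 5L, effects = 1), "outside")
})

test_that("unbalanced allocation gives every line exactly 4 plots", {
  w <- small_world()
  pt <- w$plots
  lines_only <- pt[!pt$is_check, ]
  plots_per_line <- table(lines_only$id)
  expect_identical(length(plots_per_line), nrow(w$geno))
  expect_identical(range(as.integer(plots_per_line)), c(4L, 4L))
  # (trial, row, col) unique
  expect_false(anyDuplicated(pt[, c("trial", "row", "col")]) > 0)
})

test_that("balanced allocation puts each line once in every trial", {
  d <- design_crosses(2, usage_spec(2, 1, 1), n_bi = 1, n_tri = 0,
                      n_lines = 2, seed = 3)
  spec <- allocation_spec("balanced", n_checks = 0)
  pt <- allocate_trials(d, spec, seed = 4)
  tab <- table(pt$id, pt$trial)
  expect_true(all(tab == 1))
  expect_identical(nrow(pt), 8L)
})

test_that("noiseless trials return site mean plus genetic value exactly", {
  d <- design_crosses(2, usage_spec(2, 1, 1), n_bi = 1, n_tri = 0,
                      n_lines = 6, seed = 3)
  pt0 <- allocate_trials(d, allocation_spec("balanced", n_checks = 0), seed = 4)
  g <- stats::setNames(seq(-0.5, 0.5, length.out = 6), paste0("C01_", 1:6))
  tm <- trait_model(scale_to_h2 = FALSE, spatial_var = 0, nugget = 0,
                    site_means = c(10, 20, 30, 40))
  pt <- simulate_trials(pt0, g, tm, seed = 5)
  mu <- c(10, 20, 30, 40)[match(pt$trial, unique(pt$trial))]
  expect_equal(pt$yield, mu + unname(g[pt$id]), tolerance = 1e-12)
})

test_that("simulated spatial field has the requested lag-1 autocorrelation", {
  nr <- 50; nc <- 60
  ids <- paste0("L", seq_len(nr * nc))
  pt0 <- grid_plot_table(nr, nc, ids, yield = rep(0, nr * nc))
  pt0$yield <- NULL
  g <- stats::setNames(rep(0, nr * nc), ids)
  lag1 <- function(rho) {
    tm <- trait_model(scale_to_h2 = FALSE, rho_row = rho, rho_col = rho,
                      spatial_var = 1, nugget = 0, site_means = 0)
    pt <- simulate_trials(pt0, g, tm, seed = 31)
    fld <- matrix(NA_real_, nr, nc)
    fld[cbind(pt$row, pt$col)] <- pt$yield
    stats::cor(as.vector(fld[-1, ]), as.vector(fld[-nr, ]))
  }
  expect_lt(abs(lag1(0)), 0.05)
  expect_lt(abs(lag1(0.6) - 0.6), 0.1)
})

test_that("trial simulation rejects invalid autocorrelations and flat traits", {
  w <- small_world()
  expect_error(trait_model(rho_row = 1), "inside")
  g0 <- stats::setNames(rep(0, nrow(w$geno)), rownames(w$geno))
  assign <- allocate_trials(w$design, allocation_spec(), seed = 1)
  expect_error(suppressWarnings(
    simulate_trials(assign, g0, trait_model(), seed = 1)),
    "zero genetic variance")
})

test_that("csv round-trips preserve genotypes, maps and plots", {
  w <- small_world()
  tmp <- withr::local_tempdir()
  p1 <- file.path(tmp, "g.csv")
  write_dosage_csv(w$geno, p1)
  g2 <- read_dosage_csv(p1)
  expect_equal(unname(g2), unname(w$geno[, ]), tolerance = 1e-12)
  p2 <- file.path(tmp, "m.csv")
  write_map_csv(w$map, p2)
  m2 <- read_map_csv(p2)
  expect_equal(m2$pos_cM, w$map$pos_cM, tolerance = 1e-12)
  p3 <- file.path(tmp, "p.csv")
  write_plots_csv(w$plots, p3)
  pt2 <- read_plots_csv(p3)
  expect_equal(pt2$yield, w$plots$yield, tolerance = 1e-12)
})
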