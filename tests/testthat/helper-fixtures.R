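# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

toy_map <- function(n_markers = 50, n_chr = 5, len = 100, seed = 7) {
  sim_genetic_map(n_markers, n_chr, len, seed = seed)
}

# single-marker map: a degenerate but legal one-chromosome map
one_marker_map <- function() genetic_map(chr = "chr1", pos_cM = 0)

# a small multi-cross world with genotypes, trait, plots, BLUEs and G
small_world <- function() {
  cached("small_world", function() {
    design <- design_crosses(
      n_parents = 8,
      spec = usage_spec(n_parents = c(2, 2, 4), min_crosses = c(3, 2, 1),
                        max_crosses = c(Inf, 2, 1)),
      n_bi = 6, n_tri = 1, n_lines = 20, seed = 101)
    map <- sim_genetic_map(300, 7, 120, seed = 102)
    founders <- generate_founders(8, map, seed = 103)
    geno <- simulate_population(design, founders, seed = 104)
    G <- compute_grm(filter_segregating(geno))
    tm <- trait_model()
    gv <- simulate_trait(geno, tm, seed = 105)
    assign <- allocate_trials(design, allocation_spec(), seed = 106)
    plots <- simulate_trials(assign, gv, tm, G = G, seed = 107)
    adj <- adjust_trials(plots)
    blues <- estimate_blues(adj$plots)
    bl <- blues[!blues$is_check, , drop = FALSE]
    list(design = design, map = map, founders = founders, geno = geno,
         G = G, Gs = stabilize(G), g = gv, plots = plots, adj = adj,
         blues = blues, yb = stats::setNames(bl$blue, bl$id),
         cmap = line_cross_map(design))
  })
}

# reduced-scale stated world for the trend criteria:
# 15 crosses (12 bi + 3 tri) x 40 lines, 1,000 markers, 4 unbalanced trials
desk_world <- function() {
  cached("desk_world", function() {
    seed <- 20240915
    design <- design_crosses(
      n_parents = 12,
      spec = usage_spec(n_parents = c(2, 3, 7), min_crosses = c(4, 2, 1),
                        max_crosses = c(Inf, 3, 1)),
      n_bi = 12, n_tri = 3, n_lines = 40, seed = child_seed(seed, 1))
    map <- sim_genetic_map(1000, 21, 150, seed = child_seed(seed, 2))
    founders <- generate_founders(12, map, seed = child_seed(seed, 3))
    geno <- simulate_population(design, founders, seed = child_seed(seed, 4))
    G <- compute_grm(filter_segregating(geno))
    tm <- trait_model()
    gv <- simulate_trait(geno, tm, seed = child_seed(seed, 5))
    assign <- allocate_trials(design, allocation_spec(), seed = child_seed(seed, 6))
    plots <- simulate_trials(assign, gv, tm, G = G, seed = child_seed(seed, 7))
    adj <- adjust_trials(plots)
    blues <- estimate_blues(adj$plots)
    bl <- blues[!blues$is_check, , drop = FALSE]
    list(design = design, geno = geno, G = G, Gs = stabilize(G), g = gv,
         plots = plots, adj = adj, blues = blues,
         yb = stats::setNames(bl$blue, bl$id),
         cmap = line_cross_map(design), seed = seed)
  })
}

# wider world (30 crosses x 40 lines) for the fixed-size crosses-vs-lines
# comparison: the advantage of many crosses needs a cross pool comparable to
# the study's 44 (a 15-cross pool saturates both arms with relatives)
wide_world <- function() {
  cached("wide_world", function() {
    seed <- 20240916
    design <- design_crosses(
      n_parents = 20,
      spec = usage_spec(c(4, 5, 11), c(5, 2, 1), c(Inf, 3, 1)),
      n_bi = 26, n_tri = 4, n_lines = 40, seed = child_seed(seed, 1))
    map <- sim_genetic_map(1000, 21, 150, seed = child_seed(seed, 2))
    founders <- generate_founders(20, map, seed = child_seed(seed, 3))
    geno <- simulate_population(design, founders, seed = child_seed(seed, 4))
    G <- compute_grm(filter_segregating(geno))
    tm <- trait_model()
    gv <- simulate_trait(geno, tm, seed = child_seed(seed, 5))
    assign <- allocate_trials(design, allocation_spec(), seed = child_seed(seed, 6))
    plots <- simulate_trials(assign, gv, tm, G = G, seed = child_seed(seed, 7))
    adj <- adjust_trials(plots)
    blues <- estimate_blues(adj$plots)
    bl <- blues[!blues$is_check, , drop = FALSE]
    list(design = design, G = G, Gs = stabilize(G),
         yb = stats::setNames(bl$blue, bl$id),
         cmap = line_cross_map(design), seed = seed)
  })
}

# mean per-cross accuracy of a cv_result table
mean_bycross <- function(res) {
  mean(res$r[res$cross != "(all)"], na.rm = TRUE)
}

# hand-built single-trial plot table on a full grid
grid_plot_table <- function(nr, nc, ids, yield, trial = "T1") {
  n <- nr * nc
  stopifnot(length(ids) == n, length(yield) == n)
  pt <- data.frame(trial = trial, site = "S", year = 2016L,
                   row = rep(seq_len(nr), nc),
                   col = rep(seq_len(nc), each = nr),
                   id = ids, is_check = FALSE, yield = yield,
                   stringsAsFactors = FALSE)
  class(pt) <- c("plot_table", "data.frame")
  pt
}
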