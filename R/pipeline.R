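#' Default pipeline configuration
#'
#' `preset = "full"` encodes the full-scale stated world: 27 parents, 39
#' bi-parental + 5 tri-parental crosses, 68 F2:4 lines per cross (2,992
#' lines), 2,000 markers on 21 chromosomes, 4 trials with the unbalanced
#' allocation, and a heritability target of 0.65.  `preset = "desk"` is a
#' reduced world (15 crosses x 40 lines, 1,000 markers) that runs the whole
#' pipeline in minutes on one CPU.
#'
#' @param preset `"full"` or `"desk"`.
#' @param seed master seed stored in the config.
#' @return a nested list of class `run_config`.
#' @export
default_config <- function(preset = c("full", "desk"), seed = 1L) {
  preset <- match.arg(preset)
  cfg <- if (preset == "full") {
    list(
      population = list(n_parents = 27L, n_bi = 39L, n_tri = 5L,
                        lines_per_cross = 68L,
                        usage = list(n_parents = c(5L, 6L, 1L, 15L),
                                     min_crosses = c(6, 3, 2, 1),
                                     max_crosses = c(Inf, 4, 2, 1)),
                        bulk_size = 6L),
      genome = list(n_markers = 2000L, n_chr = 21L, chr_length_cM = 150),
      trait = list(n_qtl = NULL, h2 = 0.65, rho_row = 0.4, rho_col = 0.4,
                   spatial_var = 1, nugget = 1),
      trials = list(scheme = "unbalanced", n_checks = 2L),
      cv = list(schemes = c("loco", "tenfold_crosses"), reps = 10L, k = 10L),
      seed = as.integer(seed))
  } else {
    list(
      population = list(n_parents = 12L, n_bi = 12L, n_tri = 3L,
                        lines_per_cross = 40L,
                        usage = list(n_parents = c(2L, 3L, 7L),
                                     min_crosses = c(4, 2, 1),
                                     max_crosses = c(Inf, 3, 1)),
                        bulk_size = 6L),
      genome = list(n_markers = 1000L, n_chr = 21L, chr_length_cM = 150),
      trait = list(n_qtl = NULL, h2 = 0.65, rho_row = 0.4, rho_col = 0.4,
                   spatial_var = 1, nugget = 1),
      trials = list(scheme = "unbalanced", n_checks = 2L),
      cv = list(schemes = c("loco"), reps = 2L, k = 5L),
      seed = as.integer(seed))
  }
  structure(cfg, class = "run_config")
}

.known_schemes <- c("loco", "tenfold_crosses", "tenfold_random")

#' Validate a pipeline configuration
#' @param config a `run_config` (or plain list with the same fields).
#' @return the config, invisibly; errors describe the first problem found.
#' @export
validate_config <- function(config) {
  need <- c("population", "genome", "trait", "trials", "cv", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop_fmt("config is missing section(s): %s", paste(miss, collapse = ", "))
  unknown <- setdiff(config$cv$schemes, .known_schemes)
  if (length(unknown))
    stop_fmt("unknown CV scheme(s): %s (known: %s)",
             paste(unknown, collapse = ", "), paste(.known_schemes, collapse = ", "))
  with(config$population, {
    if (n_bi + n_tri < 2) stop_fmt("need at least 2 crosses")
  })
  if (config$trait$h2 <= 0 || config$trait$h2 >= 1)
    stop_fmt("trait h2 must be inside (0, 1)")
  invisible(config)
}

#' Read / write a configuration as JSON
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$population$usage <- lapply(cfg$population$usage, function(x) {
    x[x == "Inf"] <- Inf
    as.numeric(x)
  })
  structure(cfg, class = "run_config")
}

#' Run the full simulate-adjust-BLUE-GRM-GBLUP-CV pipeline
#'
#' Executes the seven stages in order, writing every intermediate artifact
#' as CSV under `out_dir` plus a JSON manifest with seeds, stage wall times
#' and file checksums.  All randomness derives from the master seed, so a
#' rerun with the same config is byte-identical.
#'
#' @param config a [default_config()]-style configuration.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage messages.
#' @return list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package = "crosspred",
                   version = as.character(utils::packageVersion("crosspred")),
                   seed = seed, stages = list())
  t_all <- proc.time()[3]
  stage <- function(name, files, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e)
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    dt <- proc.time()[3] - t0
    manifest$stages[[name]] <<- list(
      files = files, seconds = round(dt, 2),
      md5 = as.list(tools::md5sum(file.path(out_dir, files))))
    say("stage %-9s done in %6.1fs  [%s]", name, dt, paste(files, collapse = ", "))
    res
  }

  pop <- config$population
  usage <- do.call(usage_spec, pop$usage)
  design <- design_crosses(pop$n_parents, usage, pop$n_bi, pop$n_tri,
                           pop$lines_per_cross, seed = child_seed(seed, 1))
  map <- sim_genetic_map(config$genome$n_markers, config$genome$n_chr,
                         config$genome$chr_length_cM, seed = child_seed(seed, 2))
  founders <- generate_founders(pop$n_parents, map, seed = child_seed(seed, 3))

  geno <- stage("genotypes", c("genotypes.csv", "map.csv"), function() {
    g <- simulate_population(design, founders, bulk_size = pop$bulk_size,
                             seed = child_seed(seed, 4))
    write_dosage_csv(g, file.path(out_dir, "genotypes.csv"))
    write_map_csv(map, file.path(out_dir, "map.csv"))
    g
  })

  tm <- trait_model(n_qtl = config$trait$n_qtl, h2 = config$trait$h2,
                    rho_row = config$trait$rho_row, rho_col = config$trait$rho_col,
                    spatial_var = config$trait$spatial_var,
                    nugget = config$trait$nugget)
  gseg <- filter_segregating(geno)
  G <- compute_grm(gseg)
  gv <- simulate_trait(geno, tm, seed = child_seed(seed, 5))

  plots <- stage("plots", "plots.csv", function() {
    spec <- allocation_spec(config$trials$scheme, n_checks = config$trials$n_checks)
    assign <- allocate_trials(design, spec, seed = child_seed(seed, 6))
    pt <- simulate_trials(assign, gv, tm, G = G, seed = child_seed(seed, 7))
    write_plots_csv(pt, file.path(out_dir, "plots.csv"))
    pt
  })

  adj <- stage("adjusted", c("adjusted.csv", "spatial_summary.csv"), function() {
    a <- adjust_trials(plots)
    write_plots_csv(a$plots, file.path(out_dir, "adjusted.csv"))
    data.table::fwrite(a$summary, file.path(out_dir, "spatial_summary.csv"))
    a
  })

  blues <- stage("blues", "blues.csv", function() {
    b <- estimate_blues(adj$plots)
    data.table::fwrite(as.data.frame(b), file.path(out_dir, "blues.csv"))
    b
  })

  stage("grm", c("grm.csv", "grm_sparse.txt"), function() {
    write_grm_csv(G, file.path(out_dir, "grm.csv"),
                  file.path(out_dir, "grm_sparse.txt"))
    G
  })

  is_chk <- if ("is_check" %in% names(blues)) blues$is_check else rep(FALSE, nrow(blues))
  bl <- blues[!is_chk, , drop = FALSE]
  yb <- stats::setNames(bl$blue, bl$id)
  yb <- yb[names(yb) %in% rownames(G)]
  Gs <- stabilize(G)

  vc <- stage("varcomp", "varcomp.csv", function() {
    v <- fit_aireml(yb, Gs)
    vhat <- plot_residual_variance(adj$fits)
    n_loc <- vapply(strsplit(bl$trials[match(names(yb), bl$id)], ","), length, 0L)
    h2 <- heritability(v$sigma2_g, vhat, n_loc)
    data.table::fwrite(data.frame(sigma2_g = v$sigma2_g, sigma2_e = v$sigma2_e,
                                  converged = v$converged,
                                  iterations = v$iterations,
                                  v_plot = vhat, heritability = h2),
                       file.path(out_dir, "varcomp.csv"))
    c(v, list(v_plot = vhat, heritability = h2))
  })

  cvres <- stage("cv", "cv_results.csv", function() {
    cmap <- line_cross_map(design)
    designs <- list()
    for (s in config$cv$schemes) {
      ds <- switch(s,
        loco = leave_one_cross_out(design),
        tenfold_crosses = tenfold_by_cross(design, k = config$cv$k,
                                           reps = config$cv$reps,
                                           seed = child_seed(seed, 8)),
        tenfold_random = tenfold_random(design, k = config$cv$k,
                                        reps = config$cv$reps,
                                        seed = child_seed(seed, 9)))
      designs <- c(designs, ds)
    }
    res <- run_designs(designs, yb, Gs, cmap)
    data.table::fwrite(res, file.path(out_dir, "cv_results.csv"))
    res
  })

  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: %d stages, %.1fs", length(manifest$stages),
      manifest$total_seconds)
  invisible(list(design = design, geno = geno, G = G, trait = gv,
                 plots = plots, adjusted = adj, blues = blues, varcomp = vc,
                 cv = cvres, manifest = manifest))
}
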