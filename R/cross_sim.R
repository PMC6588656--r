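# Meiosis and line development for bi- and tri-parental crosses.
#
# Individuals are pairs of haplotypes (0/1 allele vectors over the map).
# Recombination follows the Haldane model: per chromosome, crossover counts
# are Poisson with mean equal to the map length in Morgans, crossover
# positions are uniform, and there is no interference.

# Sample one gamete from an individual with haplotypes h1, h2.
# `geo` is the output of map_geometry().
sample_gamete <- function(h1, h2, geo) {
  nx <- stats::rpois(geo$n_chr, geo$len_morgan)
  tot <- sum(nx)
  if (tot > 0) {
    chr_of_bp <- rep.int(seq_len(geo$n_chr), nx)
    bp <- geo$lo_global[chr_of_bp] + stats::runif(tot) * geo$span[chr_of_bp]
    bp <- sort(bp)
    seg <- findInterval(geo$pos_global, bp)
    before <- findInterval(geo$lo_global, bp)   # breakpoints on earlier chromosomes
    seg <- seg - before[geo$chr_idx]
  } else {
    seg <- 0L
  }
  start <- sample.int(2L, geo$n_chr, replace = TRUE) - 1L
  phase <- (start[geo$chr_idx] + seg) %% 2L
  g <- h1
  take2 <- phase == 1L
  g[take2] <- h2[take2]
  g
}

self_once <- function(plant, geo) {
  list(sample_gamete(plant[[1]], plant[[2]], geo),
       sample_gamete(plant[[1]], plant[[2]], geo))
}

#' Simulate the F2:4 lines of one cross
#'
#' Bi-parental: the two inbred parents give a uniform F1; each line descends
#' from its own F2 plant (selfed F1), advanced by single-seed descent to an
#' F3 plant, whose `bulk_size` selfed F4 offspring are genotyped as a bulk.
#' The line dosage is the mean allele dosage of the bulk, so values are
#' continuous in \[0, 2\] (set `round_dosage = TRUE` for hard 0/1/2 calls).
#' Tri-parental: a three-way top-cross (P1 x P2) F1 x P3; each line descends
#' from its own three-way F1 plant and follows the same selfing chain.
#'
#' @param parents matrix of 2 or 3 founder haplotype rows (0/1), e.g. rows of
#'   `founder_pop$haplotypes`.
#' @param n_lines number of lines to derive.
#' @param map the [genetic_map()] matching the marker columns.
#' @param bulk_size number of F4 plants bulked per line (default 6).
#' @param seed optional integer seed.
#' @param round_dosage round bulk dosages to the nearest integer call.
#' @return `n_lines` x markers numeric dosage matrix in \[0, 2\].
#' @export
simulate_cross <- function(parents, n_lines, map, bulk_size = 6, seed = NULL,
                           round_dosage = FALSE) {
  parents <- as.matrix(parents)
  np <- nrow(parents)
  if (np < 2 || np > 3)
    stop_fmt("a cross needs 2 or 3 parents, got %d", np)
  stopifnot(n_lines > 0, bulk_size >= 1, ncol(parents) == nrow(map))
  local_seed(seed)
  geo <- map_geometry(map)
  m <- ncol(parents)
  p1 <- as.integer(parents[1, ]); p2 <- as.integer(parents[2, ])
  out <- matrix(0, nrow = n_lines, ncol = m,
                dimnames = list(NULL, map$marker))
  for (l in seq_len(n_lines)) {
    base <- if (np == 2) {
      list(p1, p2)                               # the uniform F1
    } else {
      # three-way F1: gamete of (P1 x P2) F1 united with the P3 gamete
      list(sample_gamete(p1, p2, geo), as.integer(parents[3, ]))
    }
    f2 <- self_once(base, geo)
    f3 <- self_once(f2, geo)
    acc <- numeric(m)
    for (b in seq_len(bulk_size)) {
      f4 <- self_once(f3, geo)
      acc <- acc + f4[[1]] + f4[[2]]
    }
    out[l, ] <- acc / bulk_size
  }
  if (round_dosage) out[] <- round(out)
  out
}

#' Simulate the full genotyped population of a crossing design
#'
#' Runs [simulate_cross()] for every cross of `design` using per-cross child
#' seeds derived from `seed`, and stacks the line dosages.  Row names are
#' `<cross>_<line number>`; the cross of origin is kept in the `"cross"`
#' attribute.
#'
#' @inheritParams simulate_cross
#' @param design a [design_crosses()] result.
#' @param founders a [generate_founders()] result.
#' @return dosage matrix (lines x markers, values in \[0, 2\]) with
#'   attributes `cross` (named character vector) and `map`.
#' @export
simulate_population <- function(design, founders, bulk_size = 6, seed = NULL,
                                round_dosage = FALSE) {
  stopifnot(inherits(design, "cross_design"), inherits(founders, "founder_pop"))
  miss <- setdiff(design$parents, rownames(founders$haplotypes))
  if (length(miss))
    stop_fmt("founders missing for parent(s): %s", paste(miss, collapse = ", "))
  cr <- design$crosses
  blocks <- vector("list", nrow(cr))
  for (i in seq_len(nrow(cr))) {
    ps <- cross_parents(design, cr$cross[i])
    g <- simulate_cross(founders$haplotypes[ps, , drop = FALSE],
                        n_lines = cr$n_lines[i], map = founders$map,
                        bulk_size = bulk_size,
                        seed = child_seed(seed, i),
                        round_dosage = round_dosage)
    rownames(g) <- paste0(cr$cross[i], "_", seq_len(cr$n_lines[i]))
    blocks[[i]] <- g
  }
  geno <- do.call(rbind, blocks)
  attr(geno, "cross") <- line_cross_map(design)
  attr(geno, "map") <- founders$map
  geno
}
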