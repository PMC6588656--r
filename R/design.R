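#' Parent-usage bucket specification
#'
#' A crossing design is constrained by "usage buckets": groups of parents
#' that must each appear in a given range of crosses.  The default mirrors a
#' commercial multi-parent trial: of 27 parents, 5 are used in 6 or more
#' crosses, 6 in 3-4 crosses, 1 in exactly 2, and the remaining 15 in a
#' single cross.
#'
#' @param n_parents number of parents per bucket.
#' @param min_crosses,max_crosses inclusive usage range per bucket
#'   (`max_crosses` may be `Inf`).
#' @return a data.frame of class `usage_spec`.
#' @export
usage_spec <- function(n_parents, min_crosses, max_crosses = min_crosses) {
  stopifnot(length(n_parents) == length(min_crosses),
            length(min_crosses) == length(max_crosses))
  if (any(n_parents < 1) || any(min_crosses < 1) || any(max_crosses < min_crosses))
    stop_fmt("invalid usage bucket: need n_parents >= 1 and min <= max")
  s <- data.frame(n_parents = as.integer(n_parents),
                  min_crosses = as.numeric(min_crosses),
                  max_crosses = as.numeric(max_crosses))
  class(s) <- c("usage_spec", "data.frame")
  s
}

#' @rdname usage_spec
#' @export
default_usage_spec <- function() {
  usage_spec(n_parents = c(5L, 6L, 1L, 15L),
             min_crosses = c(6, 3, 2, 1),
             max_crosses = c(Inf, 4, 2, 1))
}

#' Design a set of bi- and tri-parental crosses under usage constraints
#'
#' Builds a pedigree of `n_bi` two-parent and `n_tri` three-parent crosses
#' over `n_parents` parents such that each usage bucket of `spec` is
#' satisfied exactly: the number of parents whose cross count falls in a
#' bucket's range equals that bucket's size.  Parent usage counts are first
#' sampled inside the buckets, then crosses are assembled greedily, always
#' drawing the parents with the most remaining slots (random tie-break), so
#' no cross repeats a parent.
#'
#' @param n_parents number of distinct parents.
#' @param spec a [usage_spec()]; bucket ranges must be disjoint.
#' @param n_bi,n_tri number of bi-parental and tri-parental crosses.
#' @param n_lines lines per cross (all crosses equal; default 68).
#' @param seed optional integer seed.
#' @return an object of class `cross_design`: list with `parents` (character
#'   vector) and `crosses` (data.frame with `cross`, `type`, `p1`, `p2`,
#'   `p3`, `n_lines`).
#' @examples
#' d <- design_crosses(27, default_usage_spec(), n_bi = 39, n_tri = 5, seed = 1)
#' table(parent_usage(d))
#' @export
design_crosses <- function(n_parents = 27, spec = default_usage_spec(),
                           n_bi = 39, n_tri = 5, n_lines = 68, seed = NULL) {
  stopifnot(inherits(spec, "usage_spec"), n_bi >= 0, n_tri >= 0, n_lines > 0)
  n_crosses <- n_bi + n_tri
  if (n_crosses < 1) stop_fmt("need at least one cross")
  if (sum(spec$n_parents) != n_parents)
    stop_fmt("usage buckets cover %d parents but n_parents = %d",
             sum(spec$n_parents), n_parents)
  slots <- 2 * n_bi + 3 * n_tri
  cap <- pmin(spec$max_crosses, n_crosses)
  min_total <- sum(spec$n_parents * spec$min_crosses)
  max_total <- sum(spec$n_parents * cap)
  if (slots < min_total)
    stop_fmt(paste0("infeasible usage constraints: parent slots (%d) fall short of ",
                    "the bucket minima (%d); binding bucket(s): %s"),
             slots, min_total,
             paste(sprintf("%d parents >= %g crosses", spec$n_parents, spec$min_crosses),
                   collapse = "; "))
  if (slots > max_total)
    stop_fmt(paste0("infeasible usage constraints: parent slots (%d) exceed the ",
                    "bucket maxima (%g); binding bucket(s): %s"),
             slots, max_total,
             paste(sprintf("%d parents <= %g crosses", spec$n_parents, cap),
                   collapse = "; "))
  local_seed(seed)

  parents <- paste0("P", seq_len(n_parents))
  bucket <- rep(seq_len(nrow(spec)), spec$n_parents)
  counts <- spec$min_crosses[bucket]
  capacity <- cap[bucket]
  extra <- slots - sum(counts)
  while (extra > 0) {
    open <- which(counts < capacity)
    if (!length(open)) stop_fmt("internal error: no capacity left while distributing slots")
    pick <- if (length(open) == 1) open else sample(open, 1)
    counts[pick] <- counts[pick] + 1
    extra <- extra - 1
  }

  # assemble crosses, largest-parent-count first; tri-parental crosses first
  # so three distinct high-count parents are always available
  sizes <- c(rep(3L, n_tri), rep(2L, n_bi))
  remaining <- counts
  rows <- vector("list", n_crosses)
  for (i in seq_len(n_crosses)) {
    k <- sizes[i]
    avail <- which(remaining > 0)
    if (length(avail) < k)
      stop_fmt("could not realize usage constraints: only %d parents with slots left for a %d-parent cross",
               length(avail), k)
    ord <- avail[order(remaining[avail] + stats::runif(length(avail)) * 0.5,
                       decreasing = TRUE)]
    chosen <- ord[seq_len(k)]
    remaining[chosen] <- remaining[chosen] - 1
    rows[[i]] <- chosen
  }
  if (any(remaining != 0))
    stop_fmt("could not realize usage constraints: %d parent slots unassigned", sum(remaining))

  crosses <- data.frame(
    cross = sprintf("C%02d", seq_len(n_crosses)),
    type = ifelse(sizes == 3L, "tri", "bi"),
    p1 = parents[vapply(rows, `[`, integer(1), 1)],
    p2 = parents[vapply(rows, `[`, integer(1), 2)],
    p3 = ifelse(sizes == 3L, parents[vapply(rows, function(r) if (length(r) >= 3) r[3] else NA_integer_, integer(1))], NA_character_),
    n_lines = as.integer(n_lines),
    stringsAsFactors = FALSE
  )
  d <- structure(list(parents = parents, crosses = crosses, spec = spec),
                 class = "cross_design")
  validate_cross_design(d)
  d
}

validate_cross_design <- function(d) {
  cr <- d$crosses
  for (i in seq_len(nrow(cr))) {
    ps <- stats::na.omit(unlist(cr[i, c("p1", "p2", "p3")]))
    if (length(ps) < 2 || length(ps) > 3 || anyDuplicated(ps))
      stop_fmt("cross %s must have 2 or 3 distinct parents", cr$cross[i])
  }
  u <- parent_usage(d)
  if (any(u == 0)) stop_fmt("parent(s) unused: %s", paste(names(u)[u == 0], collapse = ", "))
  spec <- d$spec
  # with disjoint bucket ranges the classification of counts is unique
  ranges_disjoint <- all(vapply(seq_len(nrow(spec)), function(i) {
    all(vapply(seq_len(nrow(spec))[-i], function(j) {
      spec$max_crosses[i] < spec$min_crosses[j] || spec$max_crosses[j] < spec$min_crosses[i]
    }, logical(1)))
  }, logical(1)))
  if (ranges_disjoint) {
    for (i in seq_len(nrow(spec))) {
      got <- sum(u >= spec$min_crosses[i] & u <= spec$max_crosses[i])
      if (got != spec$n_parents[i])
        stop_fmt("bucket %d (%g-%g crosses) realized by %d parents, expected %d",
                 i, spec$min_crosses[i], spec$max_crosses[i], got, spec$n_parents[i])
    }
  }
  invisible(d)
}

#' Parent usage counts of a crossing design
#' @param design a `cross_design`.
#' @return named integer vector: number of crosses each parent appears in.
#' @export
parent_usage <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  ps <- unlist(design$crosses[, c("p1", "p2", "p3")])
  tab <- table(factor(ps[!is.na(ps)], levels = design$parents))
  stats::setNames(as.integer(tab), design$parents)
}

#' Parents of one cross
#' @param design a `cross_design`.
#' @param cross cross id.
#' @return character vector of 2 or 3 parent ids.
#' @export
cross_parents <- function(design, cross) {
  i <- match(cross, design$crosses$cross)
  if (is.na(i)) stop_fmt("unknown cross id: %s", cross)
  as.character(stats::na.omit(unlist(design$crosses[i, c("p1", "p2", "p3")])))
}

#' Map line ids to their cross of origin
#'
#' Line ids follow the `<cross>_<number>` convention used by
#' [simulate_population()].
#'
#' @param design a `cross_design`.
#' @return named character vector (names = line ids, values = cross ids).
#' @export
line_cross_map <- function(design) {
  cr <- design$crosses
  ids <- unlist(lapply(seq_len(nrow(cr)), function(i)
    paste0(cr$cross[i], "_", seq_len(cr$n_lines[i]))))
  stats::setNames(rep(cr$cross, cr$n_lines), ids)
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("cross_design: %d parents, %d crosses (%d bi, %d tri), %d lines\n",
              length(x$parents), nrow(x$crosses),
              sum(x$crosses$type == "bi"), sum(x$crosses$type == "tri"),
              sum(x$crosses$n_lines)))
  invisible(x)
}
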