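#' Genetic map
#'
#' A genetic map is a table of markers with chromosome assignment and genetic
#' position in centimorgans.  Positions must be strictly increasing within a
#' chromosome and non-negative.  The map drives the recombination model used
#' by [simulate_cross()]: crossover counts per chromosome are Poisson with
#' mean equal to the chromosome length in Morgans and crossover positions are
#' uniform (Haldane model, no interference).
#'
#' @param chr chromosome id per marker (character or integer).
#' @param pos_cM genetic position per marker, centimorgans.
#' @param marker optional marker ids; defaults to `M1..Mm`.
#' @return an object of class `genetic_map`: a data.frame with columns
#'   `marker`, `chr`, `pos_cM`.
#' @examples
#' gm <- genetic_map(chr = c(1, 1, 2), pos_cM = c(0, 50, 10))
#' @export
genetic_map <- function(chr, pos_cM, marker = NULL) {
  stopifnot(length(chr) == length(pos_cM))
  if (length(chr) == 0) stop_fmt("genetic map must contain at least one marker")
  if (any(pos_cM < 0)) stop_fmt("marker positions must be >= 0")
  marker <- marker %||% paste0("M", seq_along(chr))
  m <- data.frame(marker = as.character(marker), chr = as.character(chr),
                  pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  # preserve chromosome blocks in given order, sort positions within
  m <- m[order(match(m$chr, unique(m$chr)), m$pos_cM), , drop = FALSE]
  rownames(m) <- NULL
  bad <- unlist(lapply(split(m$pos_cM, m$chr), function(p) any(diff(p) <= 0)))
  if (any(bad)) {
    stop_fmt("marker positions must be strictly increasing within chromosome (%s)",
             paste(names(bad)[bad], collapse = ", "))
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Simulate a genetic map
#'
#' Markers are spread as evenly as possible across `n_chr` chromosomes of
#' equal genetic length, with positions drawn uniformly and sorted.  Defaults
#' give a 2,000-marker map on 21 chromosomes, a desk-scale stand-in for a
#' high-density wheat array; the marker count is configurable up to array
#' scale.
#'
#' @param n_markers total number of markers.
#' @param n_chr number of chromosomes.
#' @param chr_length_cM genetic length of each chromosome, centimorgans.
#' @param seed optional integer seed.
#' @return a [genetic_map()].
#' @export
sim_genetic_map <- function(n_markers = 2000, n_chr = 21, chr_length_cM = 150,
                            seed = NULL) {
  stopifnot(n_markers >= 1, n_chr >= 1, chr_length_cM > 0)
  local_seed(seed)
  per <- diff(floor(seq(0, n_markers, length.out = n_chr + 1)))
  per <- per[per > 0]
  chr <- rep(paste0("chr", seq_along(per)), per)
  pos <- unlist(lapply(per, function(k) {
    p <- sort(stats::runif(k, 0, chr_length_cM))
    while (anyDuplicated(p)) p <- sort(stats::runif(k, 0, chr_length_cM))
    p
  }))
  genetic_map(chr, pos)
}

# Precompute per-chromosome quantities used by the gamete sampler.
map_geometry <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  chr_f <- factor(map$chr, levels = unique(map$chr))
  lo <- tapply(map$pos_cM, chr_f, min)
  hi <- tapply(map$pos_cM, chr_f, max)
  span <- pmax(hi - lo, 0)
  # global coordinate: chromosome blocks separated by gaps so breakpoints
  # from different chromosomes never interleave
  offset <- c(0, cumsum(span + 1))[seq_along(span)] - lo
  list(
    n_chr = nlevels(chr_f),
    chr_idx = as.integer(chr_f),
    pos_global = map$pos_cM + offset[as.integer(chr_f)],
    lo_global = lo + offset,
    span = as.numeric(span),
    len_morgan = as.numeric(span) / 100
  )
}
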