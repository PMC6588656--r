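# CSV readers/writers for the standard tabular artifacts.

#' Write / read a dosage matrix as CSV
#'
#' Layout: first column `id`, one column per marker, values 0-2 dosages.
#'
#' @param geno dosage matrix (lines x markers).
#' @param path file path.
#' @return `read_dosage_csv` returns the dosage matrix (line ids as row
#'   names).
#' @export
write_dosage_csv <- function(geno, path) {
  dt <- data.table::data.table(id = rownames(geno))
  dt <- cbind(dt, data.table::as.data.table(geno))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_dosage_csv
#' @export
read_dosage_csv <- function(path) {
  dt <- data.table::fread(path)
  ids <- dt$id
  m <- as.matrix(dt[, -1])
  rownames(m) <- ids
  if (any(m < 0 | m > 2, na.rm = TRUE)) stop_fmt("dosages outside [0, 2] in %s", path)
  m
}

#' Write a genetic map as CSV (marker, chr, pos_cM)
#' @param map a [genetic_map()].
#' @param path file path.
#' @export
write_map_csv <- function(map, path) {
  data.table::fwrite(as.data.frame(map), path)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  m <- data.table::fread(path)
  genetic_map(m$chr, m$pos_cM, m$marker)
}

#' Write a plot table as CSV
#' @param plots a `plot_table`.
#' @param path file path.
#' @export
write_plots_csv <- function(plots, path) {
  data.table::fwrite(as.data.frame(plots), path)
  invisible(path)
}

#' @rdname write_plots_csv
#' @export
read_plots_csv <- function(path) {
  pt <- as.data.frame(data.table::fread(path))
  class(pt) <- c("plot_table", "data.frame")
  pt
}

#' Write a relationship matrix as dense CSV and sparse three-column text
#'
#' @param G a `grmatrix`.
#' @param path dense CSV path (first column `id`).
#' @param sparse_path optional path for the lower-triangle `id1 id2 value`
#'   layout.
#' @export
write_grm_csv <- function(G, path, sparse_path = NULL) {
  m <- unclass(G)
  dt <- data.table::data.table(id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path)
  if (!is.null(sparse_path)) {
    idx <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
    data.table::fwrite(data.table::data.table(
      id1 = rownames(m)[idx[, 1]], id2 = colnames(m)[idx[, 2]],
      value = m[idx]), sparse_path, sep = "\t")
  }
  invisible(path)
}
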