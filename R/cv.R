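# Resampling designs and accuracy metrics for training-set studies.

#' Construct a training/validation design
#'
#' @param label design family label.
#' @param rep replicate index.
#' @param train,validation character vectors of line ids (disjoint,
#'   validation non-empty).
#' @param ... further descriptors stored with the design (e.g. fraction,
#'   n_crosses, n_lines, set_type, quarters_in_training).
#' @return object of class `training_design`.
#' @export
training_design <- function(label, rep, train, validation, ...) {
  if (!length(validation)) stop_fmt("validation set must be non-empty")
  if (length(intersect(train, validation)))
    stop_fmt("training and validation sets overlap (%d lines)",
             length(intersect(train, validation)))
  structure(list(label = label, rep = rep, train = train,
                 validation = validation, descriptors = list(...)),
            class = "training_design")
}

#' @export
print.training_design <- function(x, ...) {
  cat(sprintf("training_design [%s, rep %s]: %d training, %d validation lines\n",
              x$label, x$rep, length(x$train), length(x$validation)))
  invisible(x)
}

.all_lines <- function(design) names(line_cross_map(design))

#' Tenfold cross-validation with whole crosses as folds
#'
#' Crosses are randomly partitioned into `k` folds; each fold's crosses form
#' a validation set with all their lines, so the line means of a cross are
#' confined entirely to either the training or the validation set.  Folds
#' are re-sampled in every replicate.
#'
#' @param design a `cross_design`.
#' @param k number of folds (default 10).
#' @param reps number of replicates (default 10).
#' @param seed optional integer seed.
#' @return list of [training_design()] objects.
#' @export
tenfold_by_cross <- function(design, k = 10, reps = 10, seed = NULL) {
  crosses <- design$crosses$cross
  if (k > length(crosses)) stop_fmt("k = %d exceeds the %d crosses", k, length(crosses))
  local_seed(seed)
  cmap <- line_cross_map(design)
  out <- list()
  for (r in seq_len(reps)) {
    # fold sizes as equal as possible, membership random
    fold_of <- rep_len(seq_len(k), length(crosses))[sample(length(crosses))]
    names(fold_of) <- crosses
    for (f in seq_len(k)) {
      val_cr <- crosses[fold_of == f]
      val <- names(cmap)[cmap %in% val_cr]
      out[[length(out) + 1]] <- training_design(
        "tenfold_crosses", r, setdiff(names(cmap), val), val,
        fold = f, validation_crosses = val_cr)
    }
  }
  out
}

#' Tenfold cross-validation over individual lines
#'
#' Lines (not crosses) are partitioned into `k` folds, so crosses are split
#' between training and validation sets.
#'
#' @inheritParams tenfold_by_cross
#' @return list of [training_design()] objects.
#' @export
tenfold_random <- function(design, k = 10, reps = 10, seed = NULL) {
  lines <- .all_lines(design)
  if (k > length(lines)) stop_fmt("k = %d exceeds the %d lines", k, length(lines))
  local_seed(seed)
  out <- list()
  for (r in seq_len(reps)) {
    fold_of <- rep_len(seq_len(k), length(lines))[sample(length(lines))]
    for (f in seq_len(k)) {
      val <- lines[fold_of == f]
      out[[length(out) + 1]] <- training_design(
        "tenfold_random", r, setdiff(lines, val), val, fold = f)
    }
  }
  out
}

#' Leave-one-cross-out cross-validation
#'
#' One design per cross: that cross's lines are the validation set, all
#' other lines the training set.
#'
#' @param design a `cross_design` with at least 2 crosses.
#' @return list of [training_design()] objects.
#' @export
leave_one_cross_out <- function(design) {
  crosses <- design$crosses$cross
  if (length(crosses) < 2) stop_fmt("need at least 2 crosses")
  cmap <- line_cross_map(design)
  lapply(crosses, function(cr) {
    val <- names(cmap)[cmap == cr]
    training_design("loco", 1L, setdiff(names(cmap), val), val,
                    validation_crosses = cr)
  })
}

#' Randomly mask a fraction of the training records
#'
#' For each fraction and repetition, removes that fraction of the training
#' lines uniformly at random (count rounded to the nearest integer); the
#' validation set is untouched.
#'
#' @param base a [training_design()].
#' @param fractions fractions in (0, 1) to remove.
#' @param reps repetitions per fraction (default 10).
#' @param seed optional integer seed.
#' @return list of [training_design()] objects with descriptors `fraction`
#'   (removed) and `n_train`.
#' @export
mask_training_fraction <- function(base, fractions, reps = 10, seed = NULL) {
  stopifnot(inherits(base, "training_design"))
  if (!length(base$train)) stop_fmt("base design has an empty training set")
  if (any(fractions <= 0 | fractions >= 1))
    stop_fmt("fractions must lie strictly inside (0, 1)")
  local_seed(seed)
  out <- list()
  for (f in fractions) {
    n_rm <- round(f * length(base$train))
    for (r in seq_len(reps)) {
      keep <- if (n_rm > 0) sample(base$train, length(base$train) - n_rm)
              else base$train
      out[[length(out) + 1]] <- training_design(
        paste0(base$label, "+mask"), r, keep, base$validation,
        fraction = f, n_train = length(keep),
        validation_crosses = base$descriptors$validation_crosses)
    }
  }
  out
}

#' Training sets on a crosses-by-lines grid
#'
#' For each validation cross, grid cell `(n_crosses, n_lines)` and
#' repetition, the training set is `n_lines` random lines from each of
#' `n_crosses` randomly sampled other crosses.  Infeasible cells (more
#' crosses or lines requested than available) are skipped with a message.
#'
#' @param design a `cross_design`.
#' @param n_crosses_list,n_lines_list grid margins.
#' @param validation_crosses crosses to validate on (default: all).
#' @param reps repetitions per cell (default 10).
#' @param seed optional integer seed.
#' @return list of [training_design()] objects with descriptors
#'   `n_crosses`, `n_lines`, `validation_crosses`.
#' @export
crosses_by_lines_grid <- function(design, n_crosses_list = c(1:10, 15, 20, 30, 40),
                                  n_lines_list = c(seq(10, 60, 10), 65),
                                  validation_crosses = NULL, reps = 10,
                                  seed = NULL) {
  local_seed(seed)
  cmap <- line_cross_map(design)
  crosses <- design$crosses$cross
  validation_crosses <- validation_crosses %||% crosses
  by_cross <- split(names(cmap), cmap)
  out <- list()
  for (vc in validation_crosses) {
    others <- setdiff(crosses, vc)
    for (ncr in n_crosses_list) {
      if (ncr > length(others)) {
        message(sprintf("grid cell skipped: %d crosses requested, %d available (validation %s)",
                        ncr, length(others), vc))
        next
      }
      for (nl in n_lines_list) {
        if (nl > min(lengths(by_cross[others]))) {
          message(sprintf("grid cell skipped: %d lines requested per cross (validation %s)",
                          nl, vc))
          next
        }
        for (r in seq_len(reps)) {
          tr_cr <- sample(others, ncr)
          train <- unlist(lapply(by_cross[tr_cr], sample, size = nl),
                          use.names = FALSE)
          out[[length(out) + 1]] <- training_design(
            "grid", r, train, by_cross[[vc]],
            n_crosses = ncr, n_lines = nl, validation_crosses = vc)
        }
      }
    }
  }
  out
}

#' Classify crosses as related or unrelated to a validation cross
#'
#' A cross is `related` when it shares at least one pedigree parent with the
#' validation cross and `unrelated` otherwise.  The validation cross itself
#' is excluded.
#'
#' @param design a `cross_design`.
#' @param validation_cross cross id.
#' @return named character vector over the other crosses, values
#'   `"related"` / `"unrelated"`.
#' @export
classify_relatedness <- function(design, validation_cross) {
  vp <- cross_parents(design, validation_cross)
  others <- setdiff(design$crosses$cross, validation_cross)
  out <- vapply(others, function(cr) {
    if (length(intersect(cross_parents(design, cr), vp))) "related" else "unrelated"
  }, "")
  out
}

#' Fixed random quarter partition of every cross
#'
#' Splits each cross's lines into 4 quarters, frozen for a given seed, so
#' quarter-cycling designs are exhaustive and reproducible.
#'
#' @param design a `cross_design`.
#' @param seed integer seed freezing the partition.
#' @return named list (by cross) of length-4 lists of line-id vectors.
#' @export
quarter_partition <- function(design, seed = NULL) {
  local_seed(seed)
  cmap <- line_cross_map(design)
  lapply(split(names(cmap), cmap), function(ids) {
    ids <- sample(ids)
    split(ids, rep_len(1:4, length(ids)))
  })
}

#' Relatedness-stratified training designs with partial validation-cross
#' inclusion
#'
#' Builds training sets from crosses of a chosen relatedness structure to
#' the validation cross, optionally adding 0-3 quarters of the validation
#' cross itself; accuracy is always evaluated on a held-out quarter, cycling
#' through all four.
#'
#' Set types: `"one-parent"` -- crosses sharing one specific parent;
#' `"both-parents"` -- an equal number of crosses related through each
#' validation parent; `"unrelated"` -- crosses sharing no parent;
#' `"mixed"` -- equal numbers of related and unrelated crosses.
#'
#' @param design a `cross_design`.
#' @param validation_cross cross id.
#' @param set_type one of `"one-parent"`, `"both-parents"`, `"unrelated"`,
#'   `"mixed"`.
#' @param sizes numbers of training crosses to use (default: 2 and 4).
#' @param n_combinations cross combinations sampled per size (default 5).
#' @param quarters_in_training how many validation-cross quarters join the
#'   training set, subset of `0:3`.
#' @param reps replicates (each re-samples a combination; default 10).
#' @param seed master seed; also freezes the quarter partition.
#' @return list of [training_design()] objects (possibly empty if the
#'   pedigree cannot support the set type, with a message).
#' @export
relatedness_designs <- function(design, validation_cross,
                                set_type = c("one-parent", "both-parents",
                                             "unrelated", "mixed"),
                                sizes = c(2, 4), n_combinations = 5,
                                quarters_in_training = 0:3, reps = 10,
                                seed = NULL) {
  set_type <- match.arg(set_type)
  stopifnot(all(quarters_in_training %in% 0:3))
  rel <- classify_relatedness(design, validation_cross)
  vp <- cross_parents(design, validation_cross)
  cmap <- line_cross_map(design)
  by_cross <- split(names(cmap), cmap)
  quarters <- quarter_partition(design, seed = child_seed(seed, 999))[[validation_cross]]
  local_seed(seed)

  pick_combo <- function(size) {
    switch(set_type,
      "one-parent" = {
        par <- sample(vp, 1)
        pool <- names(rel)[vapply(names(rel), function(cr)
          par %in% cross_parents(design, cr), TRUE)]
        if (length(pool) < size) NULL else sample(pool, size)
      },
      "both-parents" = {
        per <- size %/% length(vp)
        if (per < 1) return(NULL)
        pools <- lapply(vp, function(par)
          names(rel)[vapply(names(rel), function(cr)
            par %in% cross_parents(design, cr), TRUE)])
        picked <- character(0)
        for (pool in pools) {
          pool <- setdiff(pool, picked)
          if (length(pool) < per) return(NULL)
          picked <- c(picked, sample(pool, per))
        }
        picked
      },
      "unrelated" = {
        pool <- names(rel)[rel == "unrelated"]
        if (length(pool) < size) NULL else sample(pool, size)
      },
      "mixed" = {
        half <- size %/% 2
        pr <- names(rel)[rel == "related"]
        pu <- names(rel)[rel == "unrelated"]
        if (half < 1 || length(pr) < half || length(pu) < size - half) NULL
        else c(sample(pr, half), sample(pu, size - half))
      })
  }

  out <- list()
  for (size in sizes) {
    combos <- list()
    for (i in seq_len(n_combinations)) {
      cmb <- pick_combo(size)
      if (!is.null(cmb)) combos[[length(combos) + 1]] <- cmb
    }
    if (!length(combos)) {
      message(sprintf("set type '%s' infeasible at size %d for validation cross %s: skipped",
                      set_type, size, validation_cross))
      next
    }
    for (r in seq_len(reps)) {
      cmb <- combos[[((r - 1) %% length(combos)) + 1]]
      base_train <- unlist(by_cross[cmb], use.names = FALSE)
      for (q in quarters_in_training) {
        eval_q <- ((r - 1) %% 4) + 1          # cycle the held-out quarter
        train_q <- if (q > 0) {
          qs <- setdiff(1:4, eval_q)[seq_len(q)]
          unlist(quarters[qs], use.names = FALSE)
        } else character(0)
        out[[length(out) + 1]] <- training_design(
          paste0("relatedness_", set_type), r,
          c(base_train, train_q), quarters[[eval_q]],
          set_type = set_type, n_crosses = size,
          quarters_in_training = q, eval_quarter = eval_q,
          validation_crosses = validation_cross)
      }
    }
  }
  out
}

#' Prediction accuracy
#'
#' Pearson correlation between validation BLUEs and their GBLUP predictions,
#' either within each validation cross (`by-cross`) or pooled over all
#' validation lines (`across-all`).
#'
#' @param blues named numeric vector of BLUEs for the validation lines (or a
#'   `blue_table`).
#' @param preds a [predict_lines()] result (or named numeric vector).
#' @param grouping `"by-cross"` or `"across-all"`.
#' @param cross_map named character vector mapping line ids to crosses
#'   (required for `"by-cross"`); see [line_cross_map()].
#' @param min_n minimum validation lines per reported correlation
#'   (default 3).
#' @return for `"across-all"` a single correlation; for `"by-cross"` a
#'   data.frame with `cross`, `n`, `r`.  Zero-variance groups give NA.
#' @export
accuracy <- function(blues, preds, grouping = c("by-cross", "across-all"),
                     cross_map = NULL, min_n = 3) {
  grouping <- match.arg(grouping)
  b <- .as_named_values(blues, "blue")
  p <- .as_named_values(preds, "ghat")
  ids <- names(b)
  if (!all(ids %in% names(p)))
    stop_fmt("predictions missing for %d validation line(s)",
             sum(!ids %in% names(p)))
  p <- p[ids]
  safe_cor <- function(x, y) {
    if (length(x) < min_n || stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }
  if (grouping == "across-all") return(safe_cor(b, p))
  if (is.null(cross_map)) stop_fmt("by-cross accuracy needs a cross_map")
  gs <- split(ids, cross_map[ids])
  data.frame(cross = names(gs),
             n = lengths(gs),
             r = vapply(gs, function(i) safe_cor(b[i], p[i]), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

.as_named_values <- function(x, col) {
  if (is.numeric(x)) {
    if (is.null(names(x))) stop_fmt("values must be named by line id")
    return(x)
  }
  if (is.data.frame(x) && all(c("id", col) %in% names(x)))
    return(stats::setNames(x[[col]], x$id))
  stop_fmt("cannot interpret input as named values or a table with 'id'/'%s'", col)
}

#' One-sided Wald test of a correlation against zero
#'
#' Tests H0: rho = 0 against rho > 0 with the statistic
#' \eqn{r \sqrt{(n-2)/(1-r^2)}} on a t reference with `n - 2` degrees of
#' freedom.
#'
#' @param r correlation(s).
#' @param n number(s) of validation lines (>= 4).
#' @return one-sided p-value(s); `|r| = 1` gives p = 0 (or 1).
#' @export
wald_significance <- function(r, n) {
  stopifnot(all(n >= 4), all(abs(r) <= 1))
  p <- ifelse(abs(r) >= 1, ifelse(r > 0, 0, 1),
              stats::pt(r * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                        lower.tail = FALSE))
  as.numeric(p)
}

#' Paired t test on accuracy increments
#'
#' Two-sided paired t test comparing replicate-level mean accuracies of two
#' training-set configurations (e.g. lines-per-cross L vs L + 10).
#' Identical pairs (zero differences throughout) return p = 1; zero variance
#' around a non-zero mean difference returns p = 0 with a note.
#'
#' @param x,y paired accuracy vectors (same replicates, same order).
#' @return list with `statistic`, `p_value`, `mean_diff`, `n`.
#' @export
increment_ttest <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop_fmt("need at least 3 paired replicates")
  d <- y - x
  if (stats::sd(d) == 0) {
    return(list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p_value = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), n = length(d),
                note = "zero variance of differences"))
  }
  tt <- stats::t.test(y, x, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(d), n = length(d))
}

#' Accuracy restricted to the top-performing lines of each cross
#'
#' Selects the `k` lines with the highest BLUE within each validation cross
#' and computes the Pearson correlation on that subset, quantifying the
#' range-restriction attenuation a breeder faces when only the best lines
#' matter.
#'
#' @inheritParams accuracy
#' @param k lines retained per cross (default 15).
#' @return data.frame with `cross`, `n`, `r`.
#' @export
top_fraction_accuracy <- function(blues, preds, cross_map, k = 15) {
  b <- .as_named_values(blues, "blue")
  p <- .as_named_values(preds, "ghat")
  gs <- split(names(b), cross_map[names(b)])
  bad <- names(gs)[lengths(gs) < k]
  if (length(bad))
    stop_fmt("cross(es) with fewer than k = %d lines: %s", k,
             paste(bad, collapse = ", "))
  rows <- lapply(names(gs), function(cr) {
    ids <- gs[[cr]]
    top <- ids[order(b[ids], decreasing = TRUE)][seq_len(k)]
    r <- if (stats::sd(b[top]) == 0 || stats::sd(p[top]) == 0) NA_real_
         else stats::cor(b[top], p[top])
    data.frame(cross = cr, n = k, r = r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run GBLUP over a stream of training designs
#'
#' For each design: re-estimates variance components on the training BLUEs
#' (the model is refit for every training set), predicts all lines, and
#' records per-validation-cross and pooled accuracies.
#'
#' @param designs list of [training_design()] objects.
#' @param blues named numeric vector of BLUEs (or a `blue_table`) covering
#'   all lines involved.
#' @param G relationship matrix over all lines.
#' @param cross_map named character vector mapping line ids to crosses.
#' @param min_train skip designs with fewer training lines (default 3).
#' @return data.frame of class `cv_result`: one row per design x validation
#'   cross plus one `(all)` row per design with the pooled correlation;
#'   descriptor columns are carried along.
#' @export
run_designs <- function(designs, blues, G, cross_map, min_train = 3) {
  b <- .as_named_values(blues, "blue")
  rows <- list()
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    tr <- intersect(d$train, names(b))
    va <- intersect(d$validation, names(b))
    if (length(tr) < min_train || !length(va)) next
    y <- b[tr]
    vc <- suppressWarnings(fit_aireml(y, G))
    pr <- predict_lines(vc, y, G)
    pv <- stats::setNames(pr$ghat, pr$id)[va]
    acc <- accuracy(b[va], pv, "by-cross", cross_map)
    pooled <- accuracy(b[va], pv, "across-all")
    desc <- d$descriptors
    desc$validation_crosses <- NULL
    base <- data.frame(label = d$label, rep = d$rep, n_train = length(tr),
                       sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e,
                       stringsAsFactors = FALSE)
    for (nm in names(desc)) base[[nm]] <- desc[[nm]]
    per <- cbind(base[rep(1, nrow(acc)), , drop = FALSE], acc)
    all_row <- cbind(base, data.frame(cross = "(all)", n = length(va), r = pooled))
    rows[[length(rows) + 1]] <- per
    rows[[length(rows) + 1]] <- all_row
  }
  if (!length(rows)) return(NULL)
  out <- data.table::rbindlist(rows, fill = TRUE)
  out <- as.data.frame(out)
  class(out) <- c("cv_result", "data.frame")
  out
}
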