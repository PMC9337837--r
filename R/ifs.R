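#' Subset-size grid for incremental feature selection
#'
#' Sizes are `step, 2*step, ...` up to the largest multiple of `step`
#' not exceeding `max_size`, with `max_size` appended when it is not
#' itself a multiple. Under the default step of 10, grid point `i`
#' contains the first `10 * i` ranked features.
#'
#' @param n_features number of ranked features available.
#' @param step grid step (default 10).
#' @param max_size largest subset size (default all features).
#' @return strictly increasing integer vector.
#' @export
build_subset_grid <- function(n_features, step = 10, max_size = n_features) {
  if (step < 1) stop("step must be >= 1")
  if (max_size > n_features)
    stop("max_size (", max_size, ") exceeds n_features (", n_features, ")")
  if (step > max_size)
    stop("step (", step, ") exceeds max_size (", max_size, ")")
  sizes <- seq.int(step, max_size, by = step)
  if (sizes[length(sizes)] != max_size) sizes <- c(sizes, max_size)
  as.integer(sizes)
}

# Minimal IFS-result container from a bare curve (used when only sizes
# and MCC values are available, e.g. externally tabulated curves).
#' Construct an IFS result from a bare curve
#'
#' @param size,mcc,acc aligned vectors; `acc` optional.
#' @return a `cin_ifs` with `curve` only (no per-size reports).
#' @export
ifs_curve <- function(size, mcc, acc = NA_real_) {
  stopifnot(length(size) == length(mcc))
  if (is.unsorted(size, strictly = TRUE))
    stop("sizes must be strictly increasing")
  structure(list(grid = as.integer(size),
                 curve = data.frame(size = as.integer(size),
                                    acc = acc, mcc = mcc),
                 reports = NULL, learner = "external", genes = NULL),
            class = "cin_ifs")
}

#' Incremental feature selection over a ranked list
#'
#' For each subset size `s` in the grid, restricts the expression matrix
#' to the first `s` ranked genes, cross-validates the learner, and
#' records the evaluation report; the sequence of MCC values is the IFS
#' curve. Per-size CV seeds are derived from the base seed and the size
#' (not the execution order), so results do not depend on evaluation
#' order.
#'
#' @param ranked a `cin_ranking` from [mrmr_rank()] or a character
#'   vector of gene ids in rank order.
#' @param x cells x genes matrix (superset of the ranked genes).
#' @param y class label per cell.
#' @param learner a learner from [make_learner()].
#' @param grid strictly increasing subset sizes; default
#'   [build_subset_grid()] over all ranked genes.
#' @param folds CV folds (default 10).
#' @param seed base seed.
#' @return a list of class `cin_ifs` with `grid`, `curve` (data frame
#'   `size`, `acc`, `mcc`), `reports` (one `cin_eval` per size),
#'   `learner` and `genes`.
#' @export
run_ifs <- function(ranked, x, y, learner, grid = NULL, folds = 10,
                    seed = 1L) {
  genes <- if (inherits(ranked, "cin_ranking")) ranked$gene_id
           else as.character(ranked)
  grid <- grid %||% build_subset_grid(length(genes))
  grid <- as.integer(grid)
  if (anyDuplicated(grid) || is.unsorted(grid, strictly = TRUE))
    stop("grid sizes must be strictly increasing and unique")
  if (max(grid) > length(genes))
    stop("grid extends past the ranked list (", length(genes), " genes)")
  missing <- setdiff(genes[seq_len(max(grid))], colnames(x))
  if (length(missing))
    stop("ranked gene(s) absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  reports <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    s <- grid[i]
    xs <- x[, genes[seq_len(s)], drop = FALSE]
    reports[[i]] <- cross_validate(xs, y, learner, folds = folds,
                                   seed = derive_seed(seed, s))
    message(sprintf("IFS size %5d: ACC = %.4f, MCC = %.4f", s,
                    reports[[i]]$acc, reports[[i]]$mcc))
  }
  curve <- data.frame(size = grid,
                      acc = vapply(reports, `[[`, numeric(1), "acc"),
                      mcc = vapply(reports, `[[`, numeric(1), "mcc"))
  structure(list(grid = grid, curve = curve, reports = reports,
                 learner = learner$label %||% "learner", genes = genes),
            class = "cin_ifs")
}

#' Select the optimal subset size from an IFS result
#'
#' The grid point with maximal MCC; ties resolve to the smallest size.
#'
#' @param result a `cin_ifs`.
#' @return a list of class `cin_selection` with `size`, `report` (if
#'   available), `mode` and the achieved `mcc`.
#' @export
select_optimal <- function(result) {
  stopifnot(inherits(result, "cin_ifs"), nrow(result$curve) > 0)
  i <- which.max(result$curve$mcc)     # first max = smallest size
  structure(list(size = result$curve$size[i],
                 mcc = result$curve$mcc[i],
                 report = if (!is.null(result$reports)) result$reports[[i]],
                 mode = "optimal", delta = NA_real_),
            class = "cin_selection")
}

#' Select a compact, near-optimal subset size
#'
#' The smallest grid size whose MCC is within `delta` of the curve
#' maximum. This formalizes the usual visual "knee" compaction of an IFS
#' curve; with the default `delta = 0.015`, a curve whose maximum
#' exceeds an earlier plateau by at most 0.015 selects the plateau.
#'
#' @param result a `cin_ifs`.
#' @param delta nonnegative MCC tolerance (default 0.015).
#' @return a `cin_selection` with `mode = "compact"`.
#' @export
select_compact <- function(result, delta = 0.015) {
  stopifnot(inherits(result, "cin_ifs"), nrow(result$curve) > 0)
  if (delta < 0) stop("delta must be nonnegative")
  thresh <- max(result$curve$mcc) - delta
  i <- which(result$curve$mcc >= thresh)[1]
  structure(list(size = result$curve$size[i],
                 mcc = result$curve$mcc[i],
                 report = if (!is.null(result$reports)) result$reports[[i]],
                 mode = "compact", delta = delta),
            class = "cin_selection")
}

#' @export
print.cin_selection <- function(x, ...) {
  cat(sprintf("%s selection: %d features, MCC = %.4f", x$mode, x$size,
              x$mcc))
  if (!is.na(x$delta)) cat(sprintf(" (delta = %g)", x$delta))
  cat("\n")
  invisible(x)
}

#' Plot an IFS curve
#'
#' Writes a subset-size versus MCC line plot, optionally windowed on the
#' x axis and with markers at the chosen selections. The device is
#' inferred from the file extension (`.pdf` or `.png`).
#'
#' @param result a `cin_ifs`.
#' @param selections optional list of `cin_selection` objects to mark.
#' @param path output image path.
#' @param xlim optional x-range window; points outside are dropped.
#' @return `path`, invisibly.
#' @export
plot_ifs_curve <- function(result, selections = NULL, path,
                           xlim = NULL) {
  stopifnot(inherits(result, "cin_ifs"))
  curve <- result$curve
  if (!is.null(xlim))
    curve <- curve[curve$size >= xlim[1] & curve$size <= xlim[2], ,
                   drop = FALSE]
  if (nrow(curve) == 0) stop("no grid points inside the window")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = 7, height = 5),
         png = grDevices::png(path, width = 900, height = 640, res = 120),
         stop("unsupported image format: ", ext))
  on.exit(grDevices::dev.off())
  plot(curve$size, curve$mcc, type = "l", lwd = 2, col = "steelblue",
       xlab = "Number of features", ylab = "MCC",
       main = paste("IFS curve:", result$learner))
  if (is.null(selections) || inherits(selections, "cin_selection"))
    selections <- list(selections)
  for (sel in selections) {
    if (is.null(sel)) next
    if (!is.null(xlim) && (sel$size < xlim[1] || sel$size > xlim[2]))
      next
    points(sel$size, sel$mcc, pch = 19,
           col = if (sel$mode == "optimal") "firebrick" else "darkorange")
    graphics::text(sel$size, sel$mcc,
                   labels = sprintf("%s: %d", sel$mode, sel$size),
                   pos = 4, cex = 0.8)
  }
  invisible(path)
}
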