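#' Confusion matrix with a fixed class order
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes optional class order; defaults to the sorted union of
#'   both vectors.
#' @return integer matrix, true classes as rows, predicted as columns.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  classes <- classes %||% sort(unique(c(as.character(y_true),
                                        as.character(y_pred))))
  tt <- table(factor(y_true, levels = classes),
              factor(y_pred, levels = classes))
  m <- matrix(as.integer(tt), nrow = length(classes),
              dimnames = list(classes, classes))
  m
}

#' Overall accuracy from a confusion matrix
#'
#' The proportion of correctly predicted samples among all samples:
#' trace over total.
#'
#' @param confusion square counts matrix (true x predicted).
#' @return real in \[0, 1\].
#' @export
accuracy <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(as.matrix(confusion))) / total
}

#' Per-class individual accuracy (recall)
#'
#' For each class, the proportion of correctly predicted samples among
#' the samples truly in that class: diagonal entry over row sum. A class
#' with no true samples is reported as `NA` rather than 0.
#'
#' @param confusion square counts matrix (true x predicted).
#' @param class optional single class name; if omitted, all classes.
#' @return named numeric vector (or scalar when `class` is given).
#' @export
individual_accuracy <- function(confusion, class = NULL) {
  confusion <- as.matrix(confusion)
  rs <- rowSums(confusion)
  acc <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  names(acc) <- rownames(confusion)
  if (!is.null(class)) {
    if (!class %in% rownames(confusion)) stop("unknown class: ", class)
    return(acc[[class]])
  }
  acc
}

#' Covariance-form multiclass Matthews correlation coefficient
#'
#' Builds one-hot indicator matrices `X` (true classes) and `Y`
#' (predicted classes), defines `cov(A, B)` as the sum over columns of
#' per-column sample covariances, and returns
#' `cov(X, Y) / sqrt(cov(X, X) * cov(Y, Y))`. This correlation of
#' indicator matrices equals the multiclass R_K statistic computed from
#' confusion-matrix entries (the normalization constants cancel). When
#' either variance term is zero (e.g. a constant predictor) the value is
#' defined as 0 rather than NaN, which keeps feature-selection curves
#' well defined for degenerate subsets.
#'
#' @param y_true,y_pred equal-length label vectors (length >= 2); the
#'   class set is the union of both.
#' @return real in \[-1, 1\].
#' @export
mcc_multiclass <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  n <- length(y_true)
  if (n < 2) stop("need at least 2 samples")
  classes <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  K <- length(classes)
  X <- matrix(0, n, K)
  Y <- matrix(0, n, K)
  X[cbind(seq_len(n), match(as.character(y_true), classes))] <- 1
  Y[cbind(seq_len(n), match(as.character(y_pred), classes))] <- 1
  covsum <- function(A, B)
    sum(vapply(seq_len(K), function(k) stats::cov(A[, k], B[, k]),
               numeric(1)))
  sxy <- covsum(X, Y)
  sxx <- covsum(X, X)
  syy <- covsum(Y, Y)
  if (sxx <= 0 || syy <= 0) return(0)
  sxy / sqrt(sxx * syy)
}

# Build an evaluation report from aligned truth/prediction vectors.
eval_report <- function(y_true, y_pred, folds = NA_integer_,
                        seed = NA_integer_) {
  conf <- confusion_matrix(y_true, y_pred)
  structure(list(classes = rownames(conf),
                 confusion = conf,
                 acc = accuracy(conf),
                 mcc = mcc_multiclass(y_true, y_pred),
                 individual_accuracy = individual_accuracy(conf),
                 folds = folds,
                 seed = seed),
            class = "cin_eval")
}

#' @export
print.cin_eval <- function(x, ...) {
  cat(sprintf("Evaluation: ACC = %.4f, MCC = %.4f (%d samples",
              x$acc, x$mcc, sum(x$confusion)))
  if (!is.na(x$folds)) cat(sprintf(", %d-fold CV", x$folds))
  cat(")\n  per-class accuracy: ",
      paste(sprintf("%s %.3f", names(x$individual_accuracy),
                    x$individual_accuracy), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# Seeded fold assignment: shuffle (within class when stratified) and
# deal round-robin, so fold sizes differ by at most one per class.
make_folds <- function(y, folds, stratified, seed) {
  n <- length(y)
  if (folds < 2) stop("need at least 2 folds")
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        if (length(idx) < folds)
          stop("class '", cl, "' has fewer samples (", length(idx),
               ") than folds (", folds, ")")
        idx <- if (length(idx) > 1) sample(idx) else idx
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      if (n < folds) stop("fewer samples (", n, ") than folds (", folds, ")")
      fold[sample.int(n)] <- rep_len(seq_len(folds), n)
    }
  })
  fold
}

#' Cross-validated evaluation of a learner
#'
#' Partitions cells into folds (stratified by class by default), trains
#' the learner on all but one fold, predicts the held-out fold, and
#' aggregates every held-out prediction into a single evaluation report.
#' Deterministic given the seed.
#'
#' @param x cells x genes numeric matrix.
#' @param y class label per cell.
#' @param learner a learner from [make_learner()] (or any list with
#'   `fit(x, y)` and `predict(model, x)` functions).
#' @param folds number of folds (default 10).
#' @param stratified stratify folds by class (default `TRUE`); set
#'   `FALSE` e.g. for leave-one-out.
#' @param seed integer seed for the fold partition.
#' @return a `cin_eval` report: confusion matrix, `acc`, `mcc` and
#'   per-class `individual_accuracy`.
#' @export
cross_validate <- function(x, y, learner, folds = 10, stratified = TRUE,
                           seed = 1L) {
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  fold <- make_folds(y, folds, stratified, seed)
  pred <- character(length(y))
  for (f in seq_len(folds)) {
    te <- fold == f
    model <- learner$fit(x[!te, , drop = FALSE], y[!te])
    pred[te] <- learner$predict(model, x[te, , drop = FALSE])
  }
  eval_report(y, pred, folds = as.integer(folds), seed = as.integer(seed))
}

#' Repeated cross-validation
#'
#' Runs [cross_validate()] `times` times with independent fold
#' partitions (seeds `base_seed, base_seed + 1, ...`) and collects the
#' ACC/MCC distribution, plus min/median/max summaries for box-plot
#' style reporting of classifier stability.
#'
#' @inheritParams cross_validate
#' @param times number of repetitions (default 10).
#' @param base_seed seed of the first repetition.
#' @return a list of class `cin_repcv` with `results` (data frame:
#'   `repetition`, `seed`, `acc`, `mcc`) and `summary` (min/median/max
#'   for each metric).
#' @export
repeated_cv <- function(x, y, learner, folds = 10, times = 10,
                        base_seed = 1L) {
  seeds <- as.integer(base_seed) + seq_len(times) - 1L
  rows <- lapply(seq_len(times), function(i) {
    rep_i <- cross_validate(x, y, learner, folds = folds, seed = seeds[i])
    data.frame(repetition = i, seed = seeds[i],
               acc = rep_i$acc, mcc = rep_i$mcc)
  })
  results <- do.call(rbind, rows)
  summ <- lapply(results[c("acc", "mcc")], function(v)
    c(min = min(v), median = stats::median(v), max = max(v)))
  structure(list(results = results, summary = summ,
                 folds = folds, times = times,
                 base_seed = as.integer(base_seed)),
            class = "cin_repcv")
}

#' @export
print.cin_repcv <- function(x, ...) {
  cat(sprintf("Repeated CV: %d x %d-fold\n", x$times, x$folds))
  cat(sprintf("  ACC min/median/max: %.4f / %.4f / %.4f\n",
              x$summary$acc["min"], x$summary$acc["median"],
              x$summary$acc["max"]))
  cat(sprintf("  MCC min/median/max: %.4f / %.4f / %.4f\n",
              x$summary$mcc["min"], x$summary$mcc["median"],
              x$summary$mcc["max"]))
  invisible(x)
}
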