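#' Construct a learner satisfying the fit/predict contract
#'
#' Learners expose `fit(x, y) -> model` and `predict(model, x) ->
#' labels`. Three kinds are available:
#'
#' * `"tree_ensemble"` — a random forest of `n_trees` decision trees
#'   (default 100), each grown on a bootstrap sample with a random
#'   feature subset; predictions aggregate tree votes. Backed by
#'   \pkg{ranger}, run single-threaded with a fixed seed so
#'   predictions are deterministic.
#' * `"ripper"` — the decision-list inducer of [fit_ripper()].
#' * `"stub"` — predicts the modal training label; useful as a
#'   degenerate baseline in tests.
#'
#' @param kind learner family.
#' @param n_trees trees in the ensemble (tree_ensemble only).
#' @param seed integer seed for the ensemble's randomness.
#' @param grow_fraction,max_conditions RIPPER options, see
#'   [fit_ripper()].
#' @return a list of class `cin_learner` with elements `kind`, `label`,
#'   `params`, `fit` and `predict`.
#' @export
make_learner <- function(kind = c("tree_ensemble", "ripper", "stub"),
                         n_trees = 100L, seed = 1L,
                         grow_fraction = 2/3, max_conditions = 20L) {
  kind <- match.arg(kind)
  if (kind == "tree_ensemble") {
    if (n_trees < 1) stop("n_trees must be >= 1")
    fit <- function(x, y) {
      df <- as.data.frame(x)
      colnames(df) <- make.names(colnames(df), unique = TRUE)
      ranger::ranger(x = df, y = factor(y), num.trees = n_trees,
                     seed = seed, num.threads = 1)
    }
    pred <- function(model, x) {
      df <- as.data.frame(x)
      colnames(df) <- make.names(colnames(df), unique = TRUE)
      # seed also fixed at predict time: vote ties are broken randomly
      # and would otherwise depend on the session RNG state
      as.character(stats::predict(model, data = df, num.threads = 1,
                                  seed = seed)$predictions)
    }
    label <- sprintf("tree ensemble (%d trees)", n_trees)
    params <- list(n_trees = as.integer(n_trees), seed = as.integer(seed))
  } else if (kind == "ripper") {
    fit <- function(x, y)
      fit_ripper(x, y, grow_fraction = grow_fraction, seed = seed,
                 max_conditions = max_conditions)
    pred <- function(model, x) predict_ruleset(model, x)
    label <- "RIPPER decision list"
    params <- list(grow_fraction = grow_fraction, seed = as.integer(seed),
                   max_conditions = as.integer(max_conditions))
  } else {
    fit <- function(x, y) {
      tab <- table(y)
      names(tab)[which.max(tab)]
    }
    pred <- function(model, x) rep(model, nrow(x))
    label <- "majority-class stub"
    params <- list()
  }
  structure(list(kind = kind, label = label, params = params,
                 fit = fit, predict = pred),
            class = "cin_learner")
}
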