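#' FOIL information gain
#'
#' Gain of refining a rule whose positive/negative coverage is
#' `(p0, n0)` into one covering `(p1, n1)`:
#' `p1 * (log2(p1/(p1+n1)) - log2(p0/(p0+n0)))`. A refinement that
#' covers no positives (`p1 == 0`) gets `-Inf` so it is never selected.
#'
#' @param p0,n0 positive/negative coverage before the refinement
#'   (`p0 > 0`).
#' @param p1,n1 coverage after; may be vectors.
#' @return numeric vector of gains.
#' @export
foil_gain <- function(p0, n0, p1, n1) {
  if (any(p0 <= 0)) stop("p0 must be positive")
  g <- p1 * (log2(p1 / (p1 + n1)) - log2(p0 / (p0 + n0)))
  g[p1 == 0] <- -Inf
  g
}

# TRUE/FALSE mask of one condition over a cells x genes matrix.
# Gene lookup is case-insensitive. In lenient mode a condition on an
# absent gene fails (mask all-FALSE); strict mode raises an error.
cond_mask <- function(x, gene, op, threshold, strict = FALSE,
                      rule_index = NA) {
  j <- match(toupper(gene), toupper(colnames(x)))
  if (is.na(j)) {
    if (strict)
      stop("gene '", gene, "' (rule ", rule_index,
           ") not present in the data")
    return(rep(FALSE, nrow(x)))
  }
  if (op == "<=") x[, j] <= threshold else x[, j] >= threshold
}

rule_matches <- function(conditions, x, strict = FALSE, rule_index = NA) {
  m <- rep(TRUE, nrow(x))
  for (ci in seq_len(nrow(conditions))) {
    m <- m & cond_mask(x, conditions$gene[ci], conditions$op[ci],
                       conditions$threshold[ci], strict, rule_index)
    if (!any(m)) break
  }
  m
}

# Greedy rule growth on the grow set: repeatedly add the condition with
# maximal FOIL gain until no negatives are covered, the gain is no
# longer positive, or max_conditions is reached. Candidate thresholds
# are midpoints between consecutive distinct observed values of each
# feature; ties break toward the lowest feature index, then "<=" before
# ">=", then the smallest threshold.
grow_rule <- function(xg, posg, max_conditions) {
  covm <- rep(TRUE, nrow(xg))
  genes <- colnames(xg)
  conds <- data.frame(gene = character(0), op = character(0),
                      threshold = numeric(0), stringsAsFactors = FALSE)
  repeat {
    p0 <- sum(posg & covm)
    n0 <- sum(!posg & covm)
    if (n0 == 0 || p0 == 0 || nrow(conds) >= max_conditions) break
    best <- NULL
    best_gain <- 0          # require strictly positive gain
    for (j in seq_along(genes)) {
      v <- xg[covm, j]
      pv <- posg[covm]
      u <- sort(unique(v))
      nu <- length(u)
      if (nu < 2) next
      cum_pos <- cumsum(tabulate(findInterval(v[pv], u), nbins = nu))
      cum_neg <- cumsum(tabulate(findInterval(v[!pv], u), nbins = nu))
      thr <- (u[-nu] + u[-1]) / 2
      m <- nu - 1L
      P <- cum_pos[nu]
      N <- cum_neg[nu]
      gains <- c(foil_gain(p0, n0, cum_pos[1:m], cum_neg[1:m]),
                 foil_gain(p0, n0, P - cum_pos[1:m], N - cum_neg[1:m]))
      bi <- which.max(gains)
      if (gains[bi] > best_gain) {
        best_gain <- gains[bi]
        best <- if (bi <= m)
          list(gene = genes[j], op = "<=", threshold = thr[bi])
        else
          list(gene = genes[j], op = ">=", threshold = thr[bi - m])
      }
    }
    if (is.null(best)) break
    conds <- rbind(conds,
                   data.frame(gene = best$gene, op = best$op,
                              threshold = best$threshold,
                              stringsAsFactors = FALSE))
    covm <- covm & cond_mask(xg, best$gene, best$op, best$threshold)
  }
  rownames(conds) <- NULL
  conds
}

# Reduced-error pruning on the prune set: keep the prefix of conditions
# maximizing (p - n) / (p + n); a prefix covering nothing scores -1.
# Ties prefer the shorter rule (more pruning).
prune_rule <- function(conds, xp, posp) {
  k_max <- nrow(conds)
  if (nrow(xp) == 0 || k_max <= 1) return(conds)
  vals <- numeric(k_max)
  m <- rep(TRUE, nrow(xp))
  for (k in seq_len(k_max)) {
    m <- m & cond_mask(xp, conds$gene[k], conds$op[k], conds$threshold[k])
    p <- sum(m & posp)
    nn <- sum(m & !posp)
    vals[k] <- if (p + nn == 0) -1 else (p - nn) / (p + nn)
  }
  k <- which.max(vals)
  conds[seq_len(k), , drop = FALSE]
}

# Stratified grow/prune split of a pool (positives and negatives split
# separately); returns logical masks relative to the pool.
ripper_split <- function(posm, grow_fraction, seed) {
  grow <- logical(length(posm))
  withr::with_seed(seed, {
    for (is_pos in c(TRUE, FALSE)) {
      idx <- which(posm == is_pos)
      if (length(idx) == 0) next
      ng <- ceiling(grow_fraction * length(idx))
      take <- if (length(idx) == 1) idx else sample(idx)[seq_len(ng)]
      grow[take] <- TRUE
    }
  })
  list(grow = grow, prune = !grow)
}

#' Fit a RIPPER-style decision list
#'
#' Sequential-covering rule induction for multiclass continuous-feature
#' data. Classes are processed in increasing frequency order (ties by
#' first appearance in the labels); for each non-final class the
#' remaining training pool is repeatedly split (stratified) into a
#' growing set and a pruning set, one rule is grown by greedily adding
#' the condition with maximal FOIL gain until it covers no negatives on
#' the growing set, pruned by deleting trailing conditions to maximize
#' `(p - n)/(p + n)` on the pruning set, and accepted unless its
#' prune-set error exceeds 50% (which closes the class). Covered samples
#' are removed and the loop repeats until no positives remain. The most
#' frequent class becomes the default. Full MDL-based stopping and
#' post-optimization passes of canonical RIPPER are deliberately not
#' implemented; the simplified stop rule above is the documented
#' behavior.
#'
#' @param x cells x genes numeric matrix.
#' @param y class label per cell (>= 2 classes, each with >= 2 samples).
#' @param grow_fraction fraction of the pool used for growing
#'   (default 2/3).
#' @param seed integer seed controlling the grow/prune splits.
#' @param max_conditions cap on conditions per rule (default 20).
#' @return a `cin_ruleset`; attribute `training_accuracy` holds the
#'   resubstitution accuracy of the fitted list.
#' @export
fit_ripper <- function(x, y, grow_fraction = 2/3, seed = 1L,
                       max_conditions = 20L) {
  y <- as.character(y)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (grow_fraction <= 0 || grow_fraction >= 1)
    stop("grow_fraction must be in (0, 1)")
  tab <- table(y)
  if (length(tab) < 2) stop("RIPPER requires at least two classes")
  if (any(tab < 2)) stop("each class needs at least 2 samples")
  first_seen <- vapply(names(tab), function(cl) which(y == cl)[1], 0L)
  ord <- names(tab)[order(as.integer(tab), first_seen)]
  pool <- seq_len(nrow(x))
  rules <- list()
  split_counter <- 0L
  for (ci in ord[-length(ord)]) {
    repeat {
      posm <- y[pool] == ci
      if (!any(posm) || all(posm)) break
      split_counter <- split_counter + 1L
      sp <- ripper_split(posm, grow_fraction,
                         derive_seed(seed, split_counter))
      gi <- pool[sp$grow]
      pi <- pool[sp$prune]
      conds <- grow_rule(x[gi, , drop = FALSE], y[gi] == ci,
                         max_conditions)
      if (nrow(conds) == 0) break
      conds <- prune_rule(conds, x[pi, , drop = FALSE], y[pi] == ci)
      pm <- rule_matches(conds, x[pi, , drop = FALSE])
      p <- sum(pm & (y[pi] == ci))
      nn <- sum(pm & (y[pi] != ci))
      if ((p + nn) > 0 && nn / (p + nn) > 0.5) break
      rules[[length(rules) + 1L]] <- list(conditions = conds, class = ci)
      covered <- rule_matches(conds, x[pool, , drop = FALSE])
      pool <- pool[!covered]
      if (length(pool) == 0) break
    }
    pool <- pool[y[pool] != ci]
    if (length(pool) == 0) break
  }
  rs <- new_ruleset(rules, default_class = ord[length(ord)])
  attr(rs, "training_accuracy") <- mean(predict_ruleset(rs, x) == y)
  rs
}

#' Apply a decision list to samples
#'
#' First-match semantics: the first rule whose conditions all hold
#' assigns the label; samples matching no rule get the default class.
#' Gene lookup is case-insensitive. In lenient mode (default) a
#' condition on a gene absent from the data simply fails; in strict
#' mode it raises an error naming the gene and rule index. The ruleset
#' and input are never modified.
#'
#' @param ruleset a `cin_ruleset`.
#' @param x cells x genes numeric matrix with gene column names.
#' @param strict error on missing genes instead of failing the
#'   condition.
#' @return character vector of predicted labels, one per row.
#' @export
predict_ruleset <- function(ruleset, x, strict = FALSE) {
  stopifnot(inherits(ruleset, "cin_ruleset"), is.matrix(x))
  out <- rep(ruleset$default_class, nrow(x))
  open <- rep(TRUE, nrow(x))
  for (ri in seq_along(ruleset$rules)) {
    if (!any(open)) break
    r <- ruleset$rules[[ri]]
    m <- open
    for (ci in seq_len(nrow(r$conditions))) {
      m <- m & cond_mask(x, r$conditions$gene[ci], r$conditions$op[ci],
                         r$conditions$threshold[ci], strict, ri)
      if (!any(m)) break
    }
    out[m] <- r$class
    open[m] <- FALSE
  }
  out
}

#' @rdname predict_ruleset
#' @param sample a single named numeric vector (or single-row matrix)
#'   mapping gene ids to expression values.
#' @return `apply_ruleset`: a single predicted label.
#' @export
apply_ruleset <- function(ruleset, sample, strict = FALSE) {
  if (is.list(sample)) sample <- unlist(sample)
  if (is.null(dim(sample))) {
    stopifnot(!is.null(names(sample)))
    sample <- matrix(sample, nrow = 1,
                     dimnames = list(NULL, names(sample)))
  }
  stopifnot(nrow(sample) == 1)
  predict_ruleset(ruleset, sample, strict = strict)[1]
}

#' Structural statistics of a decision list
#'
#' @param ruleset a `cin_ruleset`.
#' @return list with `n_rules` (explicit rules, excluding the default),
#'   `rules_per_class` (named integer vector), `conditions_per_rule`
#'   (integer vector in rule order), `genes_used` (unique gene ids) and
#'   `default_class`.
#' @export
ruleset_stats <- function(ruleset) {
  stopifnot(inherits(ruleset, "cin_ruleset"))
  classes <- vapply(ruleset$rules, `[[`, character(1), "class")
  n_cond <- vapply(ruleset$rules, function(r) nrow(r$conditions), 0L)
  genes <- unique(unlist(lapply(ruleset$rules,
                                function(r) r$conditions$gene)))
  rpc <- if (length(classes)) table(classes) else table(character(0))
  list(n_rules = length(ruleset$rules),
       rules_per_class = stats::setNames(as.integer(rpc), names(rpc)),
       conditions_per_rule = as.integer(n_cond),
       genes_used = genes %||% character(0),
       default_class = ruleset$default_class)
}
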