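#' Plug-in mutual information between two discrete vectors
#'
#' Maximum-likelihood (plug-in) estimate on the empirical joint
#' distribution, in bits: `I(X;Y) = sum p(x,y) log2(p(x,y)/(p(x)p(y)))`.
#' No bias correction is applied. For numerical determinism the nonzero
#' terms are accumulated in ascending sorted order, so permuting the
#' contingency table's cells never changes the floating-point result.
#'
#' @param x,y equal-length vectors of discrete values (any type usable
#'   as a factor).
#' @return mutual information in bits; always in
#'   `[0, min(H(X), H(Y)) ]` up to floating error.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 1) stop("x and y must be non-empty")
  mi_from_counts(table(x, y))
}

# MI in bits from a contingency table, sorted-term accumulation.
mi_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  if (n == 0) return(0)
  r <- rowSums(counts)
  s <- colSums(counts)
  terms <- numeric(0)
  for (j in seq_along(s)) {
    for (i in seq_along(r)) {
      cij <- counts[i, j]
      if (cij > 0)
        terms <- c(terms, (cij / n) * log2(cij * n / (r[i] * s[j])))
    }
  }
  sum(sort(terms))
}

# MI (bits) of every column of a three-state matrix against one grouping
# vector. S: n x G integer matrix with values in {-1,0,1}; y: factor.
# Returns numeric G-vector, bitwise identical to mutual_information()
# applied per column (same terms, same sorted accumulation).
mi_columns <- function(S, y) {
  y <- as.factor(y)
  n <- nrow(S)
  K <- nlevels(y)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  ctot <- colSums(Y)
  states <- c(-1L, 0L, 1L)
  counts <- lapply(states, function(s) crossprod((S == s) + 0, Y)) # G x K
  rtot <- vapply(counts, rowSums, numeric(ncol(S)))                # G x 3
  if (ncol(S) == 1) rtot <- matrix(rtot, nrow = 1)
  G <- ncol(S)
  termM <- matrix(0, G, 3L * K)
  for (si in 1:3) {
    for (k in seq_len(K)) {
      cc <- counts[[si]][, k]
      tt <- numeric(G)
      pos <- cc > 0
      tt[pos] <- (cc[pos] / n) *
        log2(cc[pos] * n / (rtot[pos, si] * ctot[k]))
      termM[, (si - 1L) * K + k] <- tt
    }
  }
  # zero terms are additive identities; sorting only the nonzero terms
  # reproduces mi_from_counts() bit for bit
  vapply(seq_len(G), function(g) {
    v <- termM[g, ]
    sum(sort(v[v != 0]))
  }, numeric(1))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mRMR over a three-state discretized matrix. The first feature
#' maximizes mutual information with the class labels; each subsequent
#' feature `f` maximizes, over the unselected features, either
#' `I(f; c) - mean(I(f; s))` (MID, the difference form and default) or
#' `I(f; c) / max(mean(I(f; s)), floor)` (MIQ, the quotient form) where
#' the mean runs over the already-selected set. Ties at any argmax are
#' broken toward the lowest original gene index, so the ranking is
#' deterministic and `mrmr_rank(..., k)` is a prefix of
#' `mrmr_rank(..., k')` for `k < k'`.
#'
#' @param disc a `cin_disc` from [discretize_three_state()], or a plain
#'   integer states matrix in \{-1, 0, 1\}.
#' @param labels class label per cell (character or factor), aligned to
#'   the matrix rows.
#' @param k number of features to rank; default all.
#' @param scheme `"mid"` (difference) or `"miq"` (quotient).
#' @param redundancy_floor lower bound (bits) on the MIQ denominator to
#'   avoid division blow-up; ignored under MID.
#' @return a data frame of class `cin_ranking` with columns `rank`,
#'   `gene_id`, `relevance` (MI with labels, bits) and `score` (the
#'   criterion value at selection time).
#' @export
mrmr_rank <- function(disc, labels, k = NULL, scheme = c("mid", "miq"),
                      redundancy_floor = 0.001) {
  scheme <- match.arg(scheme)
  S <- if (inherits(disc, "cin_disc")) disc$states else disc
  stopifnot(is.matrix(S))
  y <- factor(as.character(labels))
  if (nrow(S) != length(y))
    stop("labels must have one entry per cell (matrix row)")
  G <- ncol(S)
  if (is.null(k)) k <- G
  if (k < 1 || k > G)
    stop("k must be between 1 and the number of genes (", G, ")")
  rel <- mi_columns(S, y)
  redsum <- numeric(G)
  avail <- rep(TRUE, G)
  sel <- integer(k)
  score_at <- numeric(k)
  for (r in seq_len(k)) {
    if (r == 1L) {
      score <- rel
    } else {
      redmean <- redsum / (r - 1)
      score <- if (scheme == "mid") rel - redmean
               else rel / pmax(redmean, redundancy_floor)
    }
    score[!avail] <- -Inf
    j <- which.max(score)            # first max = lowest gene index
    sel[r] <- j
    score_at[r] <- score[j]
    avail[j] <- FALSE
    if (r < k)
      redsum <- redsum + mi_columns(S, factor(S[, j], levels = c(-1, 0, 1)))
  }
  out <- data.frame(rank = seq_len(k),
                    gene_id = colnames(S)[sel] %||% as.character(sel),
                    relevance = rel[sel],
                    score = score_at,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme
  class(out) <- c("cin_ranking", "data.frame")
  out
}

#' Write a ranked feature list as TSV
#'
#' @param ranking a `cin_ranking` from [mrmr_rank()].
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
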