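# Independent oracles, written naively and separately from the package
# implementations they cross-check.

# Plug-in mutual information (bits) from the empirical contingency
# table, nested loops; nonzero terms accumulated in ascending order.
oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  r <- rowSums(tab)
  s <- colSums(tab)
  terms <- numeric(0)
  for (j in seq_along(s)) {
    for (i in seq_along(r)) {
      cij <- tab[i, j]
      if (cij > 0)
        terms <- c(terms, (cij / n) * log2(cij * n / (r[i] * s[j])))
    }
  }
  sum(sort(terms))
}

# Brute-force greedy mRMR over a states matrix; strict > comparison in
# original feature order reproduces the lowest-index tie-break.
oracle_mrmr <- function(S, y, k, scheme, floor = 0.001) {
  G <- ncol(S)
  rel <- vapply(seq_len(G), function(j) oracle_mi(S[, j], y), numeric(1))
  sel <- integer(0)
  scores <- numeric(0)
  for (r in seq_len(k)) {
    best <- -Inf
    bestj <- NA_integer_
    for (j in seq_len(G)) {
      if (j %in% sel) next
      if (length(sel) == 0) {
        sc <- rel[j]
      } else {
        red <- sum(vapply(sel, function(s2) oracle_mi(S[, j], S[, s2]),
                          numeric(1))) / length(sel)
        sc <- if (scheme == "mid") rel[j] - red else rel[j] / max(red, floor)
      }
      if (sc > best) {
        best <- sc
        bestj <- j
      }
    }
    sel <- c(sel, bestj)
    scores <- c(scores, best)
  }
  list(idx = sel, gene_id = colnames(S)[sel], score = scores,
       relevance = rel[sel])
}

# Closed-form multiclass R_K statistic from a confusion matrix
# (true rows x predicted columns).
oracle_rk <- function(C) {
  C <- as.matrix(C)
  n <- sum(C)
  t_k <- rowSums(C)
  p_k <- colSums(C)
  num <- n * sum(diag(C)) - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

# Classical binary MCC from a 2x2 confusion matrix.
oracle_binary_mcc <- function(tp, fn, fp, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# Exhaustive single-condition rule search: all (feature, midpoint,
# direction, class) combinations; returns the best training accuracy
# achievable by a one-rule decision list and one witness.
oracle_best_single_condition <- function(x, y) {
  classes <- unique(y)
  best <- list(acc = -Inf)
  for (j in seq_len(ncol(x))) {
    u <- sort(unique(x[, j]))
    if (length(u) < 2) next
    thr <- (u[-1] + u[-length(u)]) / 2
    for (t in thr) {
      for (op in c("<=", ">=")) {
        m <- if (op == "<=") x[, j] <= t else x[, j] >= t
        for (cl in classes) {
          for (def in setdiff(classes, cl)) {
            pred <- ifelse(m, cl, def)
            acc <- mean(pred == y)
            if (acc > best$acc)
              best <- list(acc = acc, feature = colnames(x)[j],
                           op = op, threshold = t, class = cl,
                           default = def)
          }
        }
      }
    }
  }
  best
}

# Random small discretized dataset for oracle-equivalence checks.
random_disc_dataset <- function(seed) {
  withr::with_seed(seed, {
    n <- 30L
    G <- sample(4:12, 1)
    K <- sample(2:3, 1)
    S <- matrix(sample(c(-1L, 0L, 1L), n * G, replace = TRUE), n, G,
                dimnames = list(NULL, paste0("f", seq_len(G))))
    y <- sample(LETTERS[seq_len(K)], n, replace = TRUE)
    # guarantee at least 2 classes realized
    y[1:2] <- LETTERS[1:2]
    list(S = S, y = y, G = G)
  })
}

# Random ruleset for serialization property tests.
random_ruleset <- function(seed) {
  withr::with_seed(seed, {
    pool <- c("NKX2-1", "LHX8", "FOXP2", "GM6180", "2610017I09RIK",
              "ACTB", "ZIC1", "MEIS2", "RPS29", "H3F3B")
    n_rules <- sample(0:6, 1)
    rules <- lapply(seq_len(n_rules), function(i) {
      nc <- sample(1:4, 1)
      conds <- data.frame(
        gene = sample(pool, nc, replace = TRUE),
        op = sample(c("<=", ">="), nc, replace = TRUE),
        threshold = round(stats::runif(nc, 0, 1000),
                          sample(0:4, nc, replace = TRUE)),
        stringsAsFactors = FALSE)
      list(conditions = conds, class = sample(c("CGE", "dMGE", "vMGE"), 1))
    })
    cinrules:::new_ruleset(rules, sample(c("CGE", "dMGE", "vMGE"), 1))
  })
}
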