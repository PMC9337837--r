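#' Configuration for the synthetic expression-matrix generator
#'
#' The generator emulates the structure of a three-class single-cell
#' RPKM matrix: heavy-tailed nonnegative expression (log-normal), heavy
#' zero-inflation (multiplicative dropout), and class-specific marker
#' genes whose log-mean is shifted upward only in their own class, so
#' that markers are threshold-separable.
#'
#' @param n_per_class integer vector of length 3: cells per class.
#' @param n_genes number of gene features.
#' @param markers_per_class planted marker genes per class; the first
#'   `3 * markers_per_class` gene indices are markers, in class blocks,
#'   so ground truth is positionally deterministic.
#' @param effect_size log-scale mean shift of a marker in its own class.
#' @param baseline_log_mean log-scale mean of background expression.
#' @param noise_sd log-scale standard deviation (must be positive).
#' @param dropout_prob probability in \[0, 1\] that an entry is zeroed.
#' @param seed integer RNG seed; identical configs give bit-identical
#'   output.
#' @param class_names three class labels.
#' @return an object of class `cin_generator_config`.
#' @export
generator_config <- function(n_per_class = c(100L, 100L, 100L),
                             n_genes = 2000L,
                             markers_per_class = 20L,
                             effect_size = 2.0,
                             baseline_log_mean = 1.0,
                             noise_sd = 0.5,
                             dropout_prob = 0.3,
                             seed = 7L,
                             class_names = c("CGE", "dMGE", "vMGE")) {
  if (length(n_per_class) != 3 || any(n_per_class < 0) ||
      any(n_per_class != floor(n_per_class)))
    stop("n_per_class must be 3 nonnegative integers")
  if (length(n_genes) != 1 || n_genes < 1)
    stop("n_genes must be a positive integer")
  if (markers_per_class < 0 || 3 * markers_per_class > n_genes)
    stop("need 3 * markers_per_class <= n_genes")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must be in [0, 1]")
  if (length(class_names) != 3 || anyDuplicated(class_names))
    stop("class_names must be 3 distinct labels")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_genes = as.integer(n_genes),
                 markers_per_class = as.integer(markers_per_class),
                 effect_size = effect_size,
                 baseline_log_mean = baseline_log_mean,
                 noise_sd = noise_sd,
                 dropout_prob = dropout_prob,
                 seed = as.integer(seed),
                 class_names = class_names),
            class = "cin_generator_config")
}

#' Generate a synthetic three-class expression dataset
#'
#' Draws each entry as `exp(N(mu, noise_sd))` where `mu` is
#' `baseline_log_mean`, plus `effect_size` for a marker gene in cells of
#' its own class, then zeroes entries independently with probability
#' `dropout_prob`. All values are nonnegative; the zero fraction equals
#' the dropout probability in expectation.
#'
#' @param config a [generator_config()].
#' @return a list of class `cin_dataset` with elements `matrix` (cells x
#'   genes), `labels` (character vector named by cell id, aligned to the
#'   matrix rows), `truth` (list of marker gene ids per class) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "cin_generator_config"))
    config <- do.call(generator_config, config)
  n <- sum(config$n_per_class)
  G <- config$n_genes
  classes <- config$class_names
  labels <- rep(classes, times = config$n_per_class)
  cell_ids <- sprintf("cell_%04d", seq_len(n))
  gene_ids <- sprintf("g%05d", seq_len(G))
  m <- config$markers_per_class
  truth <- stats::setNames(
    lapply(seq_along(classes), function(k)
      if (m > 0) gene_ids[(k - 1) * m + seq_len(m)] else character(0)),
    classes)
  mu <- matrix(config$baseline_log_mean, n, G)
  for (k in seq_along(classes)) {
    if (m > 0)
      mu[labels == classes[k], (k - 1) * m + seq_len(m)] <-
        config$baseline_log_mean + config$effect_size
  }
  vals <- withr::with_seed(config$seed, {
    v <- matrix(exp(stats::rnorm(n * G, mean = as.vector(mu),
                                 sd = config$noise_sd)), n, G)
    keep <- matrix(stats::runif(n * G) >= config$dropout_prob, n, G)
    v * keep
  })
  dimnames(vals) <- list(cell_ids, gene_ids)
  structure(list(matrix = vals,
                 labels = stats::setNames(labels, cell_ids),
                 truth = truth,
                 config = config),
            class = "cin_dataset")
}

#' Write a generated dataset to disk
#'
#' Emits the standard expression TSV (genes x cells), the labels CSV and
#' a two-column TSV of planted marker genes (`gene_id`, `class`).
#'
#' @param dataset a `cin_dataset` from [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return named list of the three file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cin_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.csv"),
    truth = file.path(dir, "markers.tsv"))
  write_expression_matrix(dataset$matrix, paths$expression)
  write_labels(dataset$labels, paths$labels)
  truth_df <- do.call(rbind, lapply(names(dataset$truth), function(cl)
    if (length(dataset$truth[[cl]]))
      data.frame(gene_id = dataset$truth[[cl]], class = cl) else NULL))
  if (is.null(truth_df))
    truth_df <- data.frame(gene_id = character(0), class = character(0))
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Reference decision list for interneuron progenitor regions
#'
#' Returns the ruleset distributed with the package: an ordered decision
#' list of 22 explicit threshold rules on gene expression (12 predicting
#' CGE, 10 predicting vMGE) with dMGE as the fallback class. Gene names
#' are upper case; rule application matches gene names
#' case-insensitively. Two typographical artifacts in the original
#' printed table (an unbalanced parenthesis and a spaced `> =` operator)
#' are normalized to well-formed conditions without altering any number.
#'
#' @return a `cin_ruleset`.
#' @export
cin_reference_ruleset <- function() {
  path <- system.file("extdata", "cin_reference_ruleset.rules",
                      package = "cinrules", mustWork = TRUE)
  read_ruleset(path)
}

#' Manifest of the reference single-cell dataset
#'
#' Structural facts about the public mouse-subpallium single-cell
#' dataset the package's formats are modeled on: three classes of
#' 856/957/856 cells (CGE, dMGE, vMGE), 37,310 measured transcripts of
#' which 6,037 are zero in every cell.
#'
#' @return a list with `class_names`, `class_counts`,
#'   `total_transcripts` and `all_zero_transcripts`.
#' @export
cin_dataset_manifest <- function() {
  path <- system.file("extdata", "cin_dataset_manifest.json",
                      package = "cinrules", mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$class_counts <- as.integer(obj$class_counts)
  obj$total_transcripts <- as.integer(obj$total_transcripts)
  obj$all_zero_transcripts <- as.integer(obj$all_zero_transcripts)
  stopifnot(obj$all_zero_transcripts <= obj$total_transcripts)
  obj
}
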