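#' Configuration for the end-to-end pipeline
#'
#' Validates paths and numeric options up front so a misconfigured run
#' fails before any computation.
#'
#' @param expression path to a genes x cells expression TSV.
#' @param labels path to a `cell_id,class` CSV.
#' @param out_dir output directory for all derived artifacts.
#' @param alpha discretization width (SD units).
#' @param scheme mRMR scheme, `"mid"` or `"miq"`.
#' @param n_ranked how many features to rank (default: all retained).
#' @param ifs_step,ifs_max IFS grid step and cap for the tree ensemble.
#' @param ripper_ifs_max separate (usually smaller) IFS cap for the rule
#'   learner, which is the slowest stage; default `ifs_max`.
#' @param delta compact-selection MCC tolerance.
#' @param folds CV folds.
#' @param repeats repetitions for the stability check.
#' @param n_trees ensemble size (default 100).
#' @param grow_fraction,max_conditions RIPPER options.
#' @param run_ripper_ifs include the rule-learner IFS stage (default
#'   `TRUE`).
#' @param log1p log-transform before discretization (sensitivity flag).
#' @param seed base seed for every stage.
#' @return validated config list of class `cin_pipeline_config`.
#' @export
pipeline_config <- function(expression, labels, out_dir,
                            alpha = 1.0, scheme = "mid", n_ranked = NULL,
                            ifs_step = 10L, ifs_max = NULL,
                            ripper_ifs_max = NULL, delta = 0.015,
                            folds = 10L, repeats = 10L, n_trees = 100L,
                            grow_fraction = 2/3, max_conditions = 20L,
                            run_ripper_ifs = TRUE, log1p = FALSE,
                            seed = 1L) {
  if (!file.exists(expression)) stop("expression file not found: ", expression)
  if (!file.exists(labels)) stop("label file not found: ", labels)
  if (ifs_step < 1) stop("ifs_step must be >= 1")
  if (!is.null(ifs_max) && ifs_step > ifs_max)
    stop("ifs_step exceeds ifs_max")
  if (delta < 0) stop("delta must be nonnegative")
  structure(list(expression = expression, labels = labels,
                 out_dir = out_dir, alpha = alpha, scheme = scheme,
                 n_ranked = n_ranked, ifs_step = as.integer(ifs_step),
                 ifs_max = ifs_max, ripper_ifs_max = ripper_ifs_max,
                 delta = delta, folds = as.integer(folds),
                 repeats = as.integer(repeats),
                 n_trees = as.integer(n_trees),
                 grow_fraction = grow_fraction,
                 max_conditions = as.integer(max_conditions),
                 run_ripper_ifs = isTRUE(run_ripper_ifs),
                 log1p = isTRUE(log1p), seed = as.integer(seed)),
            class = "cin_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: all-zero filtering, three-state discretization,
#' mRMR ranking, IFS with the tree ensemble (and optionally with the
#' rule learner), optimal and compact selection, repeated CV of the
#' compact ensemble classifier, and rule induction on the rule-learner
#' optimum. Every derived artifact (ranked list TSV, IFS curves as JSON
#' and PDF, selection and evaluation JSONs, the learned ruleset, and a
#' machine-readable run manifest) is written under `out_dir`. The input
#' files are only read. Re-running with the same config reproduces all
#' JSON outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results and the paths of
#'   all written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cin_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    message("[pipeline] ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()

  m <- stage("read input", {
    mm <- read_expression_matrix(config$expression)
    lab <- read_labels(config$labels)
    list(x = mm, y = align_labels(lab, mm))
  })
  fz <- stage("filter all-zero transcripts", {
    r <- remove_all_zero_features(m$x)
    writeLines(r$removed, out("removed_genes.txt"))
    message(sprintf("  removed %d of %d genes", length(r$removed),
                    ncol(m$x)))
    r
  })
  paths$removed_genes <- out("removed_genes.txt")
  ranked <- stage("mRMR ranking", {
    disc <- discretize_three_state(fz$filtered, alpha = config$alpha,
                                   log1p = config$log1p)
    k <- config$n_ranked %||% ncol(fz$filtered)
    r <- mrmr_rank(disc, m$y, k = k, scheme = config$scheme)
    write_ranking(r, out("ranked_features.tsv"))
    r
  })
  paths$ranking <- out("ranked_features.tsv")

  rf <- make_learner("tree_ensemble", n_trees = config$n_trees,
                     seed = config$seed)
  ifs_rf <- stage("IFS (tree ensemble)", {
    grid <- build_subset_grid(nrow(ranked), step = config$ifs_step,
                              max_size = config$ifs_max %||% nrow(ranked))
    run_ifs(ranked, fz$filtered, m$y, rf, grid = grid,
            folds = config$folds, seed = config$seed)
  })
  opt_rf <- select_optimal(ifs_rf)
  comp_rf <- select_compact(ifs_rf, delta = config$delta)
  stage("write ensemble artifacts", {
    jsonlite::write_json(ifs_rf$curve, out("ifs_tree_ensemble.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    plot_ifs_curve(ifs_rf, list(opt_rf, comp_rf),
                   out("ifs_tree_ensemble.pdf"))
    write_eval_report(opt_rf$report, out("eval_optimal_tree_ensemble.json"))
    write_eval_report(comp_rf$report, out("eval_compact_tree_ensemble.json"))
  })
  paths$ifs_rf <- out("ifs_tree_ensemble.json")

  repcv <- stage("repeated CV (compact ensemble)", {
    xs <- fz$filtered[, ranked$gene_id[seq_len(comp_rf$size)],
                      drop = FALSE]
    r <- repeated_cv(xs, m$y, rf, folds = config$folds,
                     times = config$repeats,
                     base_seed = derive_seed(config$seed, 9001L))
    jsonlite::write_json(r$results, out("repeated_cv.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    r
  })
  paths$repeated_cv <- out("repeated_cv.json")

  ifs_rip <- NULL
  opt_rip <- NULL
  ruleset <- NULL
  if (config$run_ripper_ifs) {
    rip <- make_learner("ripper", seed = config$seed,
                        grow_fraction = config$grow_fraction,
                        max_conditions = config$max_conditions)
    ifs_rip <- stage("IFS (rule learner)", {
      cap <- config$ripper_ifs_max %||% config$ifs_max %||% nrow(ranked)
      grid <- build_subset_grid(nrow(ranked), step = config$ifs_step,
                                max_size = min(cap, nrow(ranked)))
      run_ifs(ranked, fz$filtered, m$y, rip, grid = grid,
              folds = config$folds, seed = config$seed)
    })
    opt_rip <- select_optimal(ifs_rip)
    ruleset <- stage("rule induction on optimal subset", {
      xs <- fz$filtered[, ranked$gene_id[seq_len(opt_rip$size)],
                        drop = FALSE]
      rs <- fit_ripper(xs, m$y, grow_fraction = config$grow_fraction,
                       seed = config$seed,
                       max_conditions = config$max_conditions)
      write_ruleset(rs, out("ruleset.rules"))
      rs
    })
    stage("write rule-learner artifacts", {
      jsonlite::write_json(ifs_rip$curve, out("ifs_ripper.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      plot_ifs_curve(ifs_rip, list(opt_rip), out("ifs_ripper.pdf"))
      write_eval_report(opt_rip$report, out("eval_optimal_ripper.json"))
    })
    paths$ruleset <- out("ruleset.rules")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cinrules")),
    config = config[setdiff(names(config), c("expression", "labels",
                                             "out_dir"))],
    inputs = list(expression = basename(config$expression),
                  labels = basename(config$labels)),
    n_cells = nrow(m$x),
    n_genes_input = ncol(m$x),
    n_genes_retained = ncol(fz$filtered),
    selections = list(
      tree_ensemble = list(optimal = list(size = opt_rf$size,
                                          mcc = opt_rf$mcc),
                           compact = list(size = comp_rf$size,
                                          mcc = comp_rf$mcc)),
      ripper = if (!is.null(opt_rip))
        list(optimal = list(size = opt_rip$size, mcc = opt_rip$mcc))))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$manifest <- out("run_manifest.json")

  invisible(list(ranking = ranked, ifs_tree_ensemble = ifs_rf,
                 optimal = opt_rf, compact = comp_rf,
                 repeated_cv = repcv, ifs_ripper = ifs_rip,
                 ripper_optimal = opt_rip, ruleset = ruleset,
                 paths = paths, out_dir = config$out_dir))
}
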