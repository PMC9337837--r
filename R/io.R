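#' Read an expression matrix from a genes-by-cells TSV file
#'
#' The on-disk convention is the GEO-style orientation: one row per gene,
#' one column per cell, a header row of cell identifiers and a first
#' column of gene identifiers. In memory the matrix is transposed to the
#' learning convention, cells as rows and genes as columns.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, cells x genes, with cell identifiers as row
#'   names and gene identifiers as column names.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 1) stop("expression file has no columns: ", path)
  gene_ids <- as.character(df[[1]])
  cell_ids <- colnames(df)[-1]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifier(s): ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1]
      stop("non-numeric entry at gene '", gene_ids[bad %||% 1],
           "', cell '", cell_ids[j], "'")
    }
  }
  m <- as.matrix(body)
  if (anyNA(m) || any(!is.finite(m))) {
    idx <- which(is.na(m) | !is.finite(m), arr.ind = TRUE)[1, ]
    stop("missing or non-finite entry at gene '", gene_ids[idx[1]],
         "', cell '", cell_ids[idx[2]], "'")
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative entry at gene '", gene_ids[idx[1]],
         "', cell '", cell_ids[idx[2]], "'")
  }
  out <- t(m)
  dimnames(out) <- list(cell_ids, gene_ids)
  out
}

#' Write an expression matrix to a genes-by-cells TSV file
#'
#' Inverse of [read_expression_matrix()]: the in-memory cells x genes
#' matrix is written transposed, genes as rows. Values use the shortest
#' decimal representation that round-trips exactly, so
#' `read(write(m)) == m` and rewriting an unchanged matrix is
#' byte-identical.
#'
#' @param matrix numeric cells x genes matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) ||
      (ncol(matrix) > 0 && is.null(colnames(matrix))))
    stop("matrix must carry cell (row) and gene (column) identifiers")
  if (any(matrix < 0)) stop("expression values must be nonnegative")
  cells <- rownames(matrix)
  genes <- colnames(matrix)
  header <- paste(c("gene_id", cells), collapse = "\t")
  if (length(genes) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- t(matrix)                        # genes x cells
  txt <- matrix(fmt_num(body), nrow = nrow(body))
  lines <- vapply(seq_along(genes), function(i)
    paste(c(genes[i], txt[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read or write a cell-label file
#'
#' Labels travel as a two-column CSV (`cell_id,class`) with a header.
#' Order is preserved exactly; `read_labels(write_labels(x)) == x`.
#'
#' @param path CSV file path.
#' @return `read_labels`: a data frame with character columns `cell_id`
#'   and `class`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("cell_id", "class") %in% colnames(df)))
    stop("label file must have columns 'cell_id' and 'class': ", path)
  df[, c("cell_id", "class")]
}

#' @rdname read_labels
#' @param labels a data frame with columns `cell_id` and `class`, or a
#'   character vector of classes named by cell identifier.
#' @export
write_labels <- function(labels, path) {
  if (is.character(labels) && !is.null(names(labels)))
    labels <- data.frame(cell_id = names(labels), class = unname(labels),
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(labels),
            all(c("cell_id", "class") %in% colnames(labels)))
  utils::write.csv(labels[, c("cell_id", "class")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a label table to an expression matrix
#'
#' @param labels data frame from [read_labels()].
#' @param matrix cells x genes matrix.
#' @return character vector of classes in matrix row order.
#' @export
align_labels <- function(labels, matrix) {
  idx <- match(rownames(matrix), labels$cell_id)
  if (anyNA(idx)) {
    missing <- rownames(matrix)[is.na(idx)]
    stop("cell(s) absent from label file: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  labels$class[idx]
}

# ---- ruleset text format ----------------------------------------------

new_ruleset <- function(rules, default_class) {
  stopifnot(is.list(rules), is.character(default_class),
            length(default_class) == 1)
  rules <- lapply(rules, function(r) {
    stopifnot(is.data.frame(r$conditions),
              all(c("gene", "op", "threshold") %in% colnames(r$conditions)),
              all(r$conditions$op %in% c("<=", ">=")),
              all(is.finite(r$conditions$threshold)),
              is.character(r$class), length(r$class) == 1)
    conds <- r$conditions[, c("gene", "op", "threshold")]
    rownames(conds) <- NULL
    list(conditions = conds, class = r$class)
  })
  structure(list(rules = rules, default_class = default_class),
            class = "cin_ruleset")
}

#' Parse a threshold ruleset from its text format
#'
#' Each line holds one rule of the form
#' `(GENE <= NUMBER) and (GENE >= NUMBER) ... => CLASS`, and the final
#' line names the fallback: `others => CLASS`. Unicode comparison signs
#' and spaced operators (`> =`) are accepted on input and normalized to
#' ASCII `<=`/`>=`. `parse_ruleset(format_ruleset(x))` reproduces `x`
#' exactly, and formatting a parsed canonical text is byte-identical.
#'
#' @param text a single string (possibly multi-line) or a character
#'   vector of lines.
#' @return an object of class `cin_ruleset`: an ordered decision list
#'   with first-match semantics and a default class.
#' @export
parse_ruleset <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- gsub("≤", "<=", lines)
  lines <- gsub("≥", ">=", lines)
  lines <- gsub("> =", ">=", lines, fixed = TRUE)
  lines <- gsub("< =", "<=", lines, fixed = TRUE)
  rules <- list()
  default <- NULL
  num_re <- "[-+]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][-+]?[0-9]+)?"
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (!is.null(default))
      stop("line ", i, ": content after the default ('others') rule")
    if (grepl("^[Oo]thers\\s*=>", ln)) {
      cls <- trimws(sub("^[Oo]thers\\s*=>\\s*", "", ln))
      if (cls == "") stop("line ", i, ": missing default class")
      default <- cls
      next
    }
    parts <- strsplit(ln, "=>", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("line ", i, ": expected exactly one '=> CLASS'")
    cls <- trimws(parts[2])
    if (cls == "") stop("line ", i, ": missing class label")
    lhs <- trimws(parts[1])
    if (!grepl("^\\(.*\\)$", lhs))
      stop("line ", i, ": conditions must be parenthesized")
    segs <- strsplit(substr(lhs, 2, nchar(lhs) - 1),
                     "\\)\\s+and\\s+\\(")[[1]]
    cond_re <- paste0("^(.+?)\\s*(<=|>=)\\s*(", num_re, ")$")
    conds <- lapply(seq_along(segs), function(k) {
      seg <- trimws(segs[k])
      m <- regmatches(seg, regexec(cond_re, seg, perl = TRUE))[[1]]
      if (length(m) == 0)
        stop("line ", i, ": cannot parse condition '", seg, "'")
      data.frame(gene = m[2], op = m[3], threshold = as.numeric(m[4]),
                 stringsAsFactors = FALSE)
    })
    rules[[length(rules) + 1L]] <-
      list(conditions = do.call(rbind, conds), class = cls)
  }
  if (is.null(default))
    stop("missing default line 'others => CLASS'")
  new_ruleset(rules, default)
}

#' @rdname parse_ruleset
#' @param ruleset a `cin_ruleset`.
#' @return `format_ruleset`: a single string in the canonical text format.
#' @export
format_ruleset <- function(ruleset) {
  stopifnot(inherits(ruleset, "cin_ruleset"))
  lines <- vapply(ruleset$rules, function(r) {
    conds <- sprintf("(%s %s %s)", r$conditions$gene, r$conditions$op,
                     fmt_num(r$conditions$threshold))
    paste0(paste(conds, collapse = " and "), " => ", r$class)
  }, character(1))
  paste(c(lines, paste0("others => ", ruleset$default_class)),
        collapse = "\n")
}

#' @rdname parse_ruleset
#' @param path file path.
#' @export
read_ruleset <- function(path) parse_ruleset(readLines(path, warn = FALSE))

#' @rdname parse_ruleset
#' @export
write_ruleset <- function(ruleset, path) {
  writeLines(format_ruleset(ruleset), path)
  invisible(path)
}

#' @export
print.cin_ruleset <- function(x, ...) {
  cat("Decision list with ", length(x$rules), " rule(s), default class '",
      x$default_class, "'\n", sep = "")
  txt <- strsplit(format_ruleset(x), "\n")[[1]]
  for (i in seq_along(txt)) cat(sprintf("%3d  %s\n", i, txt[i]))
  invisible(x)
}

# ---- evaluation report JSON -------------------------------------------

#' Write or read an evaluation report as JSON
#'
#' Serializes a `cin_eval` report (confusion matrix, ACC, multiclass MCC,
#' per-class individual accuracies) with an explicit schema version.
#'
#' @param report a `cin_eval` object (see [cross_validate()]).
#' @param path JSON file path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "cin_eval"))
  conf <- report$confusion
  obj <- list(
    schema_version = 1L,
    classes = report$classes,
    confusion = lapply(seq_len(nrow(conf)), function(i)
      as.integer(conf[i, ])),
    acc = report$acc,
    mcc = report$mcc,
    individual_accuracy = as.list(report$individual_accuracy),
    folds = report$folds,
    seed = report$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported evaluation-report schema in ", path)
  conf <- if (is.matrix(obj$confusion)) obj$confusion
          else do.call(rbind, obj$confusion)
  conf <- matrix(as.integer(conf), nrow = length(obj$classes),
                 dimnames = list(obj$classes, obj$classes))
  structure(list(classes = obj$classes, confusion = conf,
                 acc = as.numeric(obj$acc), mcc = as.numeric(obj$mcc),
                 individual_accuracy = unlist(obj$individual_accuracy),
                 folds = obj$folds, seed = obj$seed),
            class = "cin_eval")
}
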