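# Per-target candidate-regulator matrices M1-M5.
#
# Feature columns are named "EXPR_<gene>" or "METH_<gene>".  Each matrix
# level adds one biologically defined group of candidates:
#   M1  own promoter methylation + expression of same-set genes
#   M2  + expression of the target's own promoter-binding TFs
#   M3  + expression of TFs binding promoters of any same-set gene
#   M4  + expression of genes of the other sets
#   M5  + expression of TFs of other-set genes
# Union semantics: a feature keeps the provenance of the first group in
# which it appears ("avoiding repetitions").  M4 is built for provenance
# but the analysis sequence is M2, M3, M5.

feature_name <- function(kind, gene) paste0(kind, "_", gene)

new_feature_matrix <- function(target, level, samples, response, features, values) {
  stopifnot(nrow(values) == length(samples),
            ncol(values) == nrow(features),
            !anyDuplicated(features$name))
  dimnames(values) <- list(samples, features$name)
  structure(list(target = target, level = level, samples = samples,
                 response = setNames(response, samples),
                 features = features, values = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %s | target %s | %d samples x %d features>\n",
              x$level, x$target, length(x$samples), nrow(x$features)))
  if (nrow(x$features))
    print(table(provenance = x$features$provenance))
  invisible(x)
}

#' Assemble the nested candidate matrices M1-M5 for one target gene
#'
#' @param target target gene symbol (must be a column of `expression`).
#' @param gene_sets named list of gene sets (character vectors of symbols);
#'   the set containing `target` is the "same" set, all others the "other"
#'   sets.
#' @param expression numeric matrix samples x genes (see [read_expression()]).
#' @param methyl numeric matrix samples x genes of aggregated promoter
#'   methylation (see [aggregate_methylation()]); genes without a
#'   methylation feature simply lack a column.
#' @param tf_map named list gene -> TF symbols (see [map_tf_candidates()]).
#' @return object of class `feature_matrix_set`: a named list of the five
#'   `feature_matrix` levels with identical samples and nested columns.
#' @export
build_matrices <- function(target, gene_sets, expression, methyl, tf_map) {
  if (!target %in% colnames(expression))
    stop("target gene '", target, "' absent from the expression matrix")
  in_set <- vapply(gene_sets, function(s) target %in% s, logical(1))
  if (!any(in_set)) stop("target gene '", target, "' belongs to no gene set")
  its_set <- gene_sets[[which(in_set)[1L]]]
  other_sets <- gene_sets[!seq_along(gene_sets) %in% which(in_set)[1L]]

  samples <- intersect(rownames(expression), rownames(methyl))
  if (length(samples) == 0L)
    stop("no sample has both expression and methylation data")
  expression <- expression[samples, , drop = FALSE]
  methyl <- methyl[samples, , drop = FALSE]

  known_expr <- colnames(expression)
  tfs_of <- function(genes) {
    sort(unique(unlist(tf_map[intersect(genes, names(tf_map))], use.names = FALSE)))
  }
  expr_group <- function(genes, provenance) {
    genes <- setdiff(sort(unique(genes)), target)
    missing <- setdiff(genes, known_expr)
    if (length(missing))
      warning("omitted (no expression column): ",
              paste(missing, collapse = ", "), call. = FALSE)
    genes <- intersect(genes, known_expr)
    if (!length(genes)) return(NULL)
    data.frame(name = feature_name("EXPR", genes), kind = "EXPR",
               provenance = provenance, gene = genes, stringsAsFactors = FALSE)
  }

  own_meth <- if (target %in% colnames(methyl))
    data.frame(name = feature_name("METH", target), kind = "METHYL",
               provenance = "own_methyl", gene = target, stringsAsFactors = FALSE)
  groups <- list(
    M1 = rbind(own_meth, expr_group(its_set, "same_set_gene")),
    M2 = expr_group(tf_map[[target]] %||% character(0), "own_tf"),
    M3 = expr_group(tfs_of(its_set), "same_set_tf"),
    M4 = expr_group(unlist(other_sets, use.names = FALSE), "other_set_gene"),
    M5 = expr_group(tfs_of(unlist(other_sets, use.names = FALSE)), "other_set_tf"))

  levels <- c("M1", "M2", "M3", "M4", "M5")
  features <- data.frame(name = character(0), kind = character(0),
                         provenance = character(0), gene = character(0),
                         stringsAsFactors = FALSE)
  out <- list()
  response <- expression[, target]
  for (lv in levels) {
    add <- groups[[lv]]
    if (!is.null(add)) {
      add <- add[!add$name %in% features$name, , drop = FALSE]  # first wins
      features <- rbind(features, add)
    }
    vals <- matrix(NA_real_, nrow = length(samples), ncol = nrow(features))
    for (j in seq_len(nrow(features))) {
      vals[, j] <- if (features$kind[j] == "METHYL")
        methyl[, features$gene[j]] else expression[, features$gene[j]]
    }
    out[[lv]] <- new_feature_matrix(target, lv, samples, response,
                                    features[, c("name", "kind", "provenance")],
                                    vals)
  }
  # nesting invariant, asserted on every build
  for (i in 2:5) {
    stopifnot(all(out[[i - 1L]]$features$name %in% out[[i]]$features$name))
  }
  structure(out, class = "feature_matrix_set", target = target)
}

#' Apply the missing-data policy to candidate matrices
#'
#' Columns missing in more than `max_missing_frac` of samples are dropped;
#' remaining missing values are imputed with the column mean; constant
#' (zero-variance) columns are dropped.  Samples with a missing response are
#' removed.  Applied to a `feature_matrix_set` the decisions are taken once
#' (on the widest level) and applied to every level so nesting is preserved.
#'
#' @param x a `feature_matrix` or `feature_matrix_set`.
#' @param max_missing_frac maximum tolerated fraction of missing values per
#'   column (default 0.2).
#' @return object of the same class; dropped column names are recorded in
#'   `attr(, "dropped")`.
#' @export
handle_missing <- function(x, max_missing_frac = 0.2) UseMethod("handle_missing")

missing_decisions <- function(values, max_missing_frac) {
  frac <- colMeans(is.na(values))
  drop <- frac > max_missing_frac
  means <- colMeans(values, na.rm = TRUE)
  keep <- !drop
  # impute, then test variance
  v <- values
  for (j in which(keep)) {
    nas <- is.na(v[, j])
    if (any(nas)) v[nas, j] <- means[j]
  }
  const <- keep & apply(v, 2, function(col) isTRUE(all(col == col[1L])))
  list(drop = colnames(values)[drop | const], means = means)
}

apply_missing <- function(fm, decisions) {
  keep_s <- !is.na(fm$response)
  keep_c <- !fm$features$name %in% decisions$drop
  vals <- fm$values[keep_s, keep_c, drop = FALSE]
  for (j in seq_len(ncol(vals))) {
    nas <- is.na(vals[, j])
    if (any(nas)) vals[nas, j] <- decisions$means[[colnames(vals)[j]]]
  }
  out <- new_feature_matrix(fm$target, fm$level, fm$samples[keep_s],
                            fm$response[keep_s],
                            fm$features[keep_c, , drop = FALSE], vals)
  attr(out, "dropped") <- intersect(fm$features$name, decisions$drop)
  out
}

#' @export
handle_missing.feature_matrix <- function(x, max_missing_frac = 0.2) {
  dec <- missing_decisions(x$values, max_missing_frac)
  if (length(dec$drop))
    msg("dropped columns (missingness/zero variance): ",
        paste(dec$drop, collapse = ", "))
  apply_missing(x, dec)
}

#' @export
handle_missing.feature_matrix_set <- function(x, max_missing_frac = 0.2) {
  widest <- x[[length(x)]]
  dec <- missing_decisions(widest$values, max_missing_frac)
  if (length(dec$drop))
    msg("dropped columns (missingness/zero variance): ",
        paste(dec$drop, collapse = ", "))
  out <- lapply(x, apply_missing, decisions = dec)
  structure(out, class = "feature_matrix_set", target = attr(x, "target"),
            dropped = dec$drop)
}

#' Export a feature matrix as TSV with a JSON provenance sidecar
#'
#' @param fm a `feature_matrix`.
#' @param path output TSV path; provenance is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(fm, path) {
  df <- data.frame(sample = fm$samples, response = unname(fm$response),
                   fm$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(target = fm$target, level = fm$level,
                            features = fm$features),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
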