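# Signed regulatory networks built from significant model coefficients.

meth_node <- function(feature) {
  # "METH_<gene>" features become distinct "METH:<gene>" nodes so they never
  # collide with the gene's expression node.
  ifelse(startsWith(feature, "METH_"),
         sub("^METH_", "METH:", feature),
         sub("^EXPR_", "", feature))
}

#' Build a directed regulatory network from fitted models
#'
#' One edge per (significant feature, target gene) at the requested analysis
#' level, directed feature -> target and weighted by the standardized
#' regression coefficient; positive coefficients are activating edges,
#' negative ones repressing.
#'
#' @param fits a `cohort_fit`, or a named list of `regfit` / `reg_model`.
#' @param level analysis level to use (default `"M5"`).
#' @param gene_set optional label stored with the network.
#' @return object of class `reg_network` with `nodes` and an `edges`
#'   data.frame (`regulator`, `target`, `weight`, `sign`, `kind`).
#' @export
build_network <- function(fits, level = "M5", gene_set = NULL) {
  if (inherits(fits, "cohort_fit")) fits <- fits$fits
  targets <- names(fits)
  edge_rows <- lapply(targets, function(tg) {
    f <- fits[[tg]]
    m <- if (inherits(f, "regfit")) f$models[[level]] else f
    if (is.null(m)) return(NULL)
    sig <- m$features[m$significant[m$features]]
    if (length(sig) == 0L) return(NULL)
    data.frame(regulator = meth_node(sig), target = tg,
               weight = unname(m$coefficients[sig]),
               sign = ifelse(m$coefficients[sig] > 0, "positive", "negative"),
               kind = ifelse(startsWith(sig, "METH_"), "METHYL", "EXPR"),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_rows) %||%
    data.frame(regulator = character(0), target = character(0),
               weight = numeric(0), sign = character(0), kind = character(0))
  edges <- edges[order(edges$target, edges$regulator), , drop = FALSE]
  rownames(edges) <- NULL
  stopifnot(all(edges$weight != 0))
  nodes <- sort(unique(c(targets, edges$regulator)))
  structure(list(gene_set = gene_set, level = level, nodes = nodes,
                 edges = edges),
            class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("<reg_network%s [%s]: %d nodes, %d edges (%d repressing)>\n",
              if (is.null(x$gene_set)) "" else paste0(" ", x$gene_set),
              x$level, length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Export a regulatory network
#'
#' Formats: `"sif"` (relation encodes the sign: `activates`/`represses`),
#' `"tsv"` (full edge attributes) and `"graphml"` (via igraph, attributes
#' preserved).  Node and edge order is deterministic.
#'
#' @param network a `reg_network`.
#' @param path output file path.
#' @param format `"sif"`, `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    rel <- ifelse(e$sign == "positive", "activates", "represses")
    writeLines(sprintf("%s %s %s", e$regulator, rel, e$target), path)
  } else if (format == "tsv") {
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("regulator", "target", "weight", "sign", "kind")],
      directed = TRUE,
      vertices = data.frame(name = network$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a regulatory network edge list
#'
#' Reads back networks written by [export_network()] in `"tsv"` or
#' `"graphml"` format (SIF drops the quantitative weight and is one-way).
#'
#' @param path file path.
#' @param format `"tsv"` or `"graphml"`.
#' @param level,gene_set labels for the rebuilt object.
#' @return a `reg_network`.
#' @export
import_network <- function(path, format = c("tsv", "graphml"),
                           level = NA_character_, gene_set = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    e <- read.delim(path, stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    e <- igraph::as_data_frame(g, what = "edges")
    names(e)[1:2] <- c("regulator", "target")
  }
  e <- e[order(e$target, e$regulator), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(gene_set = gene_set, level = level,
                 nodes = sort(unique(c(e$regulator, e$target))),
                 edges = e[, c("regulator", "target", "weight", "sign", "kind")]),
            class = "reg_network")
}

#' Compare a regulatory network with an external ranked edge list
#'
#' The reference (e.g. a mutual-information network produced externally)
#' provides, per target, regulators ranked by a score.  For each target the
#' overlap is the fraction of the model's significant regulators present
#' among the reference's regulators of that target; rank agreement is the
#' Spearman correlation between |coefficient| ranks and reference-score
#' ranks over the shared regulators (needs at least two; otherwise `NA`).
#' The pooled overlap over all compared edges is reported as well.
#'
#' @param network a `reg_network`.
#' @param reference `data.frame` with columns `regulator`, `target`,
#'   `score` (higher = stronger).
#' @return list with `per_target` (`data.frame`: target, n_model_features,
#'   overlap, rho), `pooled_overlap`, `mean_overlap`, and
#'   `targets_not_in_reference`.
#' @export
compare_with_reference <- function(network, reference) {
  stopifnot(all(c("regulator", "target", "score") %in% names(reference)))
  e <- network$edges
  targets <- sort(unique(e$target))
  missing <- setdiff(targets, unique(reference$target))
  compared <- setdiff(targets, missing)
  rows <- lapply(compared, function(tg) {
    mine <- e[e$target == tg, , drop = FALSE]
    ref <- reference[reference$target == tg, , drop = FALSE]
    shared <- intersect(mine$regulator, ref$regulator)
    overlap <- length(shared) / nrow(mine)
    rho <- NA_real_
    if (length(shared) >= 2L) {
      mw <- abs(mine$weight[match(shared, mine$regulator)])
      rw <- ref$score[match(shared, ref$regulator)]
      rho <- suppressWarnings(cor(rank(-mw), rank(-rw), method = "spearman"))
    }
    data.frame(target = tg, n_model_features = nrow(mine),
               overlap = overlap, rho = rho)
  })
  per_target <- do.call(rbind, rows) %||%
    data.frame(target = character(0), n_model_features = integer(0),
               overlap = numeric(0), rho = numeric(0))
  pooled <- if (nrow(per_target))
    sum(per_target$overlap * per_target$n_model_features) /
      sum(per_target$n_model_features)
  else NA_real_
  list(per_target = per_target, pooled_overlap = pooled,
       mean_overlap = if (nrow(per_target)) mean(per_target$overlap) else NA_real_,
       targets_not_in_reference = missing)
}
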