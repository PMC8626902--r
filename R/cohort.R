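#' Assemble a cohort from pre-read objects
#'
#' Derives promoter and methylation windows from the annotation, maps
#' transcription factors to genes by promoter binding, aggregates probe
#' betas per gene, and restricts to the samples having both expression and
#' methylation data.
#'
#' @param annotation a `gene_annotation` (see [read_annotation()]).
#' @param peaks peak table (see [read_narrowpeak()]); may be empty.
#' @param expression numeric samples x genes matrix.
#' @param probes methylation probe table (see [read_methyl_probes()]).
#' @param gene_sets named list of gene sets.
#' @param targets target genes to model (default: all set members present in
#'   the expression matrix).
#' @param promoter_upstream,promoter_downstream promoter extents (defaults
#'   2000/1000 bases around the TSS).
#' @param methyl_upstream,methyl_downstream methylation-window extents
#'   (defaults 4000/1000).
#' @return object of class `reg_cohort`.
#' @export
make_cohort <- function(annotation, peaks, expression, probes, gene_sets,
                        targets = NULL,
                        promoter_upstream = 2000, promoter_downstream = 1000,
                        methyl_upstream = 4000, methyl_downstream = 1000) {
  promoters <- promoter_regions(annotation, promoter_upstream,
                                promoter_downstream)
  areas <- methyl_regions(annotation, methyl_upstream, methyl_downstream)
  tf_map <- map_tf_candidates(peaks, promoters)
  # TFs are evaluated through their expression; unmatched symbols dropped
  known <- colnames(expression)
  tf_map <- lapply(tf_map, function(tfs) {
    drop <- setdiff(tfs, known)
    if (length(drop))
      msg("TF(s) without expression column dropped: ",
          paste(drop, collapse = ", "))
    intersect(tfs, known)
  })
  methyl <- suppressWarnings(aggregate_methylation(probes, areas))
  samples <- intersect(rownames(expression), rownames(methyl))
  if (length(samples) == 0L)
    stop("no sample has both expression and methylation data")
  set_genes <- unique(unlist(gene_sets, use.names = FALSE))
  targets <- targets %||% intersect(set_genes, known)
  structure(list(annotation = annotation, gene_sets = gene_sets,
                 expression = expression[samples, , drop = FALSE],
                 methyl = methyl[samples, , drop = FALSE],
                 tf_map = tf_map, targets = targets, samples = samples,
                 promoters = promoters, methyl_areas = areas),
            class = "reg_cohort")
}

#' Read a cohort from flat files
#'
#' @param annotation path to the gene annotation.
#' @param annotation_format `"gtf"` or `"bed"`.
#' @param peaks path(s) to narrowPeak files; with several files each file's
#'   peaks keep the TF symbol in their name column.
#' @param expression path to the expression TSV.
#' @param probes path to the methylation probe TSV.
#' @param gene_sets path to the gene-set GMT/TSV.
#' @param ... passed to [make_cohort()].
#' @return object of class `reg_cohort`.
#' @export
read_cohort <- function(annotation, expression, probes, gene_sets,
                        peaks = character(0),
                        annotation_format = c("gtf", "bed"), ...) {
  annotation_format <- match.arg(annotation_format)
  ann <- read_annotation(annotation, format = annotation_format)
  pk <- if (length(peaks))
    do.call(rbind, lapply(peaks, read_narrowpeak))
  else
    data.frame(tf = character(0), chrom = character(0),
               start = integer(0), end = integer(0))
  make_cohort(ann, pk, read_expression(expression),
              read_methyl_probes(probes), read_gene_sets(gene_sets), ...)
}

#' @export
print.reg_cohort <- function(x, ...) {
  cat(sprintf(paste0("<reg_cohort: %d samples, %d genes with expression, ",
                     "%d gene sets, %d targets>\n"),
              length(x$samples), ncol(x$expression), length(x$gene_sets),
              length(x$targets)))
  invisible(x)
}
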