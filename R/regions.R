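#' Derive strand-aware windows around transcription start sites
#'
#' Builds one 0-based half-open interval per (gene, TSS).  On the `+`
#' strand the window is `[tss - upstream, tss + downstream)`; on the `-`
#' strand it is mirrored, `[tss - downstream + 1, tss + upstream + 1)`.
#' Starts are clamped at 0.  With the defaults this yields the promoter
#' window of 2000 bases upstream and 1000 downstream of the TSS; the
#' extended methylation window uses 4000/1000 (see [methyl_regions()]).
#'
#' @param annotation a `gene_annotation` (see [read_annotation()]).
#' @param upstream,downstream non-negative extents in bases.
#' @param kind region label, `"promoter"` or `"methyl_area"`.
#' @return `data.frame` with columns `gene`, `chrom`, `start`, `end`,
#'   `tss`, `strand`, `kind`.
#' @export
derive_regions <- function(annotation, upstream, downstream,
                           kind = c("promoter", "methyl_area")) {
  kind <- match.arg(kind)
  stopifnot(upstream >= 0, downstream >= 0)
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream,
                  annotation$tss - downstream + 1)
  end <- ifelse(plus, annotation$tss + downstream,
                annotation$tss + upstream + 1)
  start <- pmax(start, 0)
  out <- data.frame(gene = annotation$gene, chrom = annotation$chrom,
                    start = as.integer(start), end = as.integer(end),
                    tss = annotation$tss, strand = annotation$strand,
                    kind = kind, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname derive_regions
#' @export
promoter_regions <- function(annotation, upstream = 2000, downstream = 1000) {
  derive_regions(annotation, upstream, downstream, kind = "promoter")
}

#' @rdname derive_regions
#' @export
methyl_regions <- function(annotation, upstream = 4000, downstream = 1000) {
  derive_regions(annotation, upstream, downstream, kind = "methyl_area")
}

#' Map transcription factors to target genes by promoter binding
#'
#' A transcription factor is a candidate regulator of a gene if any of its
#' peaks overlaps (by at least one base, on the same chromosome) any
#' promoter window of the gene.  Each factor is listed once per gene.
#'
#' @param peaks peak table from [read_narrowpeak()].
#' @param promoters promoter windows from [promoter_regions()].
#' @return named list: gene symbol -> sorted character vector of TF symbols.
#' @export
map_tf_candidates <- function(peaks, promoters) {
  if (!all(promoters$kind == "promoter"))
    stop("map_tf_candidates() expects promoter regions")
  genes <- sort(unique(promoters$gene))
  out <- setNames(vector("list", length(genes)), genes)
  out[] <- list(character(0))
  if (nrow(peaks) == 0L || nrow(promoters) == 0L) return(out)
  pk <- as_granges0(peaks$chrom, peaks$start, peaks$end)
  pr <- as_granges0(promoters$chrom, promoters$start, promoters$end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pk, pr))
  if (length(hits)) {
    pairs <- unique(data.frame(
      gene = promoters$gene[S4Vectors::subjectHits(hits)],
      tf = peaks$tf[S4Vectors::queryHits(hits)],
      stringsAsFactors = FALSE))
    found <- lapply(split(pairs$tf, pairs$gene), function(x) sort(unique(x)))
    out[names(found)] <- found
  }
  out
}

#' Aggregate promoter methylation per gene and sample
#'
#' For each gene, pools the distinct probes falling inside the union of its
#' methylation windows (a probe shared by two overlapping windows counts
#' once) and returns the per-sample mean beta value, skipping missing
#' betas.  A sample with no usable probe gets `NA`; a gene with no probe in
#' any window is omitted and reported in `attr(, "no_methylation")`.
#'
#' @param probes probe table from [read_methyl_probes()].
#' @param areas methylation windows from [methyl_regions()].
#' @return numeric matrix samples x genes of mean beta values, with an
#'   attribute `no_methylation` listing genes without any probe.
#' @export
aggregate_methylation <- function(probes, areas) {
  if (!all(areas$kind == "methyl_area"))
    stop("aggregate_methylation() expects methyl_area regions")
  samples <- attr(probes, "samples") %||%
    setdiff(names(probes), c("probe_id", "chrom", "position"))
  genes <- sort(unique(areas$gene))
  beta <- as.matrix(probes[, samples, drop = FALSE])
  pb <- as_granges0(probes$chrom, probes$position, probes$position + 1L)
  ar <- as_granges0(areas$chrom, areas$start, areas$end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pb, ar))
  gene_of_hit <- areas$gene[S4Vectors::subjectHits(hits)]
  probe_of_hit <- probes$probe_id[S4Vectors::queryHits(hits)]
  row_of_hit <- S4Vectors::queryHits(hits)
  keep <- !duplicated(paste(gene_of_hit, probe_of_hit, sep = "\r"))
  gene_of_hit <- gene_of_hit[keep]; row_of_hit <- row_of_hit[keep]
  out <- matrix(NA_real_, nrow = length(samples), ncol = 0,
                dimnames = list(samples, NULL))
  missing_genes <- character(0)
  cols <- list()
  for (g in genes) {
    rows <- row_of_hit[gene_of_hit == g]
    if (length(rows) == 0L) {
      missing_genes <- c(missing_genes, g)
      next
    }
    sub <- beta[rows, , drop = FALSE]
    cols[[g]] <- colMeans(sub, na.rm = TRUE)
  }
  if (length(cols)) {
    out <- do.call(cbind, cols)
    out[is.nan(out)] <- NA_real_
    rownames(out) <- samples
  }
  if (length(missing_genes))
    warning("no methylation probe in any window of: ",
            paste(missing_genes, collapse = ", "))
  attr(out, "no_methylation") <- missing_genes
  out
}
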