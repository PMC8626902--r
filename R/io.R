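#' Read a gene annotation with transcription start sites
#'
#' Parses a GTF (Ensembl/GENCODE dialect, `gene_name` attribute) or a BED6
#' file and returns one row per gene and distinct TSS.  All coordinates are
#' converted to 0-based positions: the TSS of a `+` strand transcript is the
#' feature start, that of a `-` strand transcript the last base of the
#' feature.  Duplicate TSSs of a gene are collapsed.
#'
#' @param path path to the annotation file.
#' @param format `"gtf"` or `"bed"`.  For BED input each row carries one TSS
#'   (strand-aware; for an interval the start is used on `+`, the last base
#'   on `-`) and the name field is the gene symbol.
#' @return a `data.frame` of class `gene_annotation` with columns
#'   `gene`, `chrom`, `strand`, `tss` (0-based).
#' @export
read_annotation <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gtf") {
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nfield < 9)) {
      bad <- which(body)[which(nfield < 9)[1L]]
      stop("malformed GTF line ", bad, " in ", path,
           ": expected 9 tab-separated fields, found ", nfield[nfield < 9][1L])
    }
    gr <- rtracklayer::import(path, format = "gtf")
    if (any(gr$type == "transcript")) gr <- gr[gr$type == "transcript"]
    sym <- as.character(gr$gene_name)
    if (all(is.na(sym))) stop("GTF carries no gene_name attribute: ", path)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    sym <- as.character(gr$name)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  unstranded <- strand == "*" | is.na(strand)
  if (any(unstranded)) {
    warning(sum(unstranded), " record(s) without strand rejected in ", path)
    gr <- gr[!unstranded]; sym <- sym[!unstranded]
    strand <- strand[!unstranded]
  }
  nameless <- is.na(sym) | !nzchar(sym)
  if (any(nameless)) {
    warning(sum(nameless), " record(s) without gene symbol rejected in ", path)
    gr <- gr[!nameless]; strand <- strand[!nameless]; sym <- sym[!nameless]
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)            # half-open end
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  ann <- data.frame(gene = sym, chrom = as.character(GenomicRanges::seqnames(gr)),
                    strand = strand, tss = as.integer(tss),
                    stringsAsFactors = FALSE)
  ann <- unique(ann)
  ann <- ann[order(ann$gene, ann$chrom, ann$tss), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read ChIP-seq peaks in ENCODE narrowPeak format
#'
#' narrowPeak is BED6+4 (columns 7-10: signalValue, pValue, qValue, summit
#' offset).  Coordinates are returned 0-based half-open, as in BED.
#'
#' @param path path to a narrowPeak file.
#' @param tf optional transcription-factor symbol applied to every peak in
#'   the file; by default the BED name column is used.
#' @return a `data.frame` with columns `tf`, `chrom`, `start`, `end`
#'   (0-based half-open), `signal`, `summit_offset`.
#' @export
read_narrowpeak <- function(path, tf = NULL) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(signalValue = "numeric",
                                          pValue = "numeric",
                                          qValue = "numeric",
                                          peak = "integer"))
  sym <- if (is.null(tf)) as.character(gr$name) else rep(tf, length(gr))
  out <- data.frame(tf = sym,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    signal = gr$signalValue,
                    summit_offset = gr$peak,
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("narrowPeak with non-positive width in ", path)
  out
}

#' Read a methylation probe table
#'
#' Expects a TSV with columns `probe_id`, `chrom`, `position` (0-based)
#' followed by one beta-value column per sample.  Betas must lie in
#' \eqn{[0,1]} or be missing.
#'
#' @param path path to the probe table.
#' @return a `data.frame` with the three locus columns and one numeric
#'   column per sample; sample names are carried in `attr(, "samples")`.
#' @export
read_methyl_probes <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "position")
  if (!all(need %in% names(df)))
    stop("probe table must have columns probe_id, chrom, position: ", path)
  samples <- setdiff(names(df), need)
  if (length(samples) == 0L) stop("probe table has no sample columns: ", path)
  for (s in samples) {
    v <- df[[s]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("beta values outside [0,1] in sample column '", s, "'")
  }
  attr(df, "samples") <- samples
  df
}

#' Read a gene expression matrix
#'
#' TSV with the sample (aliquot) identifier in the first column and one
#' column per gene symbol.
#'
#' @param path path to the expression table.
#' @return numeric matrix, samples in rows (rownames), genes in columns.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a sample column plus genes: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (anyDuplicated(rownames(m))) stop("duplicate sample IDs in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate gene columns in ", path)
  m
}

#' Read gene-set definitions
#'
#' Accepts GMT (set name, description, then member genes) or a two-column
#' TSV (`set_name`, `gene`).
#'
#' @param path path to the gene-set file.
#' @param format `"gmt"`, `"tsv"`, or `"auto"` (by file extension).
#' @return named list of character vectors of member gene symbols.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad)) stop("malformed GMT line ", bad[1L], " in ", path)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, "", 1L)
  } else {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("gene-set TSV needs two columns in ", path)
    sets <- lapply(split(as.character(df[[2L]]), df[[1L]]), unique)
  }
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path)
  sets
}
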