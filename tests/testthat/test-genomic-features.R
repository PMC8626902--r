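test_that("GTF TSSs follow the strand convention and are deduplicated", {
  ann <- read_annotation(write_tiny_gtf(), format = "gtf")
  g1 <- ann[ann$gene == "g1", ]
  g2 <- ann[ann$gene == "g2", ]
  expect_equal(g1$tss, 1000)            # + strand: feature start, 0-based
  expect_equal(nrow(g1), 1L)            # shared TSS collapsed to one entry
  expect_equal(g2$tss, 4999)            # - strand: last base of the feature
})

test_that("malformed GTF lines are reported with their line number", {
  bad <- write_tiny_gtf(c(
    paste0("chr1\ttest\ttranscript\t1001\t5000\t.\t+\t.\t",
           'gene_id "G1"; gene_name "g1";'),
    "chr1\tonly\tthree"))
  expect_error(read_annotation(bad, format = "gtf"), "line 2")
})

test_that("records without strand are rejected with a warning", {
  path <- write_tiny_gtf(c(
    paste0("chr1\ttest\ttranscript\t1001\t5000\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "t1"; gene_name "g1";'),
    paste0("chr1\ttest\ttranscript\t9001\t9500\t.\t.\t.\t",
           'gene_id "G3"; transcript_id "t3"; gene_name "g3";')))
  expect_warning(ann <- read_annotation(path, format = "gtf"),
                 "without strand")
  expect_identical(ann$gene, "g1")
})

test_that("BED input yields strand-aware 0-based TSSs", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t1001\tg1\t0\t+",
               "chr1\t2000\t2001\tg2\t0\t-"), path)
  ann <- read_annotation(path, format = "bed")
  expect_equal(ann$tss[ann$gene == "g1"], 1000)
  expect_equal(ann$tss[ann$gene == "g2"], 2000)
})

test_that("promoter and methylation windows have the stated extents", {
  ann <- make_annotation(c("gp", "gm"), strand = c("+", "-"),
                         tss = c(10000, 10000))
  pr <- promoter_regions(ann)
  expect_equal(unname(unlist(pr[pr$gene == "gp", c("start", "end")])),
               c(8000, 11000))
  expect_equal(unname(unlist(pr[pr$gene == "gm", c("start", "end")])),
               c(9001, 12001))
  expect_true(all(pr$end - pr$start == 3000))
  ma <- methyl_regions(ann)
  expect_true(all(ma$end - ma$start == 5000))
  # clamped at the chromosome start
  clamped <- promoter_regions(make_annotation("gc", strand = "+", tss = 500))
  expect_equal(unname(unlist(clamped[, c("start", "end")])), c(0, 1500))
})

test_that("windows contain their TSS and mirror under strand reflection", {
  set.seed(7)
  tss <- sample(5000:50000, 25)
  for (strand in c("+", "-")) {
    r <- promoter_regions(make_annotation(sprintf("g%02d", seq_along(tss)),
                                          strand = strand, tss = tss))
    expect_true(all(r$start <= r$tss & r$tss < r$end))
  }
  # reflecting coordinates around an axis and flipping strand mirrors regions
  axis <- 60000
  fwd <- promoter_regions(make_annotation("g", strand = "+", tss = tss))
  rev <- promoter_regions(make_annotation("g", strand = "-",
                                          tss = axis - 1 - tss))
  expect_equal(rev$start, axis - fwd$end)
  expect_equal(rev$end, axis - fwd$start)
})

test_that("TF-to-gene mapping uses >= 1 bp half-open overlap, once per gene", {
  ann <- make_annotation("g", strand = "+", tss = 10000)   # promoter [8000,11000)
  ann2 <- rbind(ann, data.frame(gene = "g", chrom = "chr1", strand = "+",
                                tss = 10300))              # second promoter
  class(ann2) <- c("gene_annotation", "data.frame")
  pr <- promoter_regions(ann2)
  # promoters: [8000,11000) and [8300,11300)
  peaks <- data.frame(
    tf = c("t1", "t2", "t1"),
    chrom = "chr1",
    start = c(8100, 11300, 10500),   # inside / abutting (no overlap) / inside both
    end = c(8200, 11400, 10600))
  map <- map_tf_candidates(peaks, pr)
  expect_identical(map$g, "t1")      # t2 misses (half-open); t1 listed once
  # empty peak list is valid
  empty <- map_tf_candidates(peaks[0, ], pr)
  expect_identical(empty$g, character(0))
})

test_that("interval overlap matches a brute-force per-base scan", {
  set.seed(11)
  for (i in 1:50) {
    a <- sort(sample(0:30, 2)); b <- sort(sample(0:30, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1L
    if (b[1] == b[2]) b[2] <- b[2] + 1L
    brute <- length(intersect(seq(a[1], a[2] - 1), seq(b[1], b[2] - 1))) > 0
    pr <- data.frame(gene = "g", chrom = "c", start = a[1], end = a[2],
                     tss = a[1], strand = "+", kind = "promoter")
    pk <- data.frame(tf = "t", chrom = "c", start = b[1], end = b[2])
    got <- length(map_tf_candidates(pk, pr)$g) > 0
    expect_identical(got, brute)
    # and the operator is symmetric
    pr2 <- data.frame(gene = "g", chrom = "c", start = b[1], end = b[2],
                      tss = b[1], strand = "+", kind = "promoter")
    pk2 <- data.frame(tf = "t", chrom = "c", start = a[1], end = a[2])
    expect_identical(length(map_tf_candidates(pk2, pr2)$g) > 0, brute)
  }
})

test_that("methylation aggregation pools distinct probes and skips NAs", {
  ann <- make_annotation("g", strand = "+", tss = 10000)
  ann2 <- rbind(ann, data.frame(gene = "g", chrom = "chr1", strand = "+",
                                tss = 10500))
  class(ann2) <- c("gene_annotation", "data.frame")
  areas <- methyl_regions(ann2)      # two overlapping windows
  probes <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                       position = c(9000, 9500, 9800),
                       s1 = c(0.2, 0.4, NA), s2 = c(0.5, NA, 0.6),
                       s3 = c(0.2, NA, 0.6))
  attr(probes, "samples") <- c("s1", "s2", "s3")
  m <- aggregate_methylation(probes, areas)
  expect_equal(m["s1", "g"], 0.3)            # mean of present betas
  expect_equal(m["s2", "g"], 0.55)           # probe in 2 windows counted once
  expect_equal(m["s3", "g"], 0.4)            # {0.2, NA, 0.6} -> 0.4
  # gene with no probe anywhere is flagged and omitted
  far <- make_annotation("h", strand = "+", tss = 900000)
  both <- rbind(areas, methyl_regions(far))
  expect_warning(m2 <- aggregate_methylation(probes, both), "h")
  expect_identical(attr(m2, "no_methylation"), "h")
  expect_false("h" %in% colnames(m2))
})

test_that("all-missing sample gets NA rather than a number", {
  ann <- make_annotation("g", strand = "+", tss = 10000)
  areas <- methyl_regions(ann)
  probes <- data.frame(probe_id = "p1", chrom = "chr1", position = 9000,
                       s1 = NA_real_, s2 = 0.7)
  attr(probes, "samples") <- c("s1", "s2")
  m <- aggregate_methylation(probes, areas)
  expect_true(is.na(m["s1", "g"]))
  expect_equal(m["s2", "g"], 0.7)
})

test_that("narrowPeak reader returns 0-based half-open peaks", {
  path <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t8100\t8200\tTF1\t0\t.\t5.5\t-1\t-1\t50", path)
  pk <- read_narrowpeak(path)
  expect_equal(pk$start, 8100)
  expect_equal(pk$end, 8200)
  expect_equal(pk$tf, "TF1")
  expect_equal(pk$signal, 5.5)
  expect_equal(pk$summit_offset, 50)
})
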