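# Synthetic multi-omic cohort with planted sparse linear regulatory truth.
#
# The generator emulates the shapes of the real inputs: a GTF annotation
# with strands and TSSs, narrowPeak ChIP-seq peaks placed inside (planted
# links) and outside (decoys) promoter windows, a 450k-style probe table
# with beta values in [0,1] carrying a per-sample signal on the logit
# scale, a continuous expression matrix, and gene sets.  Each target's
# expression is a sparse linear combination of z-scored regulator values
# plus Gaussian noise; regulators are exogenous, so the planted model is
# identifiable and serves as the oracle for recovery scoring.

#' Default configuration of the synthetic cohort
#'
#' The defaults define the reference study conditions used throughout the
#' package's evaluation: 400 samples, two gene sets of 10 target genes plus
#' 5 non-target member genes each, a pool of 30 transcription factors, and
#' 3 planted regulators per target (one in each analysis group: the M2
#' candidates, the same-set-gene TFs new at M3, and the other-set genes new
#' at M5) with planted standardized coefficients summing in squares to the
#' true R^2 of 0.7.  For a quarter of the targets the first-group regulator
#' is the gene's own promoter methylation, with a negative (repressive)
#' coefficient, mirroring the repressive methylation effects seen in tumor
#' cohorts.
#'
#' @param ... overrides of individual fields.
#' @return named list of generator settings.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_samples = 400L,
    targets_per_set = 10L,
    members_per_set = 5L,
    n_sets = 2L,
    n_tfs = 30L,
    regulators_per_target = 3L,
    coef_range = c(0.4, 0.55),  # magnitudes before rescaling to target_r2
    target_r2 = 0.7,
    meth_frac = 0.25,
    decoy_tfs_per_gene = 2L,
    n_decoy_peaks = 30L,
    probes_per_gene = 5L,
    probe_noise_sd = 0.1,
    meth_latent_scale = 0.5,
    gene_spacing = 100000L,
    chrom = "chr1")
  modifyList(cfg, list(...))
}

synthetic_gene_table <- function(cfg) {
  stopifnot(cfg$n_sets >= 1L)
  set_ids <- LETTERS[seq_len(cfg$n_sets)]
  rows <- lapply(seq_along(set_ids), function(i) {
    id <- set_ids[i]
    data.frame(
      gene = c(sprintf("%s%02d", id, seq_len(cfg$targets_per_set)),
               sprintf("%sM%d", id, seq_len(cfg$members_per_set))),
      set = paste0("SET_", id),
      is_target = rep(c(TRUE, FALSE),
                      c(cfg$targets_per_set, cfg$members_per_set)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic cohort on disk
#'
#' Writes `annotation.gtf`, `peaks.narrowPeak`, `methyl_probes.tsv`,
#' `expression.tsv`, `gene_sets.gmt` and `truth.json` into `dir`.  Output is
#' byte-identical for identical `(config, seed)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @param dir output directory (created if needed).
#' @return list with `paths` (named file paths), `truth` (per-target planted
#'   coefficient maps and noise sd) and `config`, invisibly classed
#'   `synthetic_truth`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 0L,
                            dir = tempfile("cohort"), sample_seed = seed) {
  cfg <- config
  if (cfg$n_samples < 50L) stop("config requires n_samples >= 50")
  if (cfg$regulators_per_target > 3L)
    stop("at most 3 planted regulators (one per analysis group) supported")
  if (cfg$n_sets < 2L && cfg$regulators_per_target >= 3L)
    stop("a third (other-set) regulator requires at least two gene sets")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- synthetic_gene_table(cfg)
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))

  # -- annotation: alternating strands, every 5th gene gets a second TSS
  n_g <- nrow(genes)
  strand <- rep(c("+", "-"), length.out = n_g)
  tss1 <- 50000L + (seq_len(n_g) - 1L) * cfg$gene_spacing
  ann <- data.frame(gene = genes$gene, chrom = cfg$chrom, strand = strand,
                    tss = tss1, stringsAsFactors = FALSE)
  extra <- genes$gene[seq_len(n_g) %% 5L == 0L]
  if (length(extra)) {
    idx <- match(extra, genes$gene)
    ann <- rbind(ann, data.frame(gene = extra, chrom = cfg$chrom,
                                 strand = strand[idx],
                                 tss = tss1[idx] + 300L))
  }
  ann <- ann[order(ann$gene, ann$tss), , drop = FALSE]
  class(ann) <- c("gene_annotation", "data.frame")
  promoters <- promoter_regions(ann)

  # structure (planted truth, TF assignments, peaks) is driven by `seed`;
  # sample-level draws by `sample_seed`, so an i.i.d. replicate cohort with
  # the same truth is generate_cohort(cfg, seed, sample_seed = other)
  struct <- with_seed(derive_seed(seed, "cohort"), {
    # -- TF binding: decoys on every set gene, then planted links
    tf_assign <- setNames(lapply(genes$gene, function(g)
      sort(sample(tfs, cfg$decoy_tfs_per_gene))), genes$gene)

    # -- planted truth, one regulator per analysis group
    truth <- list()
    targets <- genes$gene[genes$is_target]
    for (tg in targets) {
      set_of <- genes$set[genes$gene == tg]
      members_same <- genes$gene[genes$set == set_of & !genes$is_target]
      members_other <- genes$gene[genes$set != set_of & !genes$is_target]
      k <- cfg$regulators_per_target
      feats <- character(0)
      if (k >= 1L) {
        if (runif(1) < cfg$meth_frac) {
          feats <- feature_name("METH", tg)
        } else {
          feats <- feature_name("EXPR", sample(members_same, 1L))
        }
      }
      if (k >= 2L) {
        # a TF of a same-set gene, new at the M3 step: host the peak on a
        # non-target member so no later plant can put this TF on a target's
        # own promoter (which would move it into the M2 group)
        free_tfs <- setdiff(tfs, tf_assign[[tg]])
        t2 <- sample(free_tfs, 1L)
        host <- sample(members_same, 1L)
        tf_assign[[host]] <- sort(union(tf_assign[[host]], t2))
        feats <- c(feats, feature_name("EXPR", t2))
      }
      if (k >= 3L) {
        feats <- c(feats, feature_name("EXPR", sample(members_other, 1L)))
      }
      coefs <- numeric(0)
      noise_sd <- 1
      if (k >= 1L) {
        mag <- runif(k, cfg$coef_range[1L], cfg$coef_range[2L])
        mag <- mag * sqrt(cfg$target_r2 / sum(mag^2))
        sign <- ifelse(runif(k) < 0.5, -1, 1)
        sign[startsWith(feats, "METH_")] <- -1  # methylation represses
        coefs <- setNames(mag * sign, feats)
        noise_sd <- sqrt(1 - cfg$target_r2)
      }
      truth[[tg]] <- list(coefficients = as.list(coefs), noise_sd = noise_sd)
    }
    # -- peaks: one inside a promoter per (gene, TF) link + intergenic decoys
    peak_rows <- list()
    for (g in genes$gene) {
      pr <- promoters[promoters$gene == g, , drop = FALSE][1L, ]
      for (tf in tf_assign[[g]]) {
        s <- pr$start + 800L
        peak_rows[[length(peak_rows) + 1L]] <-
          data.frame(tf = tf, chrom = pr$chrom, start = s, end = s + 100L,
                     signal = round(runif(1, 2, 10), 3), summit_offset = 50L)
      }
    }
    for (i in seq_len(cfg$n_decoy_peaks)) {
      g <- sample(n_g, 1L)
      s <- tss1[g] + 40000L + i * 10L  # intergenic: far from any window
      peak_rows[[length(peak_rows) + 1L]] <-
        data.frame(tf = sample(tfs, 1L), chrom = cfg$chrom,
                   start = s, end = s + 100L,
                   signal = round(runif(1, 2, 10), 3), summit_offset = 50L)
    }
    peaks <- do.call(rbind, peak_rows)
    peaks <- peaks[order(peaks$chrom, peaks$start, peaks$tf), , drop = FALSE]
    base_logit <- setNames(qlogis(runif(n_g, 0.25, 0.75)), genes$gene)
    list(tf_assign = tf_assign, truth = truth, peaks = peaks,
         base_logit = base_logit)
  })
  truth_models <- struct$truth
  targets <- genes$gene[genes$is_target]

  out <- with_seed(derive_seed(sample_seed, "expression"), {
    # -- methylation: per-gene per-sample latent on the logit scale
    n <- cfg$n_samples
    base_logit <- struct$base_logit
    meth_latent <- matrix(rnorm(n * n_g), n, n_g,
                          dimnames = list(samples, genes$gene))
    probe_rows <- list()
    for (g in genes$gene) {
      area <- methyl_regions(ann[ann$gene == g, , drop = FALSE][1L, ])
      pos <- area$start + round(seq(500, 4500,
                                    length.out = cfg$probes_per_gene))
      for (j in seq_len(cfg$probes_per_gene)) {
        logit <- base_logit[g] + cfg$meth_latent_scale * meth_latent[, g] +
          rnorm(n, sd = cfg$probe_noise_sd)
        beta <- pmin(pmax(plogis(logit), 0.01), 0.99)
        probe_rows[[length(probe_rows) + 1L]] <- c(
          list(probe_id = sprintf("cg_%s_%d", g, j), chrom = area$chrom,
               position = pos[j]),
          as.list(round(beta, 5)))
      }
    }
    probe_df <- do.call(rbind, lapply(probe_rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    names(probe_df) <- c("probe_id", "chrom", "position", samples)

    # -- expression: exogenous regulators standard normal, targets planted
    expr <- matrix(rnorm(n * (n_g + cfg$n_tfs)), n,
                   dimnames = list(samples, c(genes$gene, tfs)))
    for (tg in targets) {
      tr <- truth_models[[tg]]
      coefs <- unlist(tr$coefficients)
      y <- rnorm(n, sd = tr$noise_sd)
      for (f in names(coefs)) {
        v <- if (startsWith(f, "METH_")) meth_latent[, sub("^METH_", "", f)]
             else expr[, sub("^EXPR_", "", f)]
        y <- y + coefs[[f]] * drop(scale(v))
      }
      expr[, tg] <- y
    }
    list(probe_df = probe_df, expr = expr)
  })

  paths <- c(annotation = file.path(dir, "annotation.gtf"),
             peaks = file.path(dir, "peaks.narrowPeak"),
             probes = file.path(dir, "methyl_probes.tsv"),
             expression = file.path(dir, "expression.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_gtf(ann, cfg, paths[["annotation"]])
  pk <- struct$peaks
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.\t%g\t-1\t-1\t%d",
                     pk$chrom, pk$start, pk$end, pk$tf, pk$signal,
                     pk$summit_offset), paths[["peaks"]])
  write.table(out$probe_df, paths[["probes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  expr_df <- data.frame(sample = samples, round(out$expr, 6),
                        check.names = FALSE)
  write.table(expr_df, paths[["expression"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  sets <- split(genes$gene, genes$set)
  writeLines(vapply(names(sets), function(s)
    paste(c(s, "synthetic", sets[[s]]), collapse = "\t"), ""),
    paths[["gene_sets"]])
  truth <- list(seed = as.integer(seed),
                sample_seed = as.integer(sample_seed),
                n_samples = cfg$n_samples,
                targets = targets,
                models = truth_models)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(structure(list(paths = paths, truth = truth, config = cfg),
                      class = "synthetic_truth"))
}

write_gtf <- function(ann, cfg, path) {
  lines <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    tss <- ann$tss[i]
    if (ann$strand[i] == "+") { s1 <- tss + 1L; e1 <- tss + 2000L }
    else { e1 <- tss + 1L; s1 <- max(1L, e1 - 1999L) }
    lines[i] <- sprintf(
      paste0("%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t",
             "gene_id \"%s\"; transcript_id \"%s.t%d\"; gene_name \"%s\";"),
      ann$chrom[i], s1, e1, ann$strand[i], ann$gene[i], ann$gene[i], i,
      ann$gene[i])
  }
  writeLines(lines, path)
}

#' Generate and load a synthetic cohort in one call
#'
#' Runs [generate_cohort()] and reads the emitted files back through the
#' package's own readers, so every synthetic run also exercises the parsing
#' layer.
#'
#' @inheritParams generate_cohort
#' @return a `reg_cohort` whose `$truth` field holds the planted truth.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 0L,
                            dir = tempfile("cohort"), sample_seed = seed) {
  gen <- generate_cohort(config, seed, dir, sample_seed = sample_seed)
  cohort <- read_cohort(annotation = gen$paths[["annotation"]],
                        expression = gen$paths[["expression"]],
                        probes = gen$paths[["probes"]],
                        gene_sets = gen$paths[["gene_sets"]],
                        peaks = gen$paths[["peaks"]],
                        annotation_format = "gtf",
                        targets = gen$truth$targets)
  cohort$truth <- gen$truth
  cohort$paths <- gen$paths
  cohort
}

#' Score feature and coefficient recovery against the planted truth
#'
#' @param fits a `cohort_fit`, a named list of `regfit`, or a named list of
#'   character vectors of selected features.
#' @param truth the `truth` element of a synthetic cohort.
#' @param level analysis level whose fitted coefficients are compared
#'   (default: each fit's last modelled level).
#' @return list with `per_target` (`data.frame`: target, n_true,
#'   n_selected, tp, precision, recall, f1) and aggregate `precision`,
#'   `recall`, `f1` (means over targets) and `coef_rmse` (root mean square
#'   error of fitted vs planted coefficients over all true positives).
#' @export
score_recovery <- function(fits, truth, level = NULL) {
  if (inherits(fits, "cohort_fit")) fits <- fits$fits
  targets <- intersect(names(fits), names(truth$models))
  sq_err <- numeric(0)
  rows <- lapply(targets, function(tg) {
    planted <- names(truth$models[[tg]]$coefficients)
    f <- fits[[tg]]
    if (is.character(f)) {
      selected <- f
      coefs <- NULL
    } else {
      selected <- f$selection$final
      lv <- level %||% last_modeled_level(f)
      coefs <- if (!is.null(lv)) coef(f, level = lv)
    }
    tp <- intersect(selected, planted)
    if (!is.null(coefs) && length(tp)) {
      est <- coefs[tp]
      tru <- unlist(truth$models[[tg]]$coefficients)[tp]
      sq_err <<- c(sq_err, (est - tru)^2)
    }
    precision <- if (length(selected)) length(tp) / length(selected) else NA_real_
    recall <- if (length(planted)) length(tp) / length(planted) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    data.frame(target = tg, n_true = length(planted),
               n_selected = length(selected), tp = length(tp),
               precision = precision, recall = recall, f1 = f1)
  })
  per_target <- do.call(rbind, rows)
  rownames(per_target) <- NULL
  list(per_target = per_target,
       precision = mean(per_target$precision, na.rm = TRUE),
       recall = mean(per_target$recall, na.rm = TRUE),
       f1 = mean(per_target$f1, na.rm = TRUE),
       coef_rmse = if (length(sq_err)) sqrt(mean(sq_err)) else NA_real_)
}
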