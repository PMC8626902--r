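# End-to-end pipeline driver: wiring of simulate / build / select / fit /
# network / transfer / compare-selection with a reproducibility manifest.

#' Default run configuration
#'
#' All analysis defaults in one place: promoter window 2000/1000 bases
#' around the TSS, methylation window 4000/1000, analysis levels M2, M3 and
#' M5, the incremental forward selection with re-evaluation strategy, a
#' required partition seed (default 0), missing-data threshold 0.2,
#' adjusted-R^2 acceptance threshold 0.6, and the transfer flags (source
#' floor 0.4, agreement delta 0.1).
#'
#' @param ... overrides of individual fields (paths to `annotation`,
#'   `expression`, `probes`, `gene_sets`, `peaks`, ...).
#' @return named list.
#' @export
run_config <- function(...) {
  cfg <- list(
    annotation = NULL, annotation_format = "gtf",
    expression = NULL, probes = NULL, gene_sets = NULL,
    peaks = character(0),
    reference_edges = NULL,
    promoter_upstream = 2000, promoter_downstream = 1000,
    methyl_upstream = 4000, methyl_downstream = 1000,
    levels = c("M2", "M3", "M5"),
    strategy = "incr_ffs_reeval",
    seed = 0L, max_k = NULL,
    max_missing_frac = 0.2,
    adj_r2_threshold = 0.6,
    transfer_floor = 0.4, transfer_delta = 0.1,
    cohort = list())   # overrides of cohort_config() for the simulate step
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.character(over[[1L]]))
    over <- yaml::read_yaml(over[[1L]])
  modifyList(cfg, over)
}

load_cohort_from_config <- function(config) {
  for (p in c("annotation", "expression", "probes", "gene_sets"))
    if (is.null(config[[p]]))
      stop("config is missing required input path: ", p)
  for (p in c(config$annotation, config$expression, config$probes,
              config$gene_sets, config$peaks))
    if (!file.exists(p)) stop("input file not found: ", p)
  read_cohort(annotation = config$annotation,
              expression = config$expression,
              probes = config$probes,
              gene_sets = config$gene_sets,
              peaks = config$peaks,
              annotation_format = config$annotation_format,
              promoter_upstream = config$promoter_upstream,
              promoter_downstream = config$promoter_downstream,
              methyl_upstream = config$methyl_upstream,
              methyl_downstream = config$methyl_downstream)
}

write_manifest <- function(config, out_dir, extra = list()) {
  inputs <- unlist(config[c("annotation", "expression", "probes",
                            "gene_sets", "peaks")])
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  sums <- vapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_, "")
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("increg")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    input_md5 = as.list(sums)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the analysis pipeline
#'
#' Executes one pipeline step and writes its artifacts (plus a manifest
#' recording the configuration, seed and input checksums) under `out_dir`:
#' \describe{
#'   \item{`simulate`}{generate a synthetic cohort into `out_dir`.}
#'   \item{`fit`}{load the cohort, run selection + regression for every
#'     target, write the model summary TSV and per-gene model JSONs.}
#'   \item{`network`}{`fit`, then write the network per analysis level
#'     (TSV + SIF); if `config$reference_edges` is set, also the overlap
#'     report against that ranked edge list.}
#'   \item{`compare-selection`}{run all five selection strategies and write
#'     the per-strategy summary (model count, feature count, mean BIC).}
#' }
#'
#' @param step one of `"simulate"`, `"fit"`, `"network"`,
#'   `"compare-selection"`.
#' @param config a [run_config()] (or path to a YAML file of overrides).
#' @param out_dir output directory.
#' @return the step's main result object, invisibly.
#' @export
run_pipeline <- function(step = c("simulate", "fit", "network",
                                  "compare-selection"),
                         config = run_config(), out_dir = "increg_run") {
  step <- match.arg(step)
  if (is.character(config)) config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (step == "simulate") {
    gen <- generate_cohort(do.call(cohort_config, config$cohort),
                           seed = config$seed, dir = out_dir)
    write_manifest(config, out_dir, list(step = step))
    return(invisible(gen))
  }

  cohort <- load_cohort_from_config(config)

  if (step == "compare-selection") {
    res <- compare_selection(cohort, seed = config$seed,
                             levels = config$levels,
                             max_k = config$max_k,
                             max_missing_frac = config$max_missing_frac)
    write.table(res, file.path(out_dir, "strategy_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(config, out_dir, list(step = step))
    return(invisible(res))
  }

  fits <- fit_cohort(cohort, seed = config$seed,
                     strategy = config$strategy, levels = config$levels,
                     max_k = config$max_k,
                     max_missing_frac = config$max_missing_frac)
  tab <- summarize_models(fits, threshold = config$adj_r2_threshold)
  write.table(tab, file.path(out_dir, "models.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  model_dir <- file.path(out_dir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  for (tg in names(fits$fits)) {
    f <- fits$fits[[tg]]
    per_level <- lapply(f$models, function(m) {
      if (is.null(m)) return(NULL)
      list(features = m$features,
           coefficients = as.list(m$coefficients[m$features]),
           intercept = m$intercept,
           ci_low = as.list(m$ci_low[m$features]),
           ci_high = as.list(m$ci_high[m$features]),
           significant = as.list(m$significant),
           r2 = m$r2, adj_r2 = m$adj_r2, bic = m$bic, n = m$n, k = m$k)
    })
    jsonlite::write_json(
      list(target = tg, strategy = f$strategy, models = per_level),
      file.path(model_dir, paste0(tg, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }

  if (step == "network") {
    for (lv in config$levels) {
      net <- build_network(fits, level = lv)
      export_network(net, file.path(out_dir, paste0("network_", lv, ".tsv")),
                     "tsv")
      export_network(net, file.path(out_dir, paste0("network_", lv, ".sif")),
                     "sif")
      if (!is.null(config$reference_edges) && lv == config$levels[length(config$levels)]) {
        ref <- read.delim(config$reference_edges, stringsAsFactors = FALSE)
        cmp <- compare_with_reference(net, ref)
        write.table(cmp$per_target,
                    file.path(out_dir, paste0("reference_overlap_", lv, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  write_manifest(config, out_dir, list(step = step))
  invisible(fits)
}
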