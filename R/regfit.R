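#' Fit the regulation model of one target gene
#'
#' The main per-gene estimator: applies the missing-data policy, z-scores
#' predictors and response, runs the requested selection strategy across the
#' nested matrix sequence under the shared fold partition, and fits the
#' final OLS model(s) on all samples using each analysis level's consensus
#' feature set.
#'
#' @param matrices a `feature_matrix_set` from [build_matrices()].
#' @param partition a [cv_partition()] shared across all genes of a run.
#' @param strategy selection strategy, see [select_features()].
#' @param levels analysis levels in nesting order (default M2, M3, M5).
#' @param max_k maximal forward-selection path length (default
#'   `min(30, floor(n_train/10))`).
#' @param max_missing_frac missing-data threshold, see [handle_missing()].
#' @param lambda optional explicit lasso penalty grid.
#' @param consensus_min minimum folds that must agree (default: all).
#' @return object of class `regfit`: the selection trace plus one
#'   `reg_model` per analysis level with a non-empty feature set (levels
#'   without features carry `NULL`, the gene has "no model" there).
#' @seealso [fit_cohort()] for all targets of a cohort.
#' @export
regfit <- function(matrices, partition,
                   strategy = "incr_ffs_reeval",
                   levels = intersect(c("M2", "M3", "M5"), names(matrices)),
                   max_k = NULL, max_missing_frac = 0.2,
                   lambda = NULL, consensus_min = NULL) {
  matrices <- handle_missing(matrices, max_missing_frac)
  z <- zscore(matrices)
  selection <- select_features(z, partition, strategy = strategy,
                               max_k = max_k, levels = levels,
                               lambda = lambda, consensus_min = consensus_min)
  sets <- level_feature_sets(selection)
  models <- setNames(vector("list", length(levels)), levels)
  for (lv in levels) {
    feats <- sets[[lv]] %||% character(0)
    if (length(feats) == 0L) next
    fm <- z[[lv]]
    models[[lv]] <- fit_ols(fm$values[, feats, drop = FALSE],
                            unname(fm$response),
                            target = fm$target, level = lv)
  }
  structure(list(target = attr(matrices, "target"), strategy = strategy,
                 levels = levels, selection = selection, models = models,
                 matrices = z, partition_seed = partition$seed),
            class = "regfit")
}

last_modeled_level <- function(x) {
  has <- x$levels[!vapply(x$models[x$levels], is.null, logical(1))]
  if (length(has) == 0L) NULL else has[length(has)]
}

#' @export
print.regfit <- function(x, ...) {
  cat(sprintf("<regfit: target %s, strategy %s>\n", x$target, x$strategy))
  for (lv in x$levels) {
    m <- x$models[[lv]]
    if (is.null(m)) cat(sprintf("  %s: no model (empty consensus)\n", lv))
    else cat(sprintf("  %s: k = %d, R^2 = %.3f, adj. R^2 = %.3f, BIC = %.1f\n",
                     lv, m$k, m$r2, m$adj_r2, m$bic))
  }
  invisible(x)
}

#' @export
summary.regfit <- function(object, ...) {
  rows <- lapply(object$levels, function(lv) {
    m <- object$models[[lv]]
    if (is.null(m))
      data.frame(target = object$target, level = lv, k = 0L, r2 = NA_real_,
                 adj_r2 = NA_real_, bic = NA_real_, n_significant = 0L)
    else
      data.frame(target = object$target, level = lv, k = m$k, r2 = m$r2,
                 adj_r2 = m$adj_r2, bic = m$bic,
                 n_significant = sum(m$significant))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.regfit", "data.frame")
  out
}

#' @export
coef.regfit <- function(object, level = NULL, ...) {
  level <- level %||% last_modeled_level(object)
  if (is.null(level)) return(NULL)
  m <- object$models[[level]]
  if (is.null(m)) NULL else coef(m)
}

#' @export
predict.regfit <- function(object, newdata = NULL, level = NULL, ...) {
  level <- level %||% last_modeled_level(object)
  if (is.null(level) || is.null(object$models[[level]]))
    stop("no model at the requested level")
  predict(object$models[[level]], newdata = newdata)
}

#' @export
residuals.regfit <- function(object, level = NULL, ...) {
  level <- level %||% last_modeled_level(object)
  if (is.null(level) || is.null(object$models[[level]]))
    stop("no model at the requested level")
  residuals(object$models[[level]])
}

#' @export
plot.regfit <- function(x, level = NULL, ...) {
  level <- level %||% last_modeled_level(x)
  if (is.null(level) || is.null(x$models[[level]]))
    stop("no model at the requested level")
  plot(x$models[[level]], ...)
}

#' Fit regulation models for every target gene of a cohort
#'
#' Builds the nested candidate matrices for each target, draws one shared
#' fold partition, and runs [regfit()] per target.
#'
#' @param cohort a `reg_cohort` (see [make_cohort()], [read_cohort()],
#'   [simulate_cohort()]).
#' @param targets target gene symbols (default: the cohort's target list).
#' @param seed partition seed (default 0), shared by all genes of the run.
#' @param ... passed to [regfit()] (`strategy`, `levels`, `max_k`, ...).
#' @return object of class `cohort_fit`: named list of `regfit` in `$fits`,
#'   plus the partition.
#' @export
fit_cohort <- function(cohort, targets = NULL, seed = 0L, ...) {
  stopifnot(inherits(cohort, "reg_cohort"))
  targets <- targets %||% cohort$targets
  partition <- cv_partition(cohort$samples, seed = seed)
  fits <- lapply(targets, function(tg) {
    mats <- build_matrices(tg, cohort$gene_sets, cohort$expression,
                           cohort$methyl, cohort$tf_map)
    regfit(mats, partition, ...)
  })
  names(fits) <- targets
  structure(list(fits = fits, partition = partition, seed = seed),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("<cohort_fit: %d targets (partition seed %d)>\n",
              length(x$fits), x$seed))
  invisible(x)
}

#' Tabulate model quality across targets and levels
#'
#' One row per target and analysis level with fit statistics; genes whose
#' consensus is empty at a level appear as "no model" rows (`k = 0`).
#' Models whose adjusted R^2 exceeds `threshold` are flagged as good fits.
#'
#' @param fits a `cohort_fit` or list of `regfit`.
#' @param threshold adjusted-R^2 acceptance threshold (default 0.6).
#' @return `data.frame` with columns `target`, `level`, `k`, `r2`,
#'   `adj_r2`, `bic`, `n_significant`, `good_fit`.
#' @export
summarize_models <- function(fits, threshold = 0.6) {
  if (inherits(fits, "cohort_fit")) fits <- fits$fits
  tab <- do.call(rbind, lapply(fits, summary))
  tab$good_fit <- !is.na(tab$adj_r2) & tab$adj_r2 > threshold
  rownames(tab) <- NULL
  as.data.frame(tab)
}

#' Benchmark the five selection strategies on one cohort
#'
#' Runs every strategy on the same targets under the same fold partition and
#' reports, per strategy, the number of target genes with a model (non-empty
#' final feature set), the total number of selected features, and the mean
#' BIC of the final models (each final set refitted by OLS on all samples at
#' the widest analysis level).
#'
#' @param cohort a `reg_cohort`.
#' @param targets target genes (default: the cohort's target list).
#' @param strategies strategies to compare (default: all five).
#' @param seed shared partition seed.
#' @param levels analysis levels (default M2, M3, M5).
#' @param ... passed to [regfit()].
#' @return `data.frame` with one row per strategy: `strategy`, `n_models`,
#'   `n_features`, `mean_bic`.
#' @export
compare_selection <- function(cohort, targets = NULL,
                              strategies = selection_strategies(),
                              seed = 0L,
                              levels = c("M2", "M3", "M5"), ...) {
  stopifnot(inherits(cohort, "reg_cohort"))
  targets <- targets %||% cohort$targets
  partition <- cv_partition(cohort$samples, seed = seed)
  mats <- lapply(targets, function(tg)
    build_matrices(tg, cohort$gene_sets, cohort$expression,
                   cohort$methyl, cohort$tf_map))
  names(mats) <- targets
  rows <- lapply(strategies, function(strat) {
    n_features <- 0L; n_models <- 0L; bics <- numeric(0)
    fits <- list()
    for (tg in targets) {
      fit <- regfit(mats[[tg]], partition, strategy = strat,
                    levels = levels, ...)
      fits[[tg]] <- fit
      feats <- fit$selection$final
      n_features <- n_features + length(feats)
      if (length(feats)) {
        n_models <- n_models + 1L
        wide <- fit$matrices[[levels[length(levels)]]]
        m <- fit_ols(wide$values[, feats, drop = FALSE],
                     unname(wide$response), target = tg)
        bics <- c(bics, m$bic)
      }
    }
    data.frame(strategy = strat, n_models = n_models,
               n_features = n_features,
               mean_bic = if (length(bics)) mean(bics) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
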