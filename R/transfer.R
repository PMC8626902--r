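# Cross-cohort model transfer: apply a fitted model, with its coefficients
# unchanged, to an independent cohort and score the fit there.

#' Apply a fitted regulation model to another cohort
#'
#' Predicts the target's expression in cohort B as
#' \eqn{\widehat{EXPR}_g = c_1 v_{f1} + \dots + c_n v_{fn}} using the source
#' coefficients unchanged (plus the source intercept), where the
#' \eqn{v_{fi}} are the z-scored feature values in B (z-scoring is always
#' within-cohort).  The transferred fit is scored by
#' \eqn{R^2 = 1 - \sum (obs - pred)^2 / \sum (obs - \overline{obs})^2}
#' against the observed z-scored expression in B; negative values are
#' possible and reported as computed.
#'
#' @param model a `reg_model` (or `regfit`, from which the model at `level`
#'   is taken).
#' @param newdata z-scored feature matrix of cohort B (samples x features).
#' @param observed z-scored observed expression of the target in B.
#' @param drop_missing if `FALSE` (default) a model feature absent from
#'   `newdata` is an error; if `TRUE` it is omitted from the prediction and
#'   listed in `missing_features`.
#' @param level analysis level when `model` is a `regfit`.
#' @return object of class `transfer_prediction` with `predicted`,
#'   `observed`, `r2`, `adj_r2`, `missing_features`.
#' @export
apply_model <- function(model, newdata, observed, drop_missing = FALSE,
                        level = NULL) {
  if (inherits(model, "regfit")) {
    level <- level %||% last_modeled_level(model)
    model <- model$models[[level]]
    if (is.null(model)) stop("no model at the requested level")
  }
  if (inherits(newdata, "feature_matrix")) {
    observed <- unname(newdata$response)
    newdata <- newdata$values
  }
  newdata <- as.matrix(newdata)
  feats <- model$features
  missing <- setdiff(feats, colnames(newdata))
  if (length(missing) && !drop_missing)
    stop("feature(s) absent from the target cohort: ",
         paste(missing, collapse = ", "), " (use drop_missing = TRUE to omit)")
  used <- setdiff(feats, missing)
  pred <- model$intercept +
    drop(newdata[, used, drop = FALSE] %*% model$coefficients[used])
  rss <- sum((observed - pred)^2)
  tss <- sum((observed - mean(observed))^2)
  r2 <- 1 - rss / tss
  n <- length(observed)
  structure(list(target = model$target, source_model = model,
                 predicted = pred, observed = observed,
                 r2 = r2,
                 adj_r2 = adjusted_r2(r2, n, length(feats)),
                 n = n, missing_features = missing),
            class = "transfer_prediction")
}

#' @export
print.transfer_prediction <- function(x, ...) {
  cat(sprintf("<transfer_prediction: target %s, n = %d, R^2 = %.4f, adj. R^2 = %.4f>\n",
              x$target %||% "?", x$n, x$r2, x$adj_r2))
  if (length(x$missing_features))
    cat("  missing features:", paste(x$missing_features, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize cross-cohort transfers and flag similarly regulated genes
#'
#' A gene is flagged "similarly regulated" when its source-model adjusted
#' R^2 reaches `adj_r2_floor` and the adjusted R^2 in the two cohorts agree
#' within `delta`.
#'
#' @param predictions named list of `transfer_prediction` (one per target).
#' @param source_fits the matching source models (`cohort_fit` or list of
#'   `reg_model`/`regfit`); used for the source adjusted R^2.
#' @param adj_r2_floor source-quality floor (default 0.4).
#' @param delta maximum |adj R^2(A) - adj R^2(B)| (default 0.1).
#' @param level analysis level for `regfit` sources.
#' @return `data.frame`: `target`, `adj_r2_source`, `adj_r2_target`,
#'   `similarly_regulated`, `missing_features`.
#' @export
transfer_report <- function(predictions, source_fits, adj_r2_floor = 0.4,
                            delta = 0.1, level = NULL) {
  if (inherits(source_fits, "cohort_fit")) source_fits <- source_fits$fits
  rows <- lapply(names(predictions), function(tg) {
    pr <- predictions[[tg]]
    src <- source_fits[[tg]]
    if (inherits(src, "regfit")) {
      lv <- level %||% last_modeled_level(src)
      src <- src$models[[lv]]
    }
    a <- src$adj_r2; b <- pr$adj_r2
    data.frame(target = tg, adj_r2_source = a, adj_r2_target = b,
               similarly_regulated = a >= adj_r2_floor & abs(a - b) <= delta,
               missing_features = paste(pr$missing_features, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transfer every fitted model of a cohort fit to another cohort
#'
#' Convenience wrapper: builds the per-target candidate matrices of the
#' target cohort, z-scores them within that cohort, applies each source
#' model unchanged, and reports.
#'
#' @param source_fit a `cohort_fit` from the source cohort.
#' @param cohort_b the target `reg_cohort`.
#' @param level analysis level (default `"M5"`).
#' @param drop_missing passed to [apply_model()].
#' @param adj_r2_floor,delta passed to [transfer_report()].
#' @return list with `predictions` and the `report` table.
#' @export
transfer_fit <- function(source_fit, cohort_b, level = "M5",
                         drop_missing = FALSE, adj_r2_floor = 0.4,
                         delta = 0.1) {
  stopifnot(inherits(source_fit, "cohort_fit"), inherits(cohort_b, "reg_cohort"))
  preds <- list()
  for (tg in names(source_fit$fits)) {
    src <- source_fit$fits[[tg]]
    if (is.null(src$models[[level]])) next
    mats <- build_matrices(tg, cohort_b$gene_sets, cohort_b$expression,
                           cohort_b$methyl, cohort_b$tf_map)
    fm <- zscore(handle_missing(mats))[[level]]
    preds[[tg]] <- apply_model(src$models[[level]], fm$values,
                               unname(fm$response),
                               drop_missing = drop_missing)
  }
  list(predictions = preds,
       report = transfer_report(preds, source_fit$fits,
                                adj_r2_floor = adj_r2_floor, delta = delta,
                                level = level))
}
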