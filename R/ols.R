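#' Z-score normalization
#'
#' Centers every column to mean 0 and scales to sample variance 1
#' (denominator \eqn{n-1}).  Applied to a `feature_matrix`, both the
#' predictor columns and the response are normalized, so that fitted
#' coefficients are standardized effects comparable across models.
#'
#' @param x numeric matrix/vector or a `feature_matrix`.
#' @param ... unused.
#' @return object of the same shape.
#' @export
zscore <- function(x, ...) UseMethod("zscore")

#' @export
zscore.default <- function(x, ...) {
  if (is.null(dim(x))) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop("constant column cannot be z-scored")
    return((x - mean(x)) / s)
  }
  s <- apply(x, 2, sd)
  bad <- !is.finite(s) | s == 0
  if (any(bad))
    stop("constant column(s) cannot be z-scored: ",
         paste(colnames(x)[bad] %||% which(bad), collapse = ", "))
  scale(x, center = TRUE, scale = s)[, , drop = FALSE]
}

#' @export
zscore.feature_matrix <- function(x, ...) {
  vals <- if (ncol(x$values)) zscore.default(x$values) else x$values
  resp <- zscore.default(unname(x$response))
  new_feature_matrix(x$target, x$level, x$samples, resp, x$features, vals)
}

#' @export
zscore.feature_matrix_set <- function(x, ...) {
  out <- lapply(x, zscore)
  structure(out, class = "feature_matrix_set", target = attr(x, "target"))
}

#' Adjusted coefficient of determination
#'
#' \eqn{1 - (1 - R^2)(n - 1)/(n - k - 1)}: the fit quality penalized for the
#' number of fitted features relative to the sample size.
#'
#' @param r2 unadjusted R^2.
#' @param n sample count.
#' @param k feature count (intercept excluded).
#' @return adjusted R^2.
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("adjusted R^2 undefined for n <= k + 1")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Bayesian information criterion of a Gaussian linear model
#'
#' Computed as \eqn{n \ln(RSS/n) + p \ln(n)} with \eqn{p = k + 1} (the
#' intercept counts as a parameter); additive constants are omitted, so
#' only differences between models on the same data are meaningful.  Lower
#' is better.
#'
#' @param n sample count.
#' @param rss residual sum of squares.
#' @param k feature count (intercept excluded).
#' @return the BIC value; `-Inf` with a warning when `rss` is zero.
#' @export
bic_score <- function(n, rss, k) {
  if (rss <= 0) {
    warning("RSS is zero; BIC reported as -Inf")
    return(-Inf)
  }
  n * log(rss / n) + (k + 1) * log(n)
}

#' Fit an ordinary-least-squares regulation model
#'
#' Fits `y ~ 1 + x` by OLS and attaches 95% confidence intervals
#' (t-distribution, \eqn{df = n - k - 1}) per coefficient.  A feature is
#' significant when its confidence interval excludes zero; the intercept is
#' fitted (numerically near zero on z-scored data) but never tested.
#'
#' @param x numeric matrix of selected features (samples x k, k >= 1),
#'   typically z-scored.
#' @param y numeric response aligned with `x`, typically z-scored.
#' @param target,level optional labels stored in the model.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return object of class `reg_model` with coefficients, standard errors,
#'   confidence bounds, significance flags, `r2`, `adj_r2`, `bic`, `n`, `k`.
#' @export
fit_ols <- function(x, y, target = NULL, level = NULL, conf_level = 0.95) {
  x <- as.matrix(x)
  n <- length(y)
  k <- ncol(x)
  if (k < 1L) stop("fit_ols() needs at least one feature")
  if (nrow(x) != n) stop("x and y have different sample counts")
  if (n <= k + 1L) stop("too few samples (", n, ") for ", k, " features")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(k))
  X <- cbind(`(Intercept)` = 1, x)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("design is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("response is constant")
  if (rss < 1e-12 * tss) rss <- 0       # exact fit up to rounding
  r2 <- 1 - rss / tss
  df <- n - k - 1L
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot)]
  se <- setNames(sqrt(pmax(diag(xtx_inv) * sigma2, 0)), colnames(X))
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  ci_low <- beta - tcrit * se
  ci_high <- beta + tcrit * se
  feat <- colnames(x)
  sig <- ci_low[feat] > 0 | ci_high[feat] < 0
  structure(list(
    target = target, level = level, features = feat,
    coefficients = beta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    significant = setNames(as.logical(sig), feat),
    intercept = unname(beta[1L]),
    r2 = r2, adj_r2 = adjusted_r2(r2, n, k),
    bic = suppressWarnings(bic_score(n, rss, k)),
    rss = rss, sigma = sqrt(sigma2), n = n, k = k, df = df,
    conf_level = conf_level,
    fitted.values = fitted, residuals = res, x = x, y = y),
    class = "reg_model")
}

#' @export
print.reg_model <- function(x, digits = 4, ...) {
  cat(sprintf("OLS regulation model%s%s: n = %d, k = %d\n",
              if (is.null(x$target)) "" else paste0(" for ", x$target),
              if (is.null(x$level)) "" else paste0(" [", x$level, "]"),
              x$n, x$k))
  cat(sprintf("R^2 = %.*f, adjusted R^2 = %.*f, BIC = %.*f\n",
              digits, x$r2, digits, x$adj_r2, digits, x$bic))
  print(coef_table(x), digits = digits)
  invisible(x)
}

coef_table <- function(m) {
  data.frame(coefficient = m$coefficients,
             ci_low = m$ci_low, ci_high = m$ci_high,
             significant = c(NA, m$significant[m$features]),
             row.names = names(m$coefficients))
}

#' @export
summary.reg_model <- function(object, ...) {
  out <- list(model = object, table = coef_table(object))
  class(out) <- "summary.reg_model"
  out
}

#' @export
print.summary.reg_model <- function(x, ...) {
  print(x$model, ...)
  invisible(x)
}

#' @export
coef.reg_model <- function(object, ...) object$coefficients

#' @export
confint.reg_model <- function(object, parm, level = 0.95, ...) {
  ci <- cbind(low = object$ci_low, high = object$ci_high)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.reg_model <- function(object, ...) object$residuals

#' @export
fitted.reg_model <- function(object, ...) object$fitted.values

#' @export
predict.reg_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop("feature(s) absent from newdata: ", paste(missing, collapse = ", "))
  drop(object$intercept +
         newdata[, object$features, drop = FALSE] %*%
         object$coefficients[object$features])
}

#' @export
simulate.reg_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  as.data.frame(replicate(nsim, mu + rnorm(object$n, sd = object$sigma)))
}

#' @export
plot.reg_model <- function(x, ...) {
  feat <- x$features
  est <- x$coefficients[feat]
  lo <- x$ci_low[feat]; hi <- x$ci_high[feat]
  ord <- order(est)
  old <- par(mar = c(4, 9, 2, 1)); on.exit(par(old))
  plot(est[ord], seq_along(feat), xlim = range(c(lo, hi, 0)),
       yaxt = "n", xlab = "standardized coefficient (95% CI)", ylab = "",
       pch = 19, main = paste0(x$target %||% "", " ", x$level %||% ""), ...)
  axis(2, at = seq_along(feat), labels = feat[ord], las = 2, cex.axis = 0.8)
  segments(lo[ord], seq_along(feat), hi[ord], seq_along(feat))
  abline(v = 0, lty = 2)
  invisible(x)
}
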