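# Fold-wise feature selection.
#
# The reference strategy is incremental forward feature selection with
# re-evaluation: candidate matrices are visited in their nesting order
# (M2, M3, M5 by default); at each step the candidate pool is the group of
# new columns plus the consensus of the previous step, so previously chosen
# features must compete again.  Within each cross-validation fold a greedy
# path is grown by adding, at each size, the candidate whose OLS fit on the
# training part maximizes R^2 on the held-out part; the fold subset is the
# path prefix with maximal held-out R^2.  Only features chosen in all five
# folds form the step consensus.

#' Greedy forward selection within one cross-validation fold
#'
#' At each size the candidate whose ordinary-least-squares fit on the
#' training samples gives the highest R^2 on the held-out samples is added;
#' ties are broken lexicographically by feature name.  The path stops at
#' `max_k` features (or when all candidates are used); the returned subset
#' is the path prefix with maximal held-out R^2.  Candidates that would make
#' the training design singular are skipped at that size.
#'
#' @param x numeric matrix (samples x features), candidate columns named.
#' @param y numeric response aligned with `x` rows.
#' @param train,test integer row indices of the training and held-out
#'   samples.
#' @param max_k maximum path length; must satisfy `length(train) > max_k + 2`.
#' @param candidates candidate column names (default: all columns of `x`).
#' @return list with `path` (ordered feature names), `path_r2` (held-out
#'   R^2 per prefix) and `best_subset`.
#' @export
forward_select_fold <- function(x, y, train, test, max_k,
                                candidates = colnames(x)) {
  if (length(candidates) == 0L) stop("no candidate features")
  if (length(train) <= max_k + 2L)
    stop("training fold too small (", length(train),
         ") for max_k = ", max_k)
  cand <- sort(candidates)
  p <- length(cand)
  Xtr <- cbind(1, x[train, cand, drop = FALSE])
  Xte <- cbind(1, x[test, cand, drop = FALSE])
  ytr <- y[train]; yte <- y[test]
  G <- crossprod(Xtr)                 # (p+1) x (p+1) training Gram
  h <- drop(crossprod(Xtr, ytr))
  Gte <- crossprod(Xte)
  hte <- drop(crossprod(Xte, yte))
  yte2 <- sum(yte^2)
  sst <- sum((yte - mean(yte))^2)
  if (sst <= 0) stop("held-out response is constant; R^2 undefined")
  scale_d <- sqrt(diag(G))

  solve_idx <- function(idx) {
    R <- tryCatch(suppressWarnings(chol(G[idx, idx, drop = FALSE])),
                  error = function(e) NULL)
    if (is.null(R) || any(diag(R) < 1e-7 * scale_d[idx])) return(NULL)
    backsolve(R, forwardsolve(t(R), h[idx]))
  }
  r2_test <- function(idx, beta) {
    rss <- yte2 - 2 * sum(beta * hte[idx]) +
      drop(crossprod(beta, Gte[idx, idx, drop = FALSE] %*% beta))
    1 - rss / sst
  }

  selected <- integer(0)
  path <- character(0)
  path_r2 <- numeric(0)
  remaining <- seq_len(p)
  steps <- min(max_k, p)
  for (size in seq_len(steps)) {
    best_j <- NA_integer_; best_r2 <- -Inf; best_beta <- NULL
    for (j in remaining) {           # lexicographic order; strict > keeps first
      idx <- c(1L, selected + 1L, j + 1L)
      beta <- solve_idx(idx)
      if (is.null(beta)) next
      r2 <- r2_test(idx, beta)
      if (r2 > best_r2) { best_r2 <- r2; best_j <- j; best_beta <- beta }
    }
    if (is.na(best_j)) break          # every remaining candidate singular
    selected <- c(selected, best_j)
    remaining <- setdiff(remaining, best_j)
    path <- c(path, cand[best_j])
    path_r2 <- c(path_r2, best_r2)
  }
  if (length(path) == 0L)
    return(list(path = character(0), path_r2 = numeric(0),
                best_subset = character(0)))
  best_len <- which.max(path_r2)
  list(path = path, path_r2 = path_r2,
       best_subset = path[seq_len(best_len)])
}

# Lasso selection within one fold: L1 path on the training part, penalty
# chosen to maximize held-out R^2 over a logarithmic grid; the fold subset
# is the set of features with nonzero coefficient at that penalty.
lasso_select_fold <- function(x, y, train, test, candidates = colnames(x),
                              lambda = NULL) {
  cand <- sort(candidates)
  Xtr <- x[train, cand, drop = FALSE]
  Xte <- x[test, cand, drop = FALSE]
  padded <- FALSE
  if (ncol(Xtr) < 2L) {               # glmnet requires >= 2 columns
    Xtr <- cbind(Xtr, `.pad.` = 0); Xte <- cbind(Xte, `.pad.` = 0)
    padded <- TRUE
  }
  fit <- glmnet::glmnet(Xtr, y[train], alpha = 1, lambda = lambda,
                        standardize = TRUE)
  pred <- predict(fit, newx = Xte)
  yte <- y[test]
  sst <- sum((yte - mean(yte))^2)
  r2 <- 1 - colSums((yte - pred)^2) / sst
  best <- which.max(r2)
  beta <- as.matrix(fit$beta)[, best]
  sel <- names(beta)[beta != 0]
  if (padded) sel <- setdiff(sel, ".pad.")
  list(path = sel, path_r2 = rep(r2[best], length(sel)),
       best_subset = sel, lambda = fit$lambda[best])
}

selection_strategies <- function() {
  c("incr_ffs_reeval", "incr_ffs_noreeval", "ffs_all",
    "incr_lasso_reeval", "lasso_all")
}

fold_indices <- function(fm, partition) {
  lapply(partition$folds, function(f) which(fm$samples %in% f))
}

default_max_k <- function(n, k_folds = 5L) {
  n_train_min <- n - ceiling(n / k_folds)
  max(1L, min(30L, n_train_min %/% 10L))
}

run_fold_selection <- function(fm, folds, candidates, method, max_k, lambda) {
  all_idx <- seq_along(fm$samples)
  lapply(folds, function(test_idx) {
    train_idx <- setdiff(all_idx, test_idx)
    if (method == "ffs")
      forward_select_fold(fm$values, fm$response, train_idx, test_idx,
                          max_k = max_k, candidates = candidates)
    else
      lasso_select_fold(fm$values, fm$response, train_idx, test_idx,
                        candidates = candidates, lambda = lambda)
  })
}

consensus_of <- function(per_fold) {
  sets <- lapply(per_fold, `[[`, "best_subset")
  sort(Reduce(intersect, sets))
}

#' Select candidate regulators across the nested matrix sequence
#'
#' Runs one of the five selection strategies on a nested sequence of
#' candidate matrices under a shared fold partition:
#' \describe{
#'   \item{`incr_ffs_reeval`}{incremental forward selection with
#'     re-evaluation: step-\eqn{k} candidates are the new column group plus
#'     the previous step's consensus (the reference strategy).}
#'   \item{`incr_ffs_noreeval`}{as above, but each step sees only the new
#'     group; earlier consensus features are appended to the final set
#'     without re-competition.}
#'   \item{`ffs_all`}{a single forward-selection step over all columns of
#'     the last matrix.}
#'   \item{`incr_lasso_reeval`}{the incremental scheme with fold-wise lasso
#'     instead of forward selection.}
#'   \item{`lasso_all`}{a single lasso step over all columns of the last
#'     matrix.}
#' }
#' In every case the fold subsets are combined by strict intersection: only
#' features selected in all folds survive a step.  An empty consensus is
#' allowed (the gene has no model at that step and nothing is carried on).
#'
#' @param matrices a `feature_matrix_set` (or named list of
#'   `feature_matrix`) already restricted to the analysis levels, in order
#'   (default analysis sequence M2, M3, M5).
#' @param partition a [cv_partition()].
#' @param strategy one of [selection_strategies()].
#' @param max_k maximal forward-selection path length per fold; default
#'   `min(30, floor(n_train/10))`.
#' @param levels names of the matrices to analyse, in nesting order.
#' @param lambda optional explicit lasso penalty grid.
#' @param consensus_min minimum number of folds that must agree for a
#'   feature to enter the consensus (default: all folds).
#' @return object of class `selection_result` with one entry per step
#'   (`level`, `candidates`, `per_fold`, `consensus`, `carried`) and the
#'   strategy's `final` feature set.
#' @export
select_features <- function(matrices, partition,
                            strategy = selection_strategies(),
                            max_k = NULL,
                            levels = intersect(c("M2", "M3", "M5"),
                                               names(matrices)),
                            lambda = NULL, consensus_min = NULL) {
  strategy <- match.arg(strategy)
  mats <- matrices[levels]
  if (any(vapply(mats, is.null, logical(1))))
    stop("requested levels absent from 'matrices'")
  target <- mats[[1L]]$target
  n <- length(mats[[1L]]$samples)
  if (is.null(max_k)) max_k <- default_max_k(n, partition$k)
  folds <- fold_indices(mats[[1L]], partition)
  if (any(lengths(folds) == 0L)) stop("a fold has no sample in the matrix")
  cons_n <- consensus_min %||% partition$k
  consensus_fun <- function(per_fold) {
    if (cons_n >= partition$k) return(consensus_of(per_fold))
    feats <- sort(unique(unlist(lapply(per_fold, `[[`, "best_subset"))))
    hits <- vapply(feats, function(f)
      sum(vapply(per_fold, function(pf) f %in% pf$best_subset, logical(1))),
      integer(1))
    feats[hits >= cons_n]
  }
  method <- if (grepl("lasso", strategy)) "lasso" else "ffs"

  steps <- list()
  if (strategy %in% c("ffs_all", "lasso_all")) {
    fm <- mats[[length(mats)]]
    per_fold <- run_fold_selection(fm, folds, fm$features$name, method,
                                   max_k, lambda)
    cons <- consensus_fun(per_fold)
    steps[[fm$level]] <- list(level = fm$level,
                              candidates = sort(fm$features$name),
                              per_fold = per_fold, consensus = cons,
                              carried = character(0))
    final <- cons
  } else {
    reeval <- grepl("reeval$", strategy) && !grepl("noreeval", strategy)
    prev_cols <- character(0)
    carried <- character(0)
    unioned <- character(0)
    for (i in seq_along(mats)) {
      fm <- mats[[i]]
      new_group <- setdiff(fm$features$name, prev_cols)
      candidates <- if (reeval) union(new_group, carried) else new_group
      if (length(candidates) == 0L) {
        steps[[fm$level]] <- list(level = fm$level, candidates = character(0),
                                  per_fold = NULL,
                                  consensus = if (reeval) carried else character(0),
                                  carried = carried)
        prev_cols <- fm$features$name
        next
      }
      per_fold <- run_fold_selection(fm, folds, candidates, method,
                                     max_k, lambda)
      cons <- consensus_fun(per_fold)
      steps[[fm$level]] <- list(level = fm$level,
                                candidates = sort(candidates),
                                per_fold = per_fold, consensus = cons,
                                carried = carried)
      if (reeval) {
        carried <- cons
      } else {
        unioned <- union(unioned, cons)
        carried <- cons
      }
      prev_cols <- fm$features$name
    }
    final <- if (reeval) carried else sort(unioned)
  }
  structure(list(target = target, strategy = strategy, steps = steps,
                 final = sort(final), max_k = max_k,
                 seed = partition$seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: target %s, strategy %s>\n",
              x$target, x$strategy))
  for (st in x$steps)
    cat(sprintf("  %s: %d candidates -> consensus {%s}\n", st$level,
                length(st$candidates), paste(st$consensus, collapse = ", ")))
  cat(sprintf("  final: {%s}\n", paste(x$final, collapse = ", ")))
  invisible(x)
}

#' Per-step consensus feature sets at each analysis level
#'
#' For the re-evaluating strategies this is each step's consensus; for the
#' non-re-evaluating incremental strategy the features accumulated up to
#' each step; for the single-step strategies only the last level is
#' populated.
#'
#' @param selection a `selection_result`.
#' @return named list level -> character vector.
#' @export
level_feature_sets <- function(selection) {
  out <- list()
  if (selection$strategy == "incr_ffs_noreeval") {
    acc <- character(0)
    for (st in selection$steps) {
      acc <- union(acc, st$consensus)
      out[[st$level]] <- sort(acc)
    }
  } else {
    for (st in selection$steps) out[[st$level]] <- sort(st$consensus)
  }
  out
}
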