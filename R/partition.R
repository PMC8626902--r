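#' Shared fivefold sample partition
#'
#' Randomly splits the samples into five (possibly equal) disjoint groups;
#' fold sizes differ by at most one.  The same partition is reused for every
#' target gene, analysis step and selection strategy of a run, so that fold
#' consensus is comparable across genes.
#'
#' @param samples character vector of sample identifiers (>= 10).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @param k number of folds (default 5).
#' @return object of class `cv_partition`: list with `seed`, `k` and
#'   `folds` (list of `k` character vectors).
#' @export
cv_partition <- function(samples, seed = 0L, k = 5L) {
  n <- length(samples)
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (n < 2L * k) stop("need at least ", 2L * k, " samples for ", k,
                       "-fold selection, got ", n)
  perm <- with_seed(derive_seed(seed, "partition"), sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- split(samples[perm], rep(seq_len(k), times = sizes))
  names(folds) <- paste0("fold", seq_len(k))
  structure(list(seed = as.integer(seed), k = k, folds = folds),
            class = "cv_partition")
}

#' @export
print.cv_partition <- function(x, ...) {
  cat(sprintf("<cv_partition: %d folds of sizes %s (seed %d)>\n", x$k,
              paste(lengths(x$folds), collapse = "/"), x$seed))
  invisible(x)
}
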