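# Shared fixtures: tiny file-based inputs and in-code simulated instances.

write_tiny_gtf <- function(lines = NULL) {
  path <- tempfile(fileext = ".gtf")
  if (is.null(lines)) lines <- c(
    paste0("chr1\ttest\ttranscript\t1001\t5000\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "G1.t1"; gene_name "g1";'),
    paste0("chr1\ttest\ttranscript\t1001\t5000\t.\t-\t.\t",
           'gene_id "G2"; transcript_id "G2.t1"; gene_name "g2";'),
    # second transcript of g1 sharing the same TSS
    paste0("chr1\ttest\ttranscript\t1001\t6000\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "G1.t2"; gene_name "g1";'))
  writeLines(lines, path)
  path
}

make_annotation <- function(gene, chrom = "chr1", strand = "+", tss) {
  ann <- data.frame(gene = gene, chrom = chrom, strand = strand, tss = tss,
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

# A minimal in-memory cohort: two sets, explicit tf_map, no files involved.
toy_matrices <- function(target = "g1",
                         sets = list(A = c("g1", "g2"), B = "g3"),
                         tf_map = list(g1 = "t1", g2 = "t2", g3 = "t3"),
                         n = 20, seed = 42) {
  genes <- unique(c(unlist(sets), unlist(tf_map)))
  set.seed(seed)
  expr <- matrix(rnorm(n * length(genes)), n,
                 dimnames = list(sprintf("s%02d", 1:n), genes))
  meth <- matrix(runif(n * length(unlist(sets))), n,
                 dimnames = list(rownames(expr), unlist(sets)))
  build_matrices(target, sets, expr, meth, tf_map)
}

# Random regression instance with planted coefficients.
sim_instance <- function(n, coefs, n_noise, noise_sd, seed) {
  set.seed(seed)
  k <- length(coefs) + n_noise
  x <- matrix(rnorm(n * k), n,
              dimnames = list(NULL, sprintf("x%02d", seq_len(k))))
  y <- drop(x[, seq_along(coefs), drop = FALSE] %*% coefs) +
    rnorm(n, sd = noise_sd)
  list(x = x, y = y, true_features = colnames(x)[seq_along(coefs)])
}

# Independent brute-force greedy forward selection: refits with lm() from
# scratch at every step and scores on the held-out samples.  Deliberately
# naive; the oracle for the fast Gram-based implementation.
bruteforce_greedy <- function(x, y, train, test, max_k) {
  cand <- sort(colnames(x))
  chosen <- character(0)
  path <- character(0); path_r2 <- numeric(0)
  for (size in seq_len(min(max_k, length(cand)))) {
    best <- NULL; best_r2 <- -Inf
    for (f in setdiff(cand, chosen)) {
      df_tr <- data.frame(y = y[train], x[train, c(chosen, f), drop = FALSE],
                          check.names = FALSE)
      fit <- lm(y ~ ., data = df_tr)
      if (anyNA(coef(fit))) next
      pred <- predict(fit, data.frame(x[test, c(chosen, f), drop = FALSE],
                                      check.names = FALSE))
      r2 <- 1 - sum((y[test] - pred)^2) / sum((y[test] - mean(y[test]))^2)
      if (r2 > best_r2) { best_r2 <- r2; best <- f }
    }
    if (is.null(best)) break
    chosen <- c(chosen, best)
    path <- c(path, best); path_r2 <- c(path_r2, best_r2)
  }
  list(path = path, path_r2 = path_r2,
       best_subset = path[seq_len(which.max(path_r2))])
}

# Independent normal-equations OLS oracle with t-based confidence bounds.
ols_oracle <- function(x, y, conf = 0.95) {
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tc <- qt(1 - (1 - conf) / 2, df)
  list(beta = drop(beta), se = se,
       ci_low = drop(beta) - tc * se, ci_high = drop(beta) + tc * se,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}
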