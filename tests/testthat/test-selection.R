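test_that("fold sizes differ by at most one and are deterministic", {
  p <- cv_partition(sprintf("s%03d", 1:372), seed = 3)
  expect_equal(sort(unname(lengths(p$folds)), decreasing = TRUE),
               c(75, 75, 74, 74, 74))
  expect_setequal(unlist(p$folds), sprintf("s%03d", 1:372))
  p10 <- cv_partition(sprintf("s%02d", 1:10), seed = 3)
  expect_equal(unname(lengths(p10$folds)), rep(2L, 5))
  expect_identical(cv_partition(sprintf("s%03d", 1:372), seed = 3), p)
  expect_false(identical(cv_partition(sprintf("s%03d", 1:372), seed = 4), p))
  expect_error(cv_partition(sprintf("s%d", 1:9), seed = 0), "at least 10")
})

test_that("greedy fold selection matches the brute-force oracle exactly", {
  set.seed(202)
  for (i in 1:10) {
    k_true <- sample(0:3, 1)
    coefs <- if (k_true) runif(k_true, 0.3, 1) * sample(c(-1, 1), k_true, TRUE)
             else numeric(0)
    inst <- sim_instance(n = 60, coefs = coefs,
                         n_noise = sample(3:8, 1) - k_true + 3,
                         noise_sd = runif(1, 0.3, 1), seed = 1000 + i)
    test_idx <- sample(60, 12)
    train_idx <- setdiff(1:60, test_idx)
    mine <- forward_select_fold(inst$x, inst$y, train_idx, test_idx, max_k = 6)
    oracle <- bruteforce_greedy(inst$x, inst$y, train_idx, test_idx, max_k = 6)
    expect_identical(mine$path, oracle$path)
    expect_identical(mine$best_subset, oracle$best_subset)
    expect_equal(mine$path_r2, oracle$path_r2, tolerance = 1e-10)
    # consensus is a subset of every fold subset by construction
    expect_true(all(mine$best_subset %in% mine$path))
  }
})

test_that("a planted two-regulator signal heads the path; fold consensus prunes chance extras", {
  inst <- sim_instance(n = 200, coefs = c(2, -3), n_noise = 6,
                       noise_sd = 0.3, seed = 99)
  sel <- forward_select_fold(inst$x, inst$y, train = 1:160, test = 161:200,
                             max_k = 8)
  # the two real regulators are picked first and always kept
  expect_setequal(sel$path[1:2], inst$true_features)
  expect_true(all(inst$true_features %in% sel$best_subset))
  # chance extras in single folds do not survive the 5-fold intersection
  part <- cv_partition(sprintf("s%03d", 1:200), seed = 1)
  folds <- lapply(part$folds, function(f) match(f, sprintf("s%03d", 1:200)))
  subsets <- lapply(folds, function(te)
    forward_select_fold(inst$x, inst$y, setdiff(1:200, te), te,
                        max_k = 8)$best_subset)
  expect_setequal(Reduce(intersect, subsets), inst$true_features)
})

test_that("a single candidate is selected as the length-one path", {
  inst <- sim_instance(n = 40, coefs = 1, n_noise = 0, noise_sd = 5, seed = 5)
  sel <- forward_select_fold(inst$x, inst$y, 1:30, 31:40, max_k = 5)
  expect_identical(sel$path, "x01")
  expect_identical(sel$best_subset, "x01")   # best over a length-1 path
})

test_that("exact ties break lexicographically by feature name", {
  x <- cbind(b = c(1, 2, 3, 4, 5, 6), a = c(1, 2, 3, 4, 5, 6))
  y <- c(1, 2, 3, 4, 5, 6)
  sel <- forward_select_fold(x, y, train = 1:4, test = 5:6, max_k = 1)
  expect_identical(sel$path, "a")
})

test_that("duplicate columns make the design singular and are skipped", {
  set.seed(8)
  x <- matrix(rnorm(120), 40)
  colnames(x) <- c("a", "b", "c")
  x <- cbind(x, a2 = x[, "a"])      # exact copy
  y <- x[, "a"] + rnorm(40, sd = 0.1)
  sel <- forward_select_fold(x, y, 1:30, 31:40, max_k = 4)
  expect_false(all(c("a", "a2") %in% sel$path))
})

test_that("incremental selection re-evaluates carried features with new groups", {
  # planted truth with one regulator in each analysis group
  co <- simulate_cohort(cohort_config(n_samples = 400, targets_per_set = 2,
                                      members_per_set = 4, n_tfs = 10,
                                      meth_frac = 0),
                        seed = 7)
  tg <- co$targets[1]
  mats <- build_matrices(tg, co$gene_sets, co$expression, co$methyl, co$tf_map)
  z <- zscore(handle_missing(mats))
  part <- cv_partition(co$samples, seed = 0)
  sel <- select_features(z, part, strategy = "incr_ffs_reeval")
  planted <- names(co$truth$models[[tg]]$coefficients)
  expect_true(all(planted %in% sel$final))
  # step-2 candidate pool = new M3 columns plus the step-1 consensus
  m2cols <- z$M2$features$name
  m3new <- setdiff(z$M3$features$name, m2cols)
  expect_setequal(sel$steps$M3$candidates,
                  union(m3new, sel$steps$M2$consensus))
  expect_identical(sel$steps$M3$carried, sel$steps$M2$consensus)
})

test_that("without re-evaluation, earlier selections are kept even if redundant", {
  # x2 = x1 + small noise; y depends on x1 only.  Step 1 sees only x2 (and
  # noise), step 2 adds x1: with no re-evaluation x2 must survive in the
  # final set even though x1 makes it redundant.
  set.seed(31)
  n <- 100
  x1 <- rnorm(n); x2 <- x1 + rnorm(n, sd = 0.5); x3 <- rnorm(n)
  y <- x1 + rnorm(n, sd = 0.2)
  samples <- sprintf("s%03d", 1:n)
  fm_small <- new_feature_matrix(
    "g", "M2", samples, y,
    data.frame(name = c("x2", "x3"), kind = "EXPR", provenance = "same_set_gene"),
    cbind(x2, x3))
  fm_big <- new_feature_matrix(
    "g", "M3", samples, y,
    data.frame(name = c("x2", "x3", "x1"), kind = "EXPR",
               provenance = "same_set_gene"),
    cbind(x2, x3, x1))
  part <- cv_partition(samples, seed = 1)
  mats <- structure(list(M2 = fm_small, M3 = fm_big),
                    class = "feature_matrix_set", target = "g")
  no_re <- select_features(zscore(mats), part, strategy = "incr_ffs_noreeval",
                           levels = c("M2", "M3"))
  expect_true("x2" %in% no_re$final)
  expect_true("x1" %in% no_re$final)   # both proxies retained, by definition
  re <- select_features(zscore(mats), part, strategy = "incr_ffs_reeval",
                        levels = c("M2", "M3"))
  # re-evaluation keeps only one of the two near-collinear proxies
  expect_equal(length(intersect(re$final, c("x1", "x2"))), 1L)
  expect_lte(length(re$final), length(no_re$final))
})

test_that("empty consensus carries nothing into the next step", {
  set.seed(17)
  n <- 80
  samples <- sprintf("s%03d", 1:n)
  # pure-noise small step 1 with many candidates rarely reaches consensus;
  # force it by making fold subsets disjoint via distinct noise columns
  x <- matrix(rnorm(n * 6), n, dimnames = list(samples, paste0("n", 1:6)))
  xb <- cbind(x, sig = rnorm(n))
  y <- xb[, "sig"] + rnorm(n, sd = 0.1)
  fm1 <- new_feature_matrix("g", "M2", samples, y,
                            data.frame(name = colnames(x), kind = "EXPR",
                                       provenance = "same_set_gene"), x)
  fm2 <- new_feature_matrix("g", "M3", samples, y,
                            data.frame(name = colnames(xb), kind = "EXPR",
                                       provenance = "same_set_gene"), xb)
  mats <- structure(list(M2 = fm1, M3 = fm2),
                    class = "feature_matrix_set", target = "g")
  part <- cv_partition(samples, seed = 2)
  sel <- select_features(zscore(mats), part, strategy = "incr_ffs_reeval",
                         levels = c("M2", "M3"))
  if (length(sel$steps$M2$consensus) == 0L) {
    expect_setequal(sel$steps$M3$candidates, "sig")
  } else {
    expect_setequal(sel$steps$M3$candidates,
                    union("sig", sel$steps$M2$consensus))
  }
})

test_that("lasso with an enormous penalty selects nothing", {
  mats <- toy_matrices(n = 50, seed = 3)
  part <- cv_partition(mats$M2$samples, seed = 0)
  sel <- select_features(zscore(handle_missing(mats)), part,
                         strategy = "lasso_all", lambda = c(1e6, 1e5))
  expect_identical(sel$final, character(0))
})

test_that("lasso recovers a strong planted signal on all features", {
  co <- simulate_cohort(cohort_config(n_samples = 400, targets_per_set = 2,
                                      members_per_set = 3, n_tfs = 8,
                                      meth_frac = 0),
                        seed = 11)
  tg <- co$targets[1]
  mats <- build_matrices(tg, co$gene_sets, co$expression, co$methyl, co$tf_map)
  z <- zscore(handle_missing(mats))
  part <- cv_partition(co$samples, seed = 0)
  sel <- select_features(z, part, strategy = "lasso_all")
  planted <- names(co$truth$models[[tg]]$coefficients)
  expect_true(all(planted %in% sel$final))
  sel2 <- select_features(z, part, strategy = "ffs_all")
  expect_true(all(planted %in% sel2$final))
  expect_identical(names(sel2$steps), "M5")
  expect_error(select_features(z, part, strategy = "nope"))
})
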