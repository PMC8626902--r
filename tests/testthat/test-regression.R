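test_that("z-scoring yields mean 0 and sample variance 1, and is idempotent", {
  expect_equal(unname(zscore(c(1, 2, 3))), c(-1, 0, 1))   # sd = 1
  set.seed(4)
  x <- matrix(rnorm(200, mean = 5, sd = 3), 50,
              dimnames = list(NULL, paste0("c", 1:4)))
  z <- zscore(x)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, var) - 1) < 1e-10))
  expect_equal(zscore(z), z, tolerance = 1e-12)            # idempotence
  x[, 2] <- 7
  expect_error(zscore(x), "c2")
})

test_that("OLS matches an independent normal-equations oracle", {
  set.seed(12)
  for (i in 1:10) {
    n <- 50; k <- 3
    x <- matrix(rnorm(n * k), n, dimnames = list(NULL, paste0("f", 1:k)))
    y <- drop(x %*% runif(k, -1, 1)) + rnorm(n)
    m <- fit_ols(x, y)
    o <- ols_oracle(x, y)
    expect_equal(unname(coef(m)), unname(o$beta), tolerance = 1e-8)
    expect_equal(unname(m$se), unname(o$se), tolerance = 1e-8)
    expect_equal(unname(m$ci_low), unname(o$ci_low), tolerance = 1e-8)
    expect_equal(unname(m$ci_high), unname(o$ci_high), tolerance = 1e-8)
    expect_equal(m$r2, o$r2, tolerance = 1e-10)
  }
})

test_that("noiseless single-feature fit is exact with zero-width intervals", {
  x <- matrix(seq(-2, 2, length.out = 20), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- 0.5 * x[, 1]
  m <- fit_ols(x, y)
  expect_equal(unname(coef(m)["f"]), 0.5)
  expect_equal(m$r2, 1)
  expect_equal(unname(m$se["f"]), 0)
  expect_true(m$significant[["f"]])
  expect_identical(m$bic, -Inf)      # RSS = 0 sentinel
})

test_that("rank-deficient designs fail naming the collinear column", {
  set.seed(3)
  x <- matrix(rnorm(60), 30, dimnames = list(NULL, c("a", "b")))
  x <- cbind(x, b_copy = x[, "b"])
  expect_error(fit_ols(x, rnorm(30)), "b_copy")
})

test_that("adjusted R^2 follows the closed form and its limits", {
  expect_equal(adjusted_r2(0.75, 101, 5), 1 - 0.25 * 100 / 95)
  expect_equal(adjusted_r2(0.75, 101, 5), 0.7368421, tolerance = 1e-6)
  expect_equal(adjusted_r2(1, 50, 7), 1)
  expect_equal(adjusted_r2(0.42, 33, 0), 0.42)
  expect_error(adjusted_r2(0.5, 6, 5), "undefined")
  # strictly below R^2 whenever k >= 1 and R^2 < 1
  set.seed(9)
  for (i in 1:20) {
    r2 <- runif(1); n <- sample(20:200, 1); k <- sample(1:10, 1)
    expect_lt(adjusted_r2(r2, n, k), r2)
  }
})

test_that("BIC follows n log(RSS/n) + p log(n) and is monotone in p", {
  expect_equal(bic_score(100, 100, 1), 2 * log(100))
  expect_equal(bic_score(100, 100, 1), 9.2103404, tolerance = 1e-6)
  expect_gt(bic_score(100, 80, 3), bic_score(100, 80, 2))
  expect_warning(b <- bic_score(50, 0, 1), "-Inf")
  expect_identical(b, -Inf)
})

test_that("adding a pure-noise feature usually increases BIC", {
  set.seed(21)
  worse <- 0L
  n <- 200; reps <- 200
  for (i in seq_len(reps)) {
    x <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("sig", "noise")))
    y <- 0.8 * x[, "sig"] + rnorm(n, sd = 0.6)
    b1 <- fit_ols(x[, "sig", drop = FALSE], y)$bic
    b2 <- fit_ols(x, y)$bic
    if (b2 > b1) worse <- worse + 1L
  }
  expect_gte(worse / reps, 0.9)
})

test_that("significance means the 95% interval excludes zero", {
  set.seed(33)
  x <- matrix(rnorm(300), 100, dimnames = list(NULL, paste0("f", 1:3)))
  y <- 0.9 * x[, 1] + rnorm(100)
  m <- fit_ols(x, y)
  for (f in m$features)
    expect_identical(unname(m$significant[f]),
                     unname(m$ci_low[f] > 0 || m$ci_high[f] < 0))
  expect_true(m$significant[["f1"]])
})

test_that("model methods behave like standard fitted-model accessors", {
  set.seed(44)
  x <- matrix(rnorm(120), 40, dimnames = list(NULL, c("a", "b", "c")))
  y <- x[, "a"] - 0.5 * x[, "b"] + rnorm(40, sd = 0.4)
  m <- fit_ols(x, y, target = "g", level = "M3")
  expect_equal(predict(m), fitted(m))
  expect_equal(unname(predict(m, x)), unname(fitted(m)))
  expect_equal(residuals(m), y - fitted(m))
  expect_equal(nrow(confint(m)), 4L)      # intercept + 3 features
  expect_error(predict(m, x[, 1:2]), "absent")
  expect_output(print(m), "adjusted R")
  sims <- simulate(m, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(40L, 3L))
})

test_that("model summaries flag levels above the adjusted-R^2 threshold", {
  fake <- function(adj) {
    structure(list(target = "g", levels = c("M2", "M3", "M5"),
                   models = list(M2 = NULL,
                                 M3 = list(k = 2, r2 = adj[1] + 0.02,
                                           adj_r2 = adj[1], bic = -10,
                                           significant = c(a = TRUE)),
                                 M5 = list(k = 3, r2 = adj[2] + 0.02,
                                           adj_r2 = adj[2], bic = -12,
                                           significant = c(a = TRUE, b = FALSE)))),
              class = "regfit")
  }
  tab <- summarize_models(list(g = fake(c(0.65, 0.7))), threshold = 0.6)
  expect_identical(tab$good_fit, c(FALSE, TRUE, TRUE))
  expect_equal(tab$k, c(0L, 2L, 3L))
  tab2 <- summarize_models(list(g = fake(c(0.5, 0.55))), threshold = 0.6)
  expect_false(any(tab2$good_fit))
})
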