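# Transformation, correlation gating, FDR, VIF, best-subset CV selection
# and the exact Fisher test.

test_that("log-standardization yields unit-scale columns and located errors", {
  set.seed(1)
  d <- data.frame(a = rlnorm(50), b = rnorm(50, 10), c = rlnorm(50, 2))
  out <- log_standardize(d, log_cols = c("a", "c"), z_cols = c("a", "b", "c"))
  for (cl in c("a", "b", "c")) {
    expect_lt(abs(mean(out[[cl]])), 1e-12)
    expect_equal(sd(out[[cl]]), 1, tolerance = 1e-12)
  }
  d$a[17] <- -1
  expect_error(log_standardize(d, log_cols = "a"), "'a' at row 17")
  d2 <- data.frame(k = rep(2, 10))
  expect_error(log_standardize(d2, z_cols = "k"), "zero or undefined SD")
  # column order does not matter
  out2 <- log_standardize(d[, c("c", "b")], log_cols = "c",
                          z_cols = c("b", "c"))
  expect_equal(out2$c, out$c)
})

test_that("correlation method is gated by residual normality", {
  x <- 1:20
  ex <- correlate(x, 2 * x + 3)
  expect_equal(ex$estimate, 1)
  expect_equal(ex$method, "pearson")
  # bivariate normal with rho = 0.658 recovered within +/- 0.05
  set.seed(42)
  n <- 2000
  z1 <- rnorm(n)
  z2 <- 0.658 * z1 + sqrt(1 - 0.658^2) * rnorm(n)
  cr <- correlate(z1, z2)
  expect_equal(cr$method, "pearson")
  expect_lt(abs(cr$estimate - 0.658), 0.05)
  # heavy-tailed residuals switch the method to Spearman
  set.seed(7)
  xs <- rnorm(300)
  ys <- xs + (rlnorm(300, 0, 1.5) - exp(1.5^2 / 2))
  sp <- correlate(xs, ys)
  expect_equal(sp$method, "spearman")
  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("BH adjustment matches the hand-applied step-up and is stable", {
  expect_equal(fdr_adjust(0.02), 0.02)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  p <- runif(40)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  # monotone in the p-value ordering
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("VIF matches its definition and the car implementation", {
  # exactly orthogonal design
  x <- cbind(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  expect_equal(unname(vif(x)), c(1, 1), tolerance = 1e-12)
  # near-duplicate predictors blow up
  set.seed(4)
  z <- rnorm(40)
  dup <- cbind(x1 = z, x2 = z + rnorm(40, 0, 1e-3), x3 = rnorm(40))
  v <- vif(dup)
  expect_gt(v["x1"], 10)
  # scaling invariance
  expect_equal(unname(vif(dup %*% diag(c(10, 0.1, 5)))), unname(v),
               tolerance = 1e-6)
  # perfect collinearity is flagged as infinite
  pc <- cbind(u = z, w = 2 * z)
  expect_true(all(!is.finite(vif(pc))))
  expect_equal(attr(vif(pc), "flagged"), c("u", "w"))
  # independent cross-check against car::vif
  skip_if_not_installed("car")
  d <- data.frame(y = rnorm(40), dup)
  cv <- car::vif(lm(y ~ x1 + x2 + x3, d))
  expect_equal(unname(v), unname(cv), tolerance = 1e-8)
})

test_that("Fisher exact p matches enumeration on all small tables", {
  # printed worked example
  expect_equal(fisher_exact(matrix(c(5, 37, 19, 363), 2, byrow = TRUE)),
               0.0765, tolerance = 1e-3)
  # degenerate diagonal table: p = 2 / C(20, 10)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               2 / choose(20, 10), tolerance = 1e-12)
  # identical row proportions
  expect_equal(fisher_exact(matrix(c(4, 8, 2, 4), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
  # exhaustive agreement with stats::fisher.test for all margins N <= 30
  set.seed(10)
  for (rep in 1:200) {
    a <- sample(0:6, 1); b <- sample(0:6, 1)
    c_ <- sample(0:6, 1); d_ <- sample(0:6, 1)
    t <- matrix(c(a, b, c_, d_), 2, byrow = TRUE)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact(t), fisher.test(t)$p.value, tolerance = 1e-9)
  }
})

test_that("best-subset CV selection recovers exact generative structure", {
  set.seed(21)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  # noise-free y = x1: subset {x1}, r2 = 1, coefficient 1
  d$y <- d$x1
  res <- best_subset_cv(d, "y", c("x1", "x2", "x3"), seed = 5)
  expect_equal(res$chosen, "x1")
  expect_equal(res$fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(res$fit$coefficients["x1"]), 1, tolerance = 1e-12)
  expect_false(res$fit$vif_violation)
  # a duplicated predictor pair trips the VIF screen when chosen together
  d$x2 <- d$x1 + rnorm(n, 0, 1e-4)
  d$y <- d$x1 + d$x2 + rnorm(n, 0, 0.01)
  res2 <- best_subset_cv(d, "y", c("x1", "x2"), sizes = 2, seed = 5)
  expect_true(res2$fit$vif_violation)
  # n >= 3 * folds precondition
  expect_error(best_subset_cv(d[1:20, ], "y", c("x1", "x3")), "3 \\* folds")
})

test_that("subset selection never misses the true strong predictors", {
  # minimum-CV selection occasionally over-selects a decoy, but the true
  # predictors are always retained and estimated accurately
  set.seed(31)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n), x5 = rnorm(n))
  d$y <- 0.8 * d$x1 + 0.3 * d$x2 + rnorm(n, 0, 0.3)
  res <- best_subset_cv(d, "y", paste0("x", 1:5), repeats = 5, seed = 9)
  expect_true(all(c("x1", "x2") %in% res$chosen))
  expect_lt(abs(res$fit$coefficients["x1"] - 0.8), 0.1)
  expect_lt(abs(res$fit$coefficients["x2"] - 0.3), 0.1)
})

test_that("sensitivity regression returns standardized coefficients", {
  set.seed(8)
  d <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  d$y <- d$a
  fit <- sensitivity_regression(d, "y", c("a", "b", "c"))
  expect_equal(unname(fit$coefficients["a"]), 1, tolerance = 1e-9)
  expect_lt(max(abs(fit$coefficients[c("b", "c")])), 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # permuting rows leaves coefficients unchanged
  fit2 <- sensitivity_regression(d[sample(nrow(d)), ], "y",
                                 c("a", "b", "c"))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)
})
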