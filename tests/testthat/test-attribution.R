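test_that("variance partitioning satisfies its inclusion-exclusion identity", {
  withr::with_seed(1, {
    d <- data.frame(a1 = rnorm(30), a2 = rnorm(30), b1 = rnorm(30),
                    c1 = rnorm(30))
    d$y <- d$a1 + 0.5 * d$b1 + rnorm(30)
  })
  vp <- variance_partition(d$y, d, list(A = c("a1", "a2"), B = "b1", C = "c1"))
  expect_equal(sum(vp$components), vp$full_adj_r2, tolerance = 1e-8)
  expect_equal(vp$residual, 1 - vp$full_adj_r2, tolerance = 1e-12)
})

test_that("duplicated predictor groups share all explained variance", {
  withr::with_seed(2, {
    d <- data.frame(x = rnorm(40))
    d$x_copy <- d$x
    d$y <- 2 * d$x + rnorm(40, 0, 0.5)
  })
  expect_warning(
    vp <- variance_partition(d$y, d, list(G1 = "x", G2 = "x_copy")),
    "collinear")
  expect_lt(abs(vp$components[["G1"]]), 1e-8)
  expect_lt(abs(vp$components[["G2"]]), 1e-8)
  expect_equal(vp$components[["G1:G2"]], vp$full_adj_r2, tolerance = 1e-8)
})

test_that("orthogonal groups recover their true variance fractions", {
  # exactly orthogonal predictors and noise: closed-form shares of 1/3 each
  n <- 200
  S <- diag(3); colnames(S) <- rownames(S) <- c("x1", "x2", "e")
  X <- exact_cov_data(S, n, seed = 3)
  y <- X[, "x1"] + X[, "x2"] + X[, "e"]
  d <- data.frame(X[, 1:2], y = y)
  vp <- variance_partition(d$y, d, list(G1 = "x1", G2 = "x2"))
  expect_lt(abs(vp$components[["G1"]] - 1 / 3), 0.05)
  expect_lt(abs(vp$components[["G2"]] - 1 / 3), 0.05)
  expect_lt(abs(vp$components[["G1:G2"]]), 0.05)
  # null response: all components near zero
  y0 <- withr::with_seed(5, rnorm(n))
  vp0 <- variance_partition(y0, d, list(G1 = "x1", G2 = "x2"))
  expect_lt(max(abs(vp0$components)), 0.05)
})

test_that("VPA agrees with vegan::varpart on a shared example", {
  withr::with_seed(6, {
    d <- data.frame(a = rnorm(40), b = rnorm(40))
    d$y <- d$a + 0.6 * d$b + rnorm(40)
  })
  vp <- variance_partition(d$y, d, list(A = "a", B = "b"))
  vref <- vegan::varpart(d$y, ~ a, ~ b, data = d)$part$indfract$Adj.R.square
  expect_equal(unname(vp$components[c("A", "B", "A:B")]), vref[1:3],
               tolerance = 1e-8)
})

test_that("LMG shares decompose R2 as the ordering average", {
  withr::with_seed(7, {
    x <- rnorm(60); y <- 1.5 * x + rnorm(60)
  })
  l1 <- lmg_importance(y, cbind(x = x))
  expect_equal(unname(l1), summary(lm(y ~ x))$r.squared, tolerance = 1e-10)

  # two orthogonal standardized predictors with equal coefficients
  S <- diag(2); colnames(S) <- rownames(S) <- c("x1", "x2")
  X <- exact_cov_data(S, 80, seed = 8)
  yy <- X[, 1] + X[, 2] + withr::with_seed(9, rnorm(80))
  l2 <- lmg_importance(yy, X)
  full <- summary(lm(yy ~ X))$r.squared
  expect_equal(sum(l2), full, tolerance = 1e-10)
  expect_true(all(l2 > 0))

  # correlated predictors with exact sample covariance: analytic shares
  S3 <- matrix(c(1, 0.5, 1,
                 0.5, 1, 0.5,
                 1, 0.5, 2), 3, 3,
               dimnames = list(c("x1", "x2", "y"), c("x1", "x2", "y")))
  D <- exact_cov_data(S3, 50, seed = 10)
  l3 <- lmg_importance(D[, "y"], D[, c("x1", "x2")])
  # sequential R2: x1 alone 1/2, x2 alone 1/8, full 1/2
  expect_equal(unname(l3["x1"]), (0.5 + (0.5 - 0.125)) / 2, tolerance = 1e-8)
  expect_equal(unname(l3["x2"]), (0 + 0.125) / 2, tolerance = 1e-8)
  expect_error(lmg_importance(yy, matrix(rnorm(80 * 9), 80)), "p > 8")
})

test_that("partial correlation matches the closed form and both routes agree", {
  S <- matrix(c(1, .6, .5,
                .6, 1, .4,
                .5, .4, 1), 3, 3,
              dimnames = list(c("y", "x", "z"), c("y", "x", "z")))
  D <- exact_cov_data(S, 40, seed = 11)
  pc <- partial_correlation(D[, "y"], D[, "x"], D[, "z", drop = FALSE])
  expect_equal(pc$r, (.6 - .5 * .4) / sqrt((1 - .25) * (1 - .16)),
               tolerance = 1e-10)
  pc2 <- partial_correlation(D[, "y"], D[, "x"], D[, "z", drop = FALSE],
                             method = "precision")
  expect_equal(pc$r, pc2$r, tolerance = 1e-10)
  # no controls -> plain Pearson
  p0 <- partial_correlation(D[, "y"], D[, "x"])
  expect_equal(p0$r, cor(D[, "y"], D[, "x"]), tolerance = 1e-12)
  # y = x exactly
  px <- partial_correlation(D[, "x"], D[, "x"], D[, "z", drop = FALSE])
  expect_equal(px$r, 1, tolerance = 1e-10)
  expect_error(partial_correlation(D[, "y"], D[, "x"],
                                   D[, c("x", "z")]), "controls")
})

test_that("the Mantel wrapper reproduces rank correlation of distances", {
  d1 <- dist(matrix(withr::with_seed(12, rnorm(10)), 5))
  m <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(m$r, 1, tolerance = 1e-12)
  # hand Spearman on the 6 upper-triangle pairs of 4x4 matrices
  m1 <- matrix(0, 4, 4); m1[upper.tri(m1)] <- c(1, 2, 3, 4, 5, 6)
  m1 <- m1 + t(m1)
  m2 <- matrix(0, 4, 4); m2[upper.tri(m2)] <- c(2, 1, 4, 3, 6, 5)
  m2 <- m2 + t(m2)
  mm <- mantel_test(m1, m2, n_perm = 99, seed = 2)
  expect_equal(mm$r, cor(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5),
                         method = "spearman"), tolerance = 1e-10)
  expect_error(mantel_test(m1, matrix(0, 3, 3)), "size")
  asym <- m1; asym[1, 2] <- 99
  expect_error(mantel_test(asym, m2), "symmetric")
})

test_that("random-forest importance ranks a strong predictor first", {
  hits <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      X <- data.frame(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
      y <- 2 * X$x1 + rnorm(100, 0, 0.5)
    })
    rf <- rf_importance(y, X, n_trees = 200, n_perm = 19, seed = s)
    hits <- hits + (rf$variable[which.max(rf$importance)] == "x1")
  }
  expect_gte(hits, 19)
  expect_error(rf_importance(rep(1, 20), data.frame(x = rnorm(20))), "constant")
})

test_that("a duplicated informative feature outranks pure noise features", {
  withr::with_seed(33, {
    X <- data.frame(x1 = rnorm(120), noise1 = rnorm(120), noise2 = rnorm(120))
    X$x1_copy <- X$x1 + rnorm(120, 0, 0.05)
    y <- 1.5 * X$x1 + rnorm(120, 0, 0.7)
  })
  rf <- rf_importance(y, X, n_trees = 300, n_perm = 19, seed = 7)
  imp <- setNames(rf$importance, rf$variable)
  expect_gt(imp["x1"] + imp["x1_copy"], max(imp[c("noise1", "noise2")]))
})
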