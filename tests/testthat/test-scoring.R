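test_that("Brier score fixtures", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1))$value, 0)
  expect_equal(brier_score(rbinom(50, 1, 0.5), rep(0.5, 50))$value, 0.25)
  expect_equal(brier_score(c(1, 0, 1), c(0.8, 0.4, 0.6))$value, 0.12,
               tolerance = 1e-12)
  expect_error(brier_score(c(1, 0), c(0.5, 1.2)), "outside")
  expect_error(brier_score(c(1, 0), 0.5), "equal length")
})

test_that("PDI calibration points", {
  y <- factor(rep(c("a", "b", "c"), each = 4))
  Pperf <- diag(3)[as.integer(y), ]
  colnames(Pperf) <- c("a", "b", "c")
  expect_equal(pdi(y, Pperf)$value, 1)
  Punif <- matrix(1 / 3, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(pdi(y, Punif)$value, 1 / 3, tolerance = 1e-12)
  expect_error(pdi(factor(rep("a", 5), levels = c("a", "b")),
                   matrix(0.5, 5, 2, dimnames = list(NULL, c("a", "b")))),
               "empty")
})

test_that("PDI equals exhaustive tuple enumeration, ties included", {
  set.seed(12)
  for (r in 1:25) {
    n <- sample(9:24, 1)
    y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    while (nlevels(droplevels(y)) < 3) {
      y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    }
    P <- matrix(runif(n * 3), n, 3)
    if (r %% 3 == 0) P <- round(P, 1) + 0.05  # provoke exact ties
    P <- P / rowSums(P)
    colnames(P) <- c("a", "b", "c")
    expect_equal(pdi(y, P)$value, pdi_exhaustive3(y, P), tolerance = 1e-12)
  }
})

test_that("PDI is permutation invariant and rewards better predictions", {
  set.seed(13)
  n <- 60
  y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  P <- matrix(runif(n * 3), n, 3)
  P <- P / rowSums(P)
  colnames(P) <- c("a", "b", "c")
  perm <- sample(n)
  expect_equal(pdi(y, P)$value, pdi(y[perm], P[perm, ])$value,
               tolerance = 1e-12)
  # raise the true-category probability of one observation
  i <- which(y == "a")[1]
  P2 <- P
  P2[i, ] <- c(0.999, 0.0005, 0.0005)
  expect_gte(pdi(y, P2)$value, pdi(y, P)$value)
})

test_that("Brant statistic is zero when cumulative slopes agree exactly", {
  # x=0 group: outcome probabilities (1/2, 1/4, 1/4); x=1 group:
  # (1/4, 1/4, 1/2): both cumulative logits shift by exactly log 3
  y <- c(rep(1:3, c(8, 4, 4)), rep(1:3, c(4, 4, 8)))
  x <- rep(c(0, 1), each = 16)
  out <- brant_test(y, cbind(x = x))
  expect_lt(out$global$statistic, 1e-8)
  expect_equal(out$global$df, 1)
  expect_equal(out$global$p, 1, tolerance = 1e-6)
})

test_that("Brant test guards and detects strong non-proportionality", {
  expect_error(brant_test(c(1, 2, 1, 2), cbind(rnorm(4))), "3 outcome levels")
  set.seed(14)
  n <- 2000
  x <- rnorm(n)
  u <- runif(n)
  # slopes differing by 1.0 across the two cumulative splits
  y <- 1L + (u < plogis(0.2 * x + 1)) + (u < plogis(1.2 * x - 1))
  out <- brant_test(y, cbind(x = x))
  expect_lt(out$global$p, 0.01)
  expect_equal(out$by_variable$df, 1)
})

test_that("accuracy change formulas", {
  expect_equal(accuracy_change(0.5, 0.5, "pdi"), 0)
  expect_equal(accuracy_change(0.60, 0.5814, "pdi"), 3.1, tolerance = 1e-8)
  expect_equal(accuracy_change(0.130, 0.1596, "brier"), 3.4, tolerance = 0.02)
  # positive = degradation on both scales
  expect_gt(accuracy_change(0.6, 0.55, "pdi"), 0)
  expect_gt(accuracy_change(0.10, 0.12, "brier"), 0)
})

test_that("the true model is not beaten by a miscalibrated perturbation", {
  set.seed(15)
  n <- 4000
  x <- rnorm(n)
  p <- plogis(-1 + 0.8 * x)
  y <- rbinom(n, 1, p)
  b_true <- brier_score(y, p)$value
  b_warp <- brier_score(y, plogis(-1 + 1.6 * x))$value
  expect_lt(b_true, b_warp)
})
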