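test_that("complete data pass through imputation unchanged", {
  tab <- small_survey(600, seed = 41)
  imp <- chained_imputation(tab, m = 3, iterations = 2, seed = 1)
  expect_equal(imp$m, 3L)
  expect_identical(imp$completed[[1]], tab)
  expect_identical(imp$completed[[3]], tab)
  expect_length(imp$variables_imputed, 0)
})

test_that("observed cells are never altered and structural gaps persist", {
  tab <- small_survey(3000, seed = 42, missingness = TRUE)
  imp <- chained_imputation(tab, m = 3, iterations = 3, seed = 2)
  for (v in imp$variables_imputed) {
    obs <- !is.na(tab[[v]])
    for (cc in imp$completed) {
      expect_identical(cc[[v]][obs], tab[[v]][obs])
    }
  }
  ex <- tab$smoker_status == "recent_ex"
  for (cc in imp$completed) {
    expect_true(all(is.na(cc$mtss3[ex])))
    expect_false(anyNA(cc$qa))
    expect_false(anyNA(cc$education))
  }
})

test_that("m below 2 and fully missing variables are rejected", {
  tab <- small_survey(200, seed = 43)
  expect_error(chained_imputation(tab, m = 1), "at least 2")
  tab$income <- NA_real_
  expect_error(chained_imputation(tab, m = 2), "100% missing")
})

test_that("masked-cell recovery: imputed income mean tracks the truth", {
  tab <- small_survey(4000, seed = 44)
  truth_mean <- mean(tab$income)
  set.seed(45)
  tab$income[runif(nrow(tab)) < 0.10] <- NA
  imp <- chained_imputation(tab, m = 5, iterations = 5, seed = 46)
  means <- vapply(imp$completed, function(cc) mean(cc$income), numeric(1))
  vars <- vapply(imp$completed, function(cc) {
    stats::var(cc$income) / nrow(cc)
  }, numeric(1))
  pl <- pool_scalar(means, vars)
  expect_lt(abs(pl$estimate - truth_mean), 2 * pl$se)
})

test_that("Rubin pooling closed-form fixtures", {
  # no between-imputation variance
  p0 <- pool_scalar(c(1.7, 1.7, 1.7), c(0.3, 0.3, 0.3))
  expect_equal(p0$between, 0)
  expect_equal(p0$total, p0$within)
  expect_equal(p0$df, Inf)
  # m = 2 hand case: qbar 2, B 2, T = 1 + 1.5 * 2 = 4
  p1 <- pool_scalar(c(1, 3), c(1, 1))
  expect_equal(p1$estimate, 2)
  expect_equal(p1$between, 2)
  expect_equal(p1$total, 4)
  # CI width grows with B at fixed W
  w1 <- diff(pool_scalar(c(2, 2.2), c(1, 1))$ci)
  w2 <- diff(pool_scalar(c(1, 3.2), c(1, 1))$ci)
  expect_gt(w2, w1)
  # invariance to imputation order
  p2 <- pool_scalar(c(3, 1), c(1, 1))
  expect_equal(p1$estimate, p2$estimate)
  expect_equal(p1$total, p2$total)
})

test_that("pooled LR test degenerates to the single-data-set test", {
  tab <- small_survey(2500, seed = 47)
  iset <- structure(
    list(completed = list(tab, tab, tab), m = 3L, iterations = 0L,
         seed = 1L, variables_imputed = character(0)),
    class = "imputation_set"
  )
  full <- qa_true_spec()
  red <- qa_true_spec()
  red$interactions <- list()
  pl <- pool_lr(full, red, iset)
  ff <- fit_model(tab, full)
  fr <- fit_model(tab, red)
  lt <- lr_test(ff, fr)
  expect_equal(pl$p, lt$p, tolerance = 1e-8)
  expect_equal(pl$df, lt$df)
  expect_equal(pl$r, 0)
})

test_that("pooled LR guards", {
  tab <- small_survey(300, seed = 48)
  expect_error(pool_lr(qa_true_spec(), qa_true_spec(),
                       as_imputation_set(tab)),
               "m >= 2")
})
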