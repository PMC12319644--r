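test_that("2x2 logistic slope equals the closed-form log odds ratio", {
  # cells (a,b,c,d) = (10,20,30,40): x=1 rows a events / c non-events,
  # x=0 rows b events / d non-events; slope = log(ad/bc) = log(2/3)
  y <- c(rep(1, 10), rep(0, 30), rep(1, 20), rep(0, 40))
  x <- c(rep(1, 40), rep(0, 60))
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- fit_logistic(X, y)
  expect_equal(unname(f$coefficients["x"]), log(10 * 40 / (20 * 30)),
               tolerance = 1e-8)
  # BIC against hand arithmetic on the saturated-by-group likelihood
  ll_hand <- 10 * log(10 / 40) + 30 * log(30 / 40) +
    20 * log(20 / 60) + 40 * log(40 / 60)
  expect_equal(f$loglik, ll_hand, tolerance = 1e-8)
  expect_equal(bic(f), -2 * ll_hand + 2 * log(100), tolerance = 1e-8)
})

test_that("balanced 2x2 with OR 1 gives slope zero", {
  y <- rep(c(1, 0, 1, 0), each = 25)
  x <- rep(c(1, 1, 0, 0), each = 25)
  f <- fit_logistic(cbind(1, x = x), y)
  expect_equal(unname(f$coefficients["x"]), 0, tolerance = 1e-10)
})

test_that("intercept-only multinomial recovers log-count ratios", {
  y <- factor(rep(c("absence", "unspecific", "motivation"), c(12, 24, 36)),
              levels = c("absence", "unspecific", "motivation"))
  X <- matrix(1, 72, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_multinomial(X, y)
  expect_equal(unname(f$coefficients[, 1]), c(log(2), log(3)),
               tolerance = 1e-8)
})

test_that("multinomial log-likelihood matches an independent optimizer", {
  set.seed(7)
  n <- 30
  X <- cbind(1, x1 = rnorm(n), x2 = rnorm(n))
  y <- factor(sample(c("a", "b", "c"), n, replace = TRUE, prob = c(.4, .35, .25)))
  f <- fit_multinomial(X, y)
  # independent route: generic BFGS on a locally written likelihood
  nll <- function(par) {
    B <- matrix(par, 2, 3, byrow = TRUE)
    E <- exp(cbind(0, X %*% t(B)))
    P <- E / rowSums(E)
    -sum(log(P[cbind(seq_len(n), as.integer(y))]))
  }
  o <- optim(rep(0, 6), nll, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  expect_equal(f$loglik, -o$value, tolerance = 1e-6)
  expect_lt(f$score_max, 1e-6)
})

test_that("multinomial with two categories equals the logistic fit", {
  set.seed(8)
  n <- 200
  X <- cbind(1, x = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 * X[, 2]))
  fl <- fit_logistic(X, y)
  fm <- fit_multinomial(X, factor(y, levels = c(0, 1)))
  expect_equal(unname(fm$coefficients[1, ]), unname(fl$coefficients),
               tolerance = 1e-8)
  expect_equal(fm$loglik, fl$loglik, tolerance = 1e-8)
})

test_that("estimates are invariant to row permutation and rescale inversely", {
  tab <- small_survey(1200, seed = 3)
  spec <- qa_true_spec()
  f1 <- fit_model(tab, spec)
  f2 <- fit_model(tab[sample(nrow(tab)), ], spec)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  tab2 <- tab
  tab2$income <- tab2$income * 10
  f3 <- fit_model(tab2, spec)
  expect_equal(unname(f3$coefficients["income"]) * 10,
               unname(f1$coefficients["income"]), tolerance = 1e-6)
})

test_that("design construction produces the documented columns", {
  tab <- small_survey(300, seed = 4)
  d1 <- build_design(tab, model_spec("qa", terms = c(sex = "cat")))
  expect_identical(colnames(d1$X), c("(Intercept)", "sexfemale"))

  d2 <- build_design(tab, model_spec("qa",
    terms = c(sex = "cat", education = "cat"),
    interactions = list(c("sex", "education"))))
  int_cols <- d2$column_map$column[d2$column_map$type == "interaction"]
  expect_length(int_cols, 2L)  # 1 x 2 product columns
  expect_equal(d2$X[, "sexfemale:educationhigh"],
               d2$X[, "sexfemale"] * d2$X[, "educationhigh"])

  d3 <- build_design(tab, model_spec("qa",
    terms = c(age = "rcs4", income = "linear"),
    interactions = list(c("age", "income"))))
  cm <- d3$column_map
  expect_equal(sum(cm$term == "age" & cm$type == "main"), 3L)
  expect_equal(sum(cm$term == "income" & cm$type == "main"), 1L)
  expect_equal(sum(cm$type == "interaction"), 3L)
  # interaction columns are elementwise products of the member columns
  expect_equal(d3$X[, "age:income"], d3$X[, "age"] * d3$X[, "income"])
  expect_equal(d3$X[, "age':income"], d3$X[, "age'"] * d3$X[, "income"])
})

test_that("unseen category levels at prediction time are named in the error", {
  tab <- small_survey(300, seed = 5)
  spec <- freeze_spec(model_spec("qa", terms = c(region = "cat")), tab)
  bad <- tab
  bad$region <- as.character(bad$region)
  bad$region[1] <- "offshore"
  expect_error(build_design(bad, spec, require_outcome = FALSE), "offshore")
})

test_that("likelihood-ratio test basics", {
  tab <- small_survey(1500, seed = 6)
  full <- fit_model(tab, qa_true_spec())
  red_spec <- qa_true_spec()
  red_spec$interactions <- list()
  red <- fit_model(tab, red_spec)
  lt <- lr_test(full, red)
  expect_equal(lt$df, 2L)  # two interaction columns dropped
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # age enters the full model linearly, so a spline-coded age model is
  # not nested within it
  other <- fit_model(tab, model_spec("qa", terms = c(age = "rcs4")))
  expect_error(lr_test(full, other), "not nested")
})

test_that("predicted probabilities behave", {
  tab <- small_survey(500, seed = 9)
  f0 <- fit_model(tab, model_spec("qa", terms = c(sex = "cat")))
  # intercept-only reduction: prevalence prediction
  fi <- fit_logistic(matrix(1, 400, 1, dimnames = list(NULL, "i")),
                     rep(c(1, 0), c(120, 280)))
  expect_equal(unname(plogis(fi$coefficients)), 0.3, tolerance = 1e-8)
  cur <- tab[tab$smoker_status == "current", ]
  fm <- fit_model(cur, model_spec("mtss3",
    terms = c(age = "rcs4", sex = "cat", income = "linear")))
  P <- predict_probs(fm, cur)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
})

test_that("contrasts reduce to coefficients and flag extrapolation", {
  tab <- small_survey(1500, seed = 10)
  spec <- model_spec("qa", terms = c(age = "linear", sex = "cat"))
  f <- fit_model(tab, spec)
  ec <- evaluate_contrast(f, "age", c(30, 31), 30)
  expect_equal(ec$or[1], 1)
  expect_equal(ec$lo[1], 1)
  expect_equal(ec$or[2], exp(unname(f$coefficients["age"])),
               tolerance = 1e-10)
  ec2 <- evaluate_contrast(f, "age", 150, 30)
  expect_true(ec2$extrapolated[1])
})

test_that("rank-deficient designs are rejected", {
  X <- cbind(1, x = 1:20, y = 2 * (1:20))
  expect_error(fit_logistic(X, rep(0:1, 10)), "rank deficient")
})
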