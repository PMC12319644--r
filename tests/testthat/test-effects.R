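test_that("identical fits pool to the single-fit odds ratios exactly", {
  tab <- small_survey(2500, seed = 61)
  spec <- qa_true_spec()
  f <- fit_model(tab, spec)
  tabOR <- pooled_or_table(list(f, f, f))
  single <- exp(f$coefficients["sexfemale"])
  row <- tabOR[tabOR$label == "sexfemale", ]
  expect_equal(row$or, unname(single), tolerance = 1e-12)
  # with zero between-imputation variance the CI is the Wald interval
  se <- sqrt(diag(f$vcov)["sexfemale"])
  expect_equal(row$lo, unname(exp(f$coefficients["sexfemale"] - 1.96 * se)),
               tolerance = 1e-3)
  # reference rows carry OR exactly 1
  refs <- tabOR[tabOR$reference, ]
  expect_true(all(refs$or == 1))
  expect_true(any(grepl("sexmale", refs$label)))
  # pooling happens on the log scale, then exponentiates
  f2 <- f
  f2$coefficients["sexfemale"] <- f$coefficients["sexfemale"] + 0.2
  tab2 <- pooled_or_table(list(f, f2))
  expect_equal(tab2[tab2$label == "sexfemale", "or"],
               exp(unname(f$coefficients["sexfemale"]) + 0.1),
               tolerance = 1e-12)
})

test_that("spline covariates are reported as pooled contrasts", {
  tab <- small_survey(3000, seed = 62)
  spec <- model_spec("qa", terms = c(age = "rcs4", sex = "cat",
                                     urges = "cat"))
  f <- fit_model(tab, spec)
  out <- pooled_or_table(list(f), contrasts = list(
    age = list(values = c(40, 60), ref = 20)
  ))
  expect_false(any(out$label == "age'"))  # no raw spline coefficients
  expect_true(all(c("age 40 vs 20", "age 60 vs 20") %in% out$label))
  direct <- evaluate_contrast(f, "age", 40, 20)
  expect_equal(out[out$label == "age 40 vs 20", "or"], direct$or[1],
               tolerance = 1e-10)
})

test_that("intercept-only marginal grid equals the prevalence everywhere", {
  tab <- small_survey(1500, seed = 63)
  spec <- model_spec("qa", terms = c(sex = "cat"))
  spec$terms <- c(sex = "cat")
  f <- fit_model(tab, spec)
  iset <- as_imputation_set(tab)
  # grid over a covariate not in the model: every cell must equal the
  # average prediction, i.e. the observed prevalence at the MLE
  g <- marginal_probabilities(list(f), iset, list(income = c(0.5, 2, 3.5)))
  prev <- mean(tab$qa == "yes")
  expect_equal(g$probability, rep(mean(predict_probs(f, tab)), 3),
               tolerance = 1e-12)
  expect_lt(abs(g$probability[1] - prev), 1e-10)
})

test_that("multinomial marginal cells sum to one and flag extrapolation", {
  tab <- small_survey(2000, seed = 64)
  cur <- tab[tab$smoker_status == "current", ]
  spec <- model_spec("mtss3", terms = c(age = "rcs4", income = "linear",
                                        sex = "cat"),
                     interactions = list(c("age", "income")))
  f <- fit_model(cur, spec)
  iset <- as_imputation_set(cur)
  g <- marginal_probabilities(list(f), iset,
                              list(age = c(30, 50, 120), income = c(1)))
  sums <- tapply(g$probability, list(g$age), sum)
  expect_true(all(abs(sums - 1) < 1e-8))
  expect_true(all(g$extrapolated[g$age == 120]))
  expect_false(any(g$extrapolated[g$age != 120]))
  expect_true(all(g$probability >= 0 & g$probability <= 1))
  expect_true(all(g$lo <= g$probability + 1e-12 &
                    g$probability <= g$hi + 1e-12))
})

test_that("external validation is exact on identical data and guards input", {
  tab <- small_survey(2500, seed = 65)
  iset <- as_imputation_set(tab)
  val <- external_validate(qa_true_spec(), iset, iset, rule = "brier")
  expect_equal(val$change_pct, 0, tolerance = 1e-12)
  expect_equal(val$score_learn, val$score_valid)
  expect_error(external_validate(NULL, iset, iset, "brier"), "missing")
})

test_that("validation degrades gracefully on independent data", {
  learn <- small_survey(4000, seed = 66)
  valid <- small_survey(2000, seed = 67)
  val <- external_validate(qa_true_spec(), as_imputation_set(learn),
                           as_imputation_set(valid), rule = "brier")
  # same generating process: degradation should be small
  expect_lt(abs(val$change_pct), 6)
})
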