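test_that("candidate enumeration counts follow the product formula", {
  space <- candidate_space(
    "qa",
    spline_options = list(age = c("linear", "rcs4"),
                          income = c("linear", "rcs4")),
    max_interactions = 1L
  )
  cands <- enumerate_candidates(space)
  expect_length(cands, 2 * 2 * (1 + 10))
  # hierarchy: every interaction member is among the terms
  for (sp in cands) {
    for (pr in sp$interactions) {
      expect_true(all(pr %in% names(sp$terms)))
    }
  }
  space0 <- candidate_space("qa", max_interactions = 0L)
  expect_true(all(vapply(enumerate_candidates(space0),
                         function(s) length(s$interactions) == 0,
                         logical(1))))
  expect_error(
    candidate_space("qa", interaction_pool = list(
      c("sex", "education"), c("education", "sex")
    )),
    "duplicate"
  )
})

test_that("bootstrap selection is reproducible and trivially picks a lone candidate", {
  tab <- small_survey(1200, seed = 51)
  iset <- as_imputation_set(tab)
  lone <- list(model_spec("qa", terms = c(age = "linear", sex = "cat",
                                          urges = "cat")))
  sel <- bootstrap_select(iset, lone, B = 50, rule = "brier", seed = 7)
  expect_equal(sel$winner_index, 1L)
  expect_equal(ncol(sel$scores), 50L)
  expect_true(all(is.finite(sel$scores[1, ])))
  sel2 <- bootstrap_select(iset, lone, B = 50, rule = "brier", seed = 7)
  expect_identical(sel$scores, sel2$scores)
  expect_error(bootstrap_select(iset, lone, B = 10, rule = "brier"),
               "at least 50")
  expect_error(bootstrap_select(iset, lone, B = 50, rule = "pdi"),
               "multinomial")
})

test_that("backward elimination removes a pure-noise covariate and keeps hierarchy", {
  set.seed(52)
  successes <- 0
  for (r in 1:5) {
    tab <- small_survey(5000, seed = 520 + r)
    tab$noise <- rnorm(nrow(tab))
    full <- model_spec("qa",
      terms = c(age = "linear", income = "linear", sex = "cat",
                education = "cat", urges = "cat", year = "linear",
                noise = "linear"),
      interactions = list(c("sex", "education"))
    )
    iset <- as_imputation_set(tab)
    out <- backward_eliminate(iset, full, protected = c("urges", "year"))
    if (!"noise" %in% names(out$terms)) successes <- successes + 1
    # hierarchy: members of retained interactions are never dropped
    for (pr in out$interactions) {
      expect_true(all(pr %in% names(out$terms)))
    }
  }
  expect_gte(successes, 4)
})

test_that("a BIC-optimal spec is a fixed point of backward elimination", {
  tab <- small_survey(4000, seed = 53)
  iset <- as_imputation_set(tab)
  lean <- model_spec("qa", terms = c(urges = "cat", year = "linear",
                                     income = "linear"))
  out <- backward_eliminate(iset, lean, protected = c("urges", "year",
                                                      "income"))
  expect_identical(out$terms, freeze_spec(lean, tab)$terms)
  expect_length(out$interactions, 0)
})

test_that("interaction confirmation retains strong effects and passes vacuously", {
  tab <- small_survey(6000, seed = 54)
  iset <- as_imputation_set(tab)
  sel <- confirm_interaction(freeze_spec(qa_true_spec(), tab), iset)
  expect_false(sel$lr_confirmation$vacuous)
  expect_lt(sel$lr_confirmation$p, 0.05)
  expect_true(sel$lr_confirmation$retained)
  no_int <- qa_true_spec()
  no_int$interactions <- list()
  sel0 <- confirm_interaction(freeze_spec(no_int, tab), iset)
  expect_true(sel0$lr_confirmation$vacuous)
  expect_true(sel0$lr_confirmation$retained)
})
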