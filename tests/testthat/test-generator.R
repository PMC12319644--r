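test_that("configuration guards reject invalid input", {
  expect_error(generator_config(0), "positive integer")
  expect_error(generator_config(-5), "positive integer")
  expect_error(
    generator_config(10, covariate_params = list(
      education_p = c(low = 0.5, middle = 0.4, high = 0.2)
    )),
    "sum to 1"
  )
  expect_error(
    generator_config(10, covariate_params = list(
      age = list(mean = 40, sd = 10, lo = 60, hi = 20)
    )),
    "ordered"
  )
  expect_error(
    generator_config(10, missingness_params = list(
      rates = c(education = 1.4)
    )),
    "\\[0, 1\\]"
  )
})

test_that("generation is deterministic given the config", {
  cfg <- generator_config(1500, seed = 77, n_calibration = 5000)
  t1 <- simulate_survey(cfg)
  t2 <- simulate_survey(cfg)
  expect_identical(t1, t2)
})

test_that("covariate margins track the configured distributions", {
  cfg <- generator_config(20000, seed = 201, n_calibration = 5000)
  tab <- generate_covariates(cfg)
  expect_true(all(tab$age >= 18 & tab$age <= 99))
  expect_true(all(tab$income >= 0 & tab$income <= 7))
  expect_lt(abs(mean(tab$age) - 46.8), 2 * 16.7 / sqrt(20000) + 0.2)
  p <- cfg$covariate_params
  expect_lt(max(abs(prop.table(table(tab$education)) - p$education_p)), 0.015)
  expect_lt(max(abs(prop.table(table(tab$region)) - p$region_p)), 0.015)
  expect_lt(max(abs(prop.table(table(tab$urges)) - p$urges_p)), 0.015)
  expect_lt(abs(mean(tab$sex == "female") - p$sex_p_female), 0.015)
})

test_that("zeroed motivation model yields equal collapsed categories", {
  zero <- default_zero <- list(
    intercepts = c(unspecific = 0, motivation = 0),
    urges = matrix(0, 2, 5, dimnames = list(c("unspecific", "motivation"),
      c("none", "light", "strong", "very_strong", "extremely_strong"))),
    year = matrix(0, 2, 4, dimnames = list(c("unspecific", "motivation"),
      c("2017", "2018", "2019", "2020"))),
    sex_female = c(unspecific = 0, motivation = 0),
    education = matrix(0, 2, 2, dimnames = list(c("unspecific", "motivation"),
      c("middle", "high"))),
    region = matrix(0, 2, 2, dimnames = list(c("unspecific", "motivation"),
      c("urban", "metropolitan"))),
    income = c(unspecific = 0, motivation = 0),
    age_spline = list(knots = c(25, 40, 55, 75), ref_age = 20,
                      beta = matrix(0, 2, 3, dimnames = list(
                        c("unspecific", "motivation"), NULL))),
    age_income_scale = c(unspecific = 0, motivation = 0)
  )
  cfg <- generator_config(24000, seed = 31, mtss_coefficients = zero,
                          calibrate = FALSE)
  tab <- recode_outcomes(generate_mtss(generate_covariates(cfg), cfg))
  sh <- prop.table(table(tab$mtss3))
  expect_lt(max(abs(sh - 1 / 3)), 0.015)
})

test_that("zero-slope quit-attempt model gives 50% prevalence", {
  zero_qa <- c(null_interaction_qa(), list(
    intercept = 0,
    urges = c(none = 0, light = 0, strong = 0, very_strong = 0,
              extremely_strong = 0),
    time_per_year = 0, age_per_year = 0, sex_female = 0,
    education = c(middle = 0, high = 0),
    region = c(urban = 0, metropolitan = 0), income = 0
  ))
  cfg <- generator_config(20000, seed = 32, qa_coefficients = zero_qa,
                          calibrate = FALSE)
  tab <- generate_qa(generate_covariates(cfg), cfg)
  expect_lt(abs(mean(tab$n_quit_attempts >= 1) - 0.5), 0.015)
})

test_that("degenerate expansion proportions suppress levels 5-7", {
  cfg <- generator_config(8000, seed = 33, n_calibration = 5000,
    mtss_expansion = list(cat3 = c(`4` = 1, `5` = 0, `6` = 0, `7` = 0)))
  tab <- generate_mtss(generate_covariates(cfg), cfg)
  expect_false(any(tab$mtss_level %in% 5:7))
  expect_true(any(tab$mtss_level == 4))
})

test_that("motivation level is structurally missing for recent ex-smokers", {
  tab <- small_survey(4000, seed = 34)
  ex <- tab$smoker_status == "recent_ex"
  expect_true(all(is.na(tab$mtss_level[ex])))
  expect_gt(sum(ex), 0)
})

test_that("missingness injection matches targets and strata ordering", {
  cfg <- generator_config(20000, seed = 35, n_calibration = 5000)
  complete <- simulate_survey(cfg, missingness = FALSE)
  # zero rates: no-op
  cfg0 <- generator_config(20000, seed = 35, n_calibration = 5000,
    missingness_params = list(rates = c(education = 0, urges = 0, mtss = 0,
                                        qa = 0, income = 0)))
  expect_identical(inject_missingness(complete, cfg0), complete)
  # +2 log-odds male/high increment: stratum rate strictly above female/low
  cfg2 <- generator_config(20000, seed = 35, n_calibration = 5000,
    missingness_params = list(male_high_increment = 2))
  tab2 <- inject_missingness(complete, cfg2)
  mh <- tab2$sex == "male" & complete$education == "high"
  fl <- tab2$sex == "female" & complete$education == "low"
  rate_mh <- mean(is.na(tab2$n_quit_attempts[mh]))
  rate_fl <- mean(is.na(tab2$n_quit_attempts[fl]))
  expect_gt(rate_mh, rate_fl)
})

test_that("outcome recoding obeys the collapsing map and is idempotent", {
  tab <- data.frame(mtss_level = c(1L, 2L, 3L, 4L, 7L, NA),
                    n_quit_attempts = c(0L, 1L, 3L, NA, 2L, 0L))
  out <- recode_outcomes(tab)
  expect_equal(as.character(out$mtss3),
               c("absence", "unspecific", "unspecific", "motivation",
                 "motivation", NA))
  expect_equal(as.character(out$qa), c("no", "yes", "yes", NA, "yes", "no"))
  expect_identical(recode_outcomes(out), out)
  expect_error(recode_outcomes(data.frame(mtss_level = 8L)), "domain error")
  expect_error(recode_outcomes(data.frame(n_quit_attempts = -1L)),
               "domain error")
})

test_that("learning/validation split is an exact partition", {
  tab <- data.frame(id = 1:10, x = rnorm(10))
  sp <- split_learning_validation(tab, 0.7, seed = 5)
  expect_equal(nrow(sp$learning), 7)
  expect_equal(nrow(sp$validation), 3)
  expect_length(intersect(sp$learning$id, sp$validation$id), 0)
  # documented sizes for the survey-scale split under round-half-to-even
  tab2 <- data.frame(id = seq_len(13245))
  sp2 <- split_learning_validation(tab2, 0.7, seed = 6)
  expect_equal(nrow(sp2$learning), 9272)
  expect_equal(nrow(sp2$validation), 3973)
  # partition property over random fractions and seeds
  set.seed(36)
  for (r in 1:10) {
    fr <- runif(1, 0.1, 0.9)
    s <- sample.int(10000, 1)
    sp3 <- split_learning_validation(tab2, fr, seed = s)
    expect_equal(sort(c(sp3$learning$id, sp3$validation$id)), tab2$id)
  }
  sp4 <- split_learning_validation(tab2, 0.7, seed = 6)
  expect_identical(sp2, sp4)
  expect_error(split_learning_validation(tab, 1.2), "\\(0, 1\\)")
})

test_that("full-stratification cell counts multiply", {
  expect_equal(count_full_strata(c(2, 3, 3, 3, 3)), 162L)
  expect_equal(count_full_strata(1), 1L)
  expect_equal(count_full_strata(c(4, 5)), 20L)
  expect_error(count_full_strata(numeric(0)), "non-empty")
  expect_error(count_full_strata(c(2, 0)), "positive")
})

test_that("survey tables round-trip through CSV", {
  tab <- small_survey(300, seed = 37, missingness = TRUE)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_survey(tab, path)
  back <- read_survey(path)
  expect_equal(back$age, tab$age, tolerance = 1e-12)
  expect_identical(back$sex, tab$sex)
  expect_identical(back$mtss3, tab$mtss3)
  expect_identical(is.na(back$n_quit_attempts), is.na(tab$n_quit_attempts))
})
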