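# Synthetic survey generator.
#
# Default parameters emulate a German adult smoker survey: covariate
# margins (age, sex, education, region, standardised net household
# income 0-7, strength of urges to smoke), a 3-category motivation-to-
# stop outcome driven by a multinomial model with a smooth age x income
# interaction, a binary past-year quit-attempt outcome driven by a
# logistic model with a sex x education interaction, and selective
# missing-at-random missingness (males with high education more often
# withhold smoking-habit information).

# ---- truncated-normal helpers -------------------------------------------

tn_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Underlying (mu, sigma) such that the truncated normal on [lo, hi] has
# the requested mean and sd.
tn_solve <- function(mean, sd, lo, hi) {
  obj <- function(par) {
    mo <- suppressWarnings(tn_moments(par[1L], exp(par[2L]), lo, hi))
    if (any(!is.finite(mo))) return(1e10)
    (mo[1L] - mean)^2 + (mo[2L] - sd)^2
  }
  opt <- stats::optim(c(mean, log(sd)), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  c(mu = opt$par[1L], sigma = exp(opt$par[2L]))
}

rtruncnorm <- function(n, mu, sigma, lo, hi) {
  a <- stats::pnorm((lo - mu) / sigma)
  b <- stats::pnorm((hi - mu) / sigma)
  mu + sigma * stats::qnorm(stats::runif(n, a, b))
}

# ---- default parameters --------------------------------------------------

default_covariate_params <- function() {
  list(
    age = list(mean = 46.8, sd = 16.7, lo = 18, hi = 99),
    sex_p_female = 4312 / 9253,
    education_p = c(low = 3114, middle = 3623, high = 2391) / 9128,
    region_p = c(rural = 3323, urban = 3995, metropolitan = 1935) / 9253,
    income = list(mean = 1.47, sd = 0.818, lo = 0, hi = 7),
    urges_p = c(none = 668, light = 2046, medium_strong = 3708,
                strong = 2109, very_strong = 519, extremely_strong = 92) / 9142,
    p_current = 12784 / 13245
  )
}

# Age effect targets (log odds-ratios vs age 20) used to set the default
# spline coefficients of the motivation model; least-squares fitted to a
# 4-knot restricted cubic spline at config-build time.
mtss_age_targets <- function() {
  list(
    ages = c(20, 30, 40, 50, 60, 70, 80),
    unspecific = log(c(1, 1.00, 1.00, 1.04, 1.10, 1.01, 0.74)),
    motivation = log(c(1, 2.04, 1.88, 1.55, 1.87, 1.32, 0.50))
  )
}

default_mtss_coefficients <- function() {
  tg <- mtss_age_targets()
  sp <- spline_spec(c(25, 40, 55, 75))
  H <- rcs_basis(tg$ages, sp) -
    matrix(rcs_basis(20, sp), length(tg$ages), 3, byrow = TRUE)
  beta <- cbind(
    unspecific = qr.solve(H, tg$unspecific),
    motivation = qr.solve(H, tg$motivation)
  )
  list(
    categories = c("unspecific", "motivation"),
    # intercepts are calibrated so that marginal collapsed-category
    # shares match the target margins; see calibrate flag
    intercepts = c(unspecific = 0, motivation = 0),
    urges = rbind(
      unspecific = log(c(none = 0.64, light = 0.75, strong = 0.86,
                         very_strong = 0.72, extremely_strong = 0.52)),
      motivation = log(c(none = 0.63, light = 0.85, strong = 0.73,
                         very_strong = 0.43, extremely_strong = 0.80))
    ),
    year = rbind(
      unspecific = log(c(`2017` = 1.26, `2018` = 1.20, `2019` = 1.15,
                         `2020` = 1.25)),
      motivation = log(c(`2017` = 0.84, `2018` = 0.70, `2019` = 0.59,
                         `2020` = 0.54))
    ),
    sex_female = c(unspecific = log(1.18), motivation = log(1.13)),
    education = rbind(
      unspecific = log(c(middle = 1.13, high = 1.33)),
      motivation = log(c(middle = 1.19, high = 1.65))
    ),
    region = rbind(
      unspecific = log(c(urban = 1.12, metropolitan = 0.92)),
      motivation = log(c(urban = 1.17, metropolitan = 0.91))
    ),
    income = c(unspecific = -0.05, motivation = -0.25),
    age_spline = list(knots = sp$knots, ref_age = 20, beta = t(beta)),
    # age-effect multiplier (1 + scale * income): shrinks the age bump
    # as income grows, giving a motivation surface that peaks at ages
    # 30-50 for low/middle incomes
    age_income_scale = c(unspecific = -0.10, motivation = -0.35)
  )
}

default_mtss_expansion <- function() {
  list(
    cat2 = c(`2` = 2347, `3` = 961) / 3308,
    cat3 = c(`4` = 307, `5` = 786, `6` = 100, `7` = 86) / 1279
  )
}

default_qa_coefficients <- function() {
  list(
    intercept = 0,  # calibrated to the target prevalence
    urges = log(c(none = 2.54, light = 0.90, strong = 1.06,
                  very_strong = 0.80, extremely_strong = 1.47)),
    time_per_year = log(0.77),
    age_per_year = log(0.95) / 10,  # printed OR interpreted per decade
    sex_female = log(1.26),
    education = log(c(middle = 1.10, high = 1.42)),
    region = log(c(urban = 1.02, metropolitan = 0.99)),
    income = log(0.83),
    sex_education = log(c(female_middle = 0.94, female_high = 0.67)),
    positive_split = c(`1` = 0.7, `2` = 0.2, `3` = 0.1)
  )
}

default_missingness_params <- function() {
  list(
    rates = c(education = 0.014, urges = 0.012, mtss = 0.014,
              qa = 0.046, income = 0.0002),
    male_high_increment = 0.5,
    habit_variables = c("urges", "mtss", "qa")
  )
}

check_props <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop("configuration error: proportions for ", what,
         " must be non-negative and sum to 1")
  }
}

# ---- configuration -------------------------------------------------------

#' Build a synthetic survey generator configuration
#'
#' Defaults emulate the learning-data margins of a large German smoker
#' survey: age from a truncated normal (sample mean 46.8, sd 16.7 on
#' [18, 99]), 46.6% female, three education and region levels, a
#' right-skewed standardised income on [0, 7] (moment-matched gamma),
#' six urges-to-smoke levels, and 96.5% current smokers.  Outcome
#' coefficients default to published odds ratios: the motivation model
#' includes a 4-knot restricted cubic spline in age whose effect is
#' damped with rising income (the age x income interaction) and the
#' quit-attempt model includes a sex x education interaction
#' (female:high OR 0.67).  Intercepts are calibrated numerically (under
#' an internal fixed seed) so that marginal outcome frequencies hit
#' their targets: 47.9% motivation-absence among current smokers and
#' 18.3% with at least one past-year quit attempt.
#'
#' @param n_records Positive integer number of respondents.
#' @param year_range Inclusive integer pair of survey years.
#' @param seed Integer seed; fully determines the generated table.
#' @param covariate_params,mtss_coefficients,qa_coefficients,missingness_params,mtss_expansion
#'   Named lists of overrides merged into the defaults.
#' @param calibrate Recalibrate outcome intercepts after overrides?
#'   (Skipped for an outcome whose intercept is overridden explicitly.)
#' @param n_calibration Sample size of the internal calibration draw.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_records, year_range = c(2016L, 2020L),
                             seed = 1L,
                             covariate_params = list(),
                             mtss_coefficients = list(),
                             qa_coefficients = list(),
                             missingness_params = list(),
                             mtss_expansion = list(),
                             calibrate = TRUE,
                             n_calibration = 20000L) {
  if (length(n_records) != 1L || !is.finite(n_records) || n_records < 1 ||
      n_records != floor(n_records)) {
    stop("configuration error: n_records must be a positive integer")
  }
  if (length(year_range) != 2L || year_range[2L] < year_range[1L]) {
    stop("configuration error: year_range must be an ordered pair")
  }
  cp <- utils::modifyList(default_covariate_params(), covariate_params)
  mc <- utils::modifyList(default_mtss_coefficients(), mtss_coefficients)
  qc <- utils::modifyList(default_qa_coefficients(), qa_coefficients)
  mp <- utils::modifyList(default_missingness_params(), missingness_params)
  me <- utils::modifyList(default_mtss_expansion(), mtss_expansion)

  check_props(cp$education_p, "education")
  check_props(cp$region_p, "region")
  check_props(cp$urges_p, "urges")
  check_props(me$cat2, "mtss expansion category 2")
  check_props(me$cat3, "mtss expansion category 3")
  check_props(qc$positive_split, "positive quit-attempt counts")
  if (cp$sex_p_female < 0 || cp$sex_p_female > 1 ||
      cp$p_current < 0 || cp$p_current > 1) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  for (b in list(cp$age, cp$income)) {
    if (b$lo >= b$hi || b$sd <= 0) {
      stop("configuration error: bounds must be ordered and sd positive")
    }
  }
  if (any(mp$rates < 0 | mp$rates > 1)) {
    stop("configuration error: missingness rates must lie in [0, 1]")
  }

  cfg <- structure(
    list(
      n_records = as.integer(n_records),
      year_range = as.integer(year_range),
      seed = as.integer(seed),
      covariate_params = cp,
      mtss_coefficients = mc,
      qa_coefficients = qc,
      missingness_params = mp,
      mtss_expansion = me,
      targets = list(
        mtss3_shares = c(absence = 4221, unspecific = 3308,
                         motivation = 1279) / 8808,
        qa_prevalence = 1689 / 9253
      ),
      age_tn = tn_solve(cp$age$mean, cp$age$sd, cp$age$lo, cp$age$hi)
    ),
    class = "generator_config"
  )

  if (calibrate) {
    cal_tab <- with_seed(987301L, {
      generate_covariates(cfg, n_override = as.integer(n_calibration),
                          reseed = FALSE)
    })
    if (is.null(mtss_coefficients$intercepts)) {
      cfg$mtss_coefficients$intercepts <-
        calibrate_mtss_intercepts(cal_tab, cfg)
    }
    if (is.null(qa_coefficients$intercept)) {
      cfg$qa_coefficients$intercept <- calibrate_qa_intercept(cal_tab, cfg)
    }
  }
  cfg
}

# ---- linear predictors ---------------------------------------------------

require_columns <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss)) {
    stop("specification error: coefficients reference absent covariate(s): ",
         paste(miss, collapse = ", "))
  }
}

# n x 2 matrix of motivation-model linear predictors (vs "absence").
mtss_linpred <- function(table, cf) {
  require_columns(table, c("age", "sex", "education", "region", "income",
                           "urges", "year"))
  n <- nrow(table)
  sp <- spline_spec(cf$age_spline$knots)
  Hage <- rcs_basis(as.numeric(table$age), sp) -
    matrix(rcs_basis(cf$age_spline$ref_age, sp), n, length(sp$knots) - 1L,
           byrow = TRUE)
  eta <- matrix(0, n, 2L, dimnames = list(NULL, cf$categories))
  for (k in 1:2) {
    cat <- cf$categories[k]
    e <- rep(cf$intercepts[[cat]], n)
    ul <- as.character(table$urges)
    idx <- match(ul, colnames(cf$urges))
    e <- e + ifelse(is.na(idx), 0, cf$urges[cat, ifelse(is.na(idx), 1L, idx)])
    yl <- as.character(table$year)
    yidx <- match(yl, colnames(cf$year))
    e <- e + ifelse(is.na(yidx), 0, cf$year[cat, ifelse(is.na(yidx), 1L, yidx)])
    e <- e + cf$sex_female[[cat]] * (table$sex == "female")
    el <- as.character(table$education)
    eidx <- match(el, colnames(cf$education))
    e <- e + ifelse(is.na(eidx), 0,
                    cf$education[cat, ifelse(is.na(eidx), 1L, eidx)])
    rl <- as.character(table$region)
    ridx <- match(rl, colnames(cf$region))
    e <- e + ifelse(is.na(ridx), 0, cf$region[cat, ifelse(is.na(ridx), 1L, ridx)])
    inc <- as.numeric(table$income)
    e <- e + cf$income[[cat]] * inc
    g <- as.vector(Hage %*% cf$age_spline$beta[cat, ])
    e <- e + g * (1 + cf$age_income_scale[[cat]] * inc)
    eta[, k] <- e
  }
  eta
}

# Quit-attempt logit linear predictor.
qa_linpred <- function(table, cf) {
  require_columns(table, c("age", "sex", "education", "region", "income",
                           "urges", "year"))
  ul <- as.character(table$urges)
  uidx <- match(ul, names(cf$urges))
  e <- rep(cf$intercept, nrow(table))
  e <- e + ifelse(is.na(uidx), 0, cf$urges[ifelse(is.na(uidx), 1L, uidx)])
  e <- e + cf$time_per_year * (as.numeric(table$year) - 2016)
  e <- e + cf$age_per_year * as.numeric(table$age)
  fem <- table$sex == "female"
  e <- e + cf$sex_female * fem
  el <- as.character(table$education)
  eidx <- match(el, names(cf$education))
  e <- e + ifelse(is.na(eidx), 0, cf$education[ifelse(is.na(eidx), 1L, eidx)])
  rl <- as.character(table$region)
  ridx <- match(rl, names(cf$region))
  e <- e + ifelse(is.na(ridx), 0, cf$region[ifelse(is.na(ridx), 1L, ridx)])
  e <- e + cf$income * as.numeric(table$income)
  e <- e + cf$sex_education[["female_middle"]] * (fem & el == "middle")
  e <- e + cf$sex_education[["female_high"]] * (fem & el == "high")
  as.numeric(e)
}

# ---- intercept calibration ----------------------------------------------

# Solve the two multinomial intercepts so that mean category
# probabilities over a covariate draw match the target collapsed shares.
calibrate_mtss_intercepts <- function(cal_tab, cfg) {
  cf <- cfg$mtss_coefficients
  cf$intercepts <- c(unspecific = 0, motivation = 0)
  cal_tab <- cal_tab[cal_tab$smoker_status == "current", , drop = FALSE]
  offs <- mtss_linpred(cal_tab, cf)
  target <- cfg$targets$mtss3_shares[c("unspecific", "motivation")]
  a <- c(0, 0)
  for (it in 1:50) {
    P <- softmax_probs(cbind(0, offs[, 1L] + a[1L], offs[, 2L] + a[2L]))
    sh <- colMeans(P)[2:3]
    J <- matrix(0, 2, 2)
    for (k in 1:2) {
      for (j in 1:2) {
        J[k, j] <- mean(P[, k + 1L] * ((k == j) - P[, j + 1L]))
      }
    }
    delta <- solve(J, target - sh)
    a <- a + delta
    if (max(abs(delta)) < 1e-10) break
  }
  c(unspecific = a[1L], motivation = a[2L])
}

# Solve the quit-attempt intercept so the marginal prevalence matches.
calibrate_qa_intercept <- function(cal_tab, cfg) {
  cf <- cfg$qa_coefficients
  cf$intercept <- 0
  off <- qa_linpred(cal_tab, cf)
  target <- cfg$targets$qa_prevalence
  stats::uniroot(function(a) mean(stats::plogis(off + a)) - target,
                 c(-20, 10), tol = 1e-12)$root
}

# ---- generation ----------------------------------------------------------

#' Generate survey covariates
#'
#' Draws `n_records` rows: age from a truncated normal whose realised
#' mean/sd match the configured values, sex/education/region/urges from
#' the configured categorical proportions, income from a moment-matched
#' gamma truncated to its bounds, year uniform over the year range, and
#' smoker status (current vs recent ex-smoker) with the configured
#' probability.  Fully deterministic given the config (incl. seed).
#'
#' @param config A [generator_config()].
#' @param n_override,reseed Internal (calibration) use.
#' @return Survey data frame with columns `id`, `year`, `age`, `sex`,
#'   `education`, `region`, `income`, `urges`, `smoker_status`.
#' @export
generate_covariates <- function(config, n_override = NULL, reseed = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  if (reseed) set.seed(config$seed)
  n <- if (is.null(n_override)) config$n_records else n_override
  cp <- config$covariate_params
  age <- rtruncnorm(n, config$age_tn[["mu"]], config$age_tn[["sigma"]],
                    cp$age$lo, cp$age$hi)
  sex <- factor(ifelse(stats::runif(n) < cp$sex_p_female, "female", "male"),
                levels = survey_levels$sex)
  education <- factor(
    sample(names(cp$education_p), n, replace = TRUE, prob = cp$education_p),
    levels = survey_levels$education
  )
  region <- factor(
    sample(names(cp$region_p), n, replace = TRUE, prob = cp$region_p),
    levels = survey_levels$region
  )
  shape <- (cp$income$mean / cp$income$sd)^2
  rate <- cp$income$mean / cp$income$sd^2
  income <- stats::rgamma(n, shape = shape, rate = rate)
  while (any(bad <- income > cp$income$hi | income < cp$income$lo)) {
    income[bad] <- stats::rgamma(sum(bad), shape = shape, rate = rate)
  }
  urges <- factor(
    sample(names(cp$urges_p), n, replace = TRUE, prob = cp$urges_p),
    levels = survey_levels$urges
  )
  year <- sample(seq(config$year_range[1L], config$year_range[2L]), n,
                 replace = TRUE)
  smoker_status <- factor(
    ifelse(stats::runif(n) < cp$p_current, "current", "recent_ex"),
    levels = survey_levels$smoker_status
  )
  data.frame(
    id = seq_len(n), year = as.integer(year), age = age, sex = sex,
    education = education, region = region, income = income, urges = urges,
    smoker_status = smoker_status, stringsAsFactors = FALSE
  )
}

#' Generate the 7-level motivation-to-stop outcome
#'
#' Draws the collapsed 3-category outcome from the configured
#' multinomial model (with its age x income interaction surface), then
#' expands category 2 to levels 2-3 and category 3 to levels 4-7 using
#' the configured conditional proportions.  Recent ex-smokers are not
#' assessed and receive `NA`.
#'
#' @param table Covariate table from [generate_covariates()].
#' @param config A [generator_config()].
#' @return `table` with an added integer column `mtss_level`.
#' @export
generate_mtss <- function(table, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  n <- nrow(table)
  level <- rep(NA_integer_, n)
  cur <- which(table$smoker_status == "current")
  if (length(cur)) {
    eta <- mtss_linpred(table[cur, , drop = FALSE], config$mtss_coefficients)
    P <- softmax_probs(cbind(0, eta))
    u <- stats::runif(length(cur))
    cat3 <- 1L + (u > P[, 1L]) + (u > P[, 1L] + P[, 2L])
    ex <- config$mtss_expansion
    lev <- integer(length(cur))
    lev[cat3 == 1L] <- 1L
    n2 <- sum(cat3 == 2L)
    if (n2) {
      lev[cat3 == 2L] <- sample(as.integer(names(ex$cat2)), n2,
                                replace = TRUE, prob = ex$cat2)
    }
    n3 <- sum(cat3 == 3L)
    if (n3) {
      lev[cat3 == 3L] <- sample(as.integer(names(ex$cat3)), n3,
                                replace = TRUE, prob = ex$cat3)
    }
    level[cur] <- lev
  }
  table$mtss_level <- level
  table
}

#' Generate the past-year quit-attempt count
#'
#' Draws at-least-one-attempt from the configured logistic model
#' (including the sex x education interaction); positive counts are
#' expanded to 1-3 attempts with fixed conditional proportions.
#'
#' @param table Covariate table.
#' @param config A [generator_config()].
#' @return `table` with an added integer column `n_quit_attempts`.
#' @export
generate_qa <- function(table, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2L)
  p <- stats::plogis(qa_linpred(table, config$qa_coefficients))
  any_qa <- stats::runif(nrow(table)) < p
  counts <- integer(nrow(table))
  npos <- sum(any_qa)
  if (npos) {
    split <- config$qa_coefficients$positive_split
    counts[any_qa] <- sample(as.integer(names(split)), npos,
                             replace = TRUE, prob = split)
  }
  table$n_quit_attempts <- counts
  table
}

#' Inject missing-at-random missingness
#'
#' Sets values missing via per-variable logistic models: the intercept
#' is solved so the marginal missingness rate matches the configured
#' target, and smoking-habit variables (urges, motivation level, quit
#' attempts) receive an additive log-odds increment for men with high
#' education.  Probabilities are computed on the pre-injection
#' (fully observed) table, so the mechanism is missing-at-random with
#' respect to observed covariates.  The motivation rate applies to
#' current smokers (recent ex-smokers are structurally missing already).
#'
#' @param table Complete survey table.
#' @param config A [generator_config()].
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, config) {
  stopifnot(inherits(config, "generator_config"))
  mp <- config$missingness_params
  if (any(mp$rates < 0 | mp$rates > 1)) {
    stop("configuration error: missingness rates must lie in [0, 1]")
  }
  set.seed(config$seed + 3L)
  male_high <- table$sex == "male" & table$education == "high"
  columns <- c(education = "education", urges = "urges",
               mtss = "mtss_level", qa = "n_quit_attempts",
               income = "income")
  for (var in names(mp$rates)) {
    r <- mp$rates[[var]]
    if (r <= 0) next
    col <- columns[[var]]
    if (!col %in% names(table)) next
    rows <- if (var == "mtss") which(table$smoker_status == "current") else seq_len(nrow(table))
    inc <- if (var %in% mp$habit_variables) mp$male_high_increment else 0
    s <- as.numeric(male_high[rows])
    if (inc != 0 && r < 1) {
      a <- stats::uniroot(function(a) mean(stats::plogis(a + inc * s)) - r,
                          c(-30, 30), tol = 1e-12)$root
      pmiss <- stats::plogis(a + inc * s)
    } else {
      pmiss <- rep(r, length(rows))
    }
    hit <- rows[stats::runif(length(rows)) < pmiss]
    table[[col]][hit] <- NA
  }
  table
}

#' Recode raw outcomes into analysis outcomes
#'
#' Adds the collapsed motivation category `mtss3` (level 1 = absence;
#' levels 2-3 = unspecific; levels 4-7 = motivation; missing propagates)
#' and the binary quit-attempt indicator `qa` (at least one attempt =
#' yes).  Idempotent: recomputing from the unchanged raw columns gives
#' the same result.
#'
#' @param table Survey table with `mtss_level` and/or `n_quit_attempts`.
#' @return The table with factor columns `mtss3` and `qa` added.
#' @export
recode_outcomes <- function(table) {
  if ("mtss_level" %in% names(table)) {
    lv <- table$mtss_level
    if (any(!is.na(lv) & (lv < 1 | lv > 7))) {
      stop("domain error: mtss_level outside 1-7")
    }
    table$mtss3 <- factor(
      ifelse(is.na(lv), NA_character_,
             ifelse(lv == 1, "absence",
                    ifelse(lv <= 3, "unspecific", "motivation"))),
      levels = survey_levels$mtss3
    )
  }
  if ("n_quit_attempts" %in% names(table)) {
    nq <- table$n_quit_attempts
    if (any(!is.na(nq) & nq < 0)) stop("domain error: negative quit attempts")
    table$qa <- factor(
      ifelse(is.na(nq), NA_character_, ifelse(nq >= 1, "yes", "no")),
      levels = survey_levels$qa
    )
  }
  table
}

#' Randomly split a table into learning and validation data
#'
#' Simple random partition without replacement; the learning size is
#' `n * fraction` rounded half to even, the validation part is the
#' remainder.  Disjoint and exhaustive for every fraction and seed.
#'
#' @param table Survey table.
#' @param fraction Learning fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `learning` and `validation`.
#' @export
split_learning_validation <- function(table, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n <- nrow(table)
  n_learn <- round(n * fraction)  # round-half-to-even
  idx <- with_seed(seed, sample.int(n, n_learn))
  list(
    learning = table[sort(idx), , drop = FALSE],
    validation = table[setdiff(seq_len(n), idx), , drop = FALSE]
  )
}

#' Simulate a complete synthetic survey
#'
#' Runs [generate_covariates()], [generate_mtss()], [generate_qa()] and
#' [inject_missingness()] in sequence.
#'
#' @param config A [generator_config()].
#' @param missingness Inject missingness? (Default `TRUE`.)
#' @return Survey data frame.
#' @export
simulate_survey <- function(config, missingness = TRUE) {
  tab <- generate_covariates(config)
  tab <- generate_mtss(tab, config)
  tab <- generate_qa(tab, config)
  if (missingness) tab <- inject_missingness(tab, config)
  tab
}
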