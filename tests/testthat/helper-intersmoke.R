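# Shared fixtures and independent oracles for the test suite.

# Quit-attempt coefficients with the sex x education interaction
# switched off (null-interaction generator).
null_interaction_qa <- function() {
  list(sex_education = c(female_middle = 0, female_high = 0))
}

# A small complete synthetic survey, recoded for analysis.
small_survey <- function(n = 2000, seed = 1, missingness = FALSE, ...) {
  cfg <- generator_config(n, seed = seed, ...)
  recode_outcomes(simulate_survey(cfg, missingness = missingness))
}

# Exhaustive-enumeration PDI oracle for K = 3 (independent of the
# package's sort-and-count implementation): loops over every tuple of
# one observation per category, splitting ties 1/t.
pdi_exhaustive3 <- function(y, P) {
  lev <- colnames(P)
  idx <- lapply(lev, function(l) which(y == l))
  total <- 0
  for (j in seq_along(lev)) {
    s <- 0
    for (i1 in idx[[1]]) {
      for (i2 in idx[[2]]) {
        for (i3 in idx[[3]]) {
          v <- c(P[i1, j], P[i2, j], P[i3, j])
          mx <- max(v)
          if (v[j] == mx) s <- s + 1 / sum(v == mx)
        }
      }
    }
    total <- total + s / prod(lengths(idx))
  }
  total / length(lev)
}

# Compact candidate space used in selection tests: linear-or-spline age
# plus the sex x education interaction (4 candidates).
qa_test_space <- function() {
  candidate_space(
    "qa",
    spline_options = list(age = c("linear", "rcs4"), income = "linear"),
    interaction_pool = list(c("sex", "education")),
    max_interactions = 1L
  )
}

# The data-generating quit-attempt specification.
qa_true_spec <- function() {
  model_spec(
    "qa",
    terms = c(age = "linear", income = "linear", sex = "cat",
              education = "cat", region = "cat", urges = "cat",
              year = "linear"),
    interactions = list(c("sex", "education"))
  )
}
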