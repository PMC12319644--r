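#' @keywords internal
"_PACKAGE"

# Canonical level sets of the survey schema.  Every factor column in a
# survey table carries exactly these levels so that dummy coding and
# CSV round trips are stable.
survey_levels <- list(
  sex = c("male", "female"),
  education = c("low", "middle", "high"),
  region = c("rural", "urban", "metropolitan"),
  urges = c("none", "light", "medium_strong", "strong",
            "very_strong", "extremely_strong"),
  smoker_status = c("current", "recent_ex"),
  mtss3 = c("absence", "unspecific", "motivation"),
  qa = c("no", "yes")
)

#' Default reference levels for dummy coding
#'
#' Male sex, low education, rural region, medium-strong urges, the first
#' survey year and the "absence of motivation" outcome category act as
#' references throughout.
#' @return Named list of reference levels.
#' @export
default_references <- function() {
  list(
    sex = "male", education = "low", region = "rural",
    urges = "medium_strong", year = "2016",
    mtss3 = "absence", qa = "no"
  )
}

survey_factor <- function(x, var) {
  lev <- survey_levels[[var]]
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x) & x != ""]), lev)
  if (length(bad)) {
    stop("unknown level(s) for '", var, "': ", paste(bad, collapse = ", "))
  }
  x[x == ""] <- NA
  factor(x, levels = lev)
}

#' Write a survey table to CSV
#'
#' Missing values are encoded as empty fields; factor columns are
#' written as their level labels.
#' @param table Survey data frame.
#' @param path Output file path.
#' @export
write_survey <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a survey table from CSV
#'
#' Restores the canonical factor levels and column types produced by
#' [generate_covariates()] / [write_survey()].
#' @param path CSV file path.
#' @return Survey data frame.
#' @export
read_survey <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (var in intersect(names(survey_levels), names(raw))) {
    raw[[var]] <- survey_factor(raw[[var]], var)
  }
  for (var in intersect(c("id", "year", "mtss_level", "n_quit_attempts"),
                        names(raw))) {
    raw[[var]] <- as.integer(raw[[var]])
  }
  raw
}

#' Number of cells in a full cross-stratification
#'
#' The heuristic alternative to model-based intersection analysis
#' stratifies on every covariate jointly; the number of strata is the
#' product of the per-dimension level counts (e.g. sex x three-level
#' age x education x income x region gives 2 x 3 x 3 x 3 x 3 = 162).
#'
#' @param levels_per_dimension Non-empty vector of positive integers.
#' @return Integer: the product of the entries.
#' @export
count_full_strata <- function(levels_per_dimension) {
  x <- as.numeric(levels_per_dimension)
  if (length(x) == 0L || any(!is.finite(x)) || any(x < 1) ||
      any(x != floor(x))) {
    stop("levels_per_dimension must be a non-empty vector of positive integers")
  }
  as.integer(prod(x))
}

# Run a block of code with an isolated RNG state: restores .Random.seed
# afterwards so helper draws do not perturb the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
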