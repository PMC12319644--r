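# Candidate-model enumeration and bootstrap out-of-bag selection.
#
# The candidate space crosses the allowed functional forms of the
# continuous covariates (linear or restricted cubic splines with 3-5
# knots) with subsets of pairwise interactions among the five
# intersectionality covariates (age, sex, education, income, region).
# Within the learning data, repeated bootstrap samples act as inner
# learning data and their out-of-bag complements as inner validation
# data; the model with the best average out-of-bag score (highest PDI
# for the motivation outcome, lowest Brier score for quit attempts)
# wins, and any interaction it contains is confirmed by a pooled
# likelihood-ratio test.

intersection_covariates <- c("age", "sex", "education", "income", "region")

#' Define a candidate model space
#'
#' @param outcome `"mtss3"` or `"qa"`.
#' @param base_terms Named character vector of always-included covariates
#'   and their fixed forms.  Defaults: urges categorical, year
#'   categorical for the multinomial outcome and linear for the binary
#'   one, sex/education/region categorical.
#' @param spline_options Named list: allowed forms per continuous
#'   covariate, each a subset of `c("linear", "rcs3", "rcs4", "rcs5")`.
#' @param interaction_pool List of unordered covariate pairs eligible as
#'   interactions; defaults to all pairs among the five
#'   intersectionality covariates.  Duplicates are an error.
#' @param max_interactions Maximum number of interaction terms per
#'   candidate (default 1).
#' @return Object of class `candidate_space`.
#' @export
candidate_space <- function(outcome = c("mtss3", "qa"),
                            base_terms = NULL,
                            spline_options = list(
                              age = c("linear", "rcs4"),
                              income = c("linear", "rcs4")
                            ),
                            interaction_pool = NULL,
                            max_interactions = 1L) {
  outcome <- match.arg(outcome)
  if (is.null(base_terms)) {
    base_terms <- c(
      urges = "cat", year = if (outcome == "qa") "linear" else "cat",
      sex = "cat", education = "cat", region = "cat"
    )
  }
  if (max_interactions < 0L) stop("max_interactions must be >= 0")
  if (is.null(interaction_pool)) {
    covs <- intersection_covariates
    interaction_pool <- utils::combn(covs, 2L, simplify = FALSE)
  }
  keys <- vapply(interaction_pool, function(pr) {
    paste(sort(pr), collapse = ":")
  }, character(1))
  if (anyDuplicated(keys)) stop("duplicate pair in interaction_pool")
  all_covs <- c(names(base_terms), names(spline_options))
  for (pr in interaction_pool) {
    if (!all(pr %in% all_covs)) {
      stop("interaction pool member outside the term set: ",
           paste(pr, collapse = ":"))
    }
  }
  structure(
    list(outcome = outcome, base_terms = base_terms,
         spline_options = spline_options,
         interaction_pool = interaction_pool,
         max_interactions = as.integer(max_interactions)),
    class = "candidate_space"
  )
}

#' Enumerate all candidate model specifications
#'
#' Cartesian product of the spline options over continuous covariates
#' and interaction subsets of size up to `max_interactions`; every
#' candidate includes the base terms, and interaction members are
#' always present among the terms (hierarchy).
#'
#' @param space A [candidate_space()].
#' @return List of [model_spec()]s.
#' @export
enumerate_candidates <- function(space) {
  stopifnot(inherits(space, "candidate_space"))
  form_grid <- expand.grid(space$spline_options, stringsAsFactors = FALSE)
  if (nrow(form_grid) == 0L) form_grid <- data.frame(row.names = 1L)
  subsets <- list(list())
  if (space$max_interactions > 0L && length(space$interaction_pool)) {
    for (sz in seq_len(min(space$max_interactions,
                           length(space$interaction_pool)))) {
      combos <- utils::combn(seq_along(space$interaction_pool), sz,
                             simplify = FALSE)
      subsets <- c(subsets, lapply(combos, function(ix) {
        space$interaction_pool[ix]
      }))
    }
  }
  out <- list()
  for (i in seq_len(max(1L, nrow(form_grid)))) {
    forms <- if (ncol(form_grid)) unlist(form_grid[i, , drop = FALSE]) else character(0)
    terms <- c(space$base_terms, forms)
    for (ints in subsets) {
      out[[length(out) + 1L]] <- model_spec(
        outcome = space$outcome, terms = terms, interactions = ints
      )
    }
  }
  out
}

spec_label <- function(spec) {
  forms <- paste(names(spec$terms), spec$terms, sep = "=", collapse = ",")
  ints <- if (length(spec$interactions)) {
    paste(vapply(spec$interactions, paste, character(1), collapse = ":"),
          collapse = "+")
  } else {
    "none"
  }
  paste0(forms, " | ", ints)
}

has_interaction <- function(spec, pair) {
  any(vapply(spec$interactions, function(pr) {
    setequal(pr, pair)
  }, logical(1)))
}

score_predictions <- function(rule, y, pred) {
  if (rule == "brier") brier_score(y, pred)$value else pdi(y, pred)$value
}

#' Bootstrap out-of-bag model selection
#'
#' For each of `B` replicates, ids are drawn with replacement (the
#' inner learning data); the out-of-bag ids form the inner validation
#' data.  Every candidate is fitted on the inner learning rows of every
#' imputed data set and scored on the out-of-bag rows; scores are
#' averaged over imputations, and after `B` replicates the candidate
#' with the best mean score wins (highest PDI or lowest Brier score).
#' Replicates in which a factor level or outcome category is missing
#' from the bootstrap sample (or the out-of-bag part, for the PDI) are
#' redrawn up to `max_retry` times, then skipped and logged.
#'
#' @param imputation_set An `imputation_set` (use [as_imputation_set()]
#'   for complete data).
#' @param candidates List of [model_spec()]s sharing one outcome.
#' @param B Number of bootstrap replicates (at least 50).
#' @param rule `"pdi"` (multinomial outcome) or `"brier"` (binary).
#' @param seed Integer seed; fully determines the replicate draws.
#' @param max_retry Redraw attempts per degenerate replicate.
#' @return Object of class `selection_result`: `winner` (frozen
#'   [model_spec()]), `winner_index`, `scores` (candidates x B matrix),
#'   `mean_scores`, `rule`, `B`, `skipped` (replicate indices),
#'   `labels`.
#' @export
bootstrap_select <- function(imputation_set, candidates, B = 200L,
                             rule = c("pdi", "brier"), seed = 1L,
                             max_retry = 10L) {
  rule <- match.arg(rule)
  if (B < 50L) stop("B must be at least 50")
  if (!length(candidates)) stop("no candidates supplied")
  outcome <- candidates[[1L]]$outcome
  if (rule == "pdi" && outcome != "mtss3") {
    stop("the PDI applies to the multinomial outcome")
  }
  if (rule == "brier" && outcome != "qa") {
    stop("the Brier score applies to the binary outcome")
  }
  m <- imputation_set$m
  first <- imputation_set$completed[[1L]]
  candidates <- lapply(candidates, function(sp) {
    if (sp$frozen) sp else freeze_spec(sp, first)
  })
  C <- length(candidates)

  # designs built once per (imputation, candidate); bootstrap replicates
  # only subset rows
  designs <- vector("list", m)
  starts <- vector("list", m)
  rows_ref <- NULL
  for (l in seq_len(m)) {
    designs[[l]] <- lapply(candidates, function(sp) {
      build_design(imputation_set$completed[[l]], sp)
    })
    rows_l <- designs[[l]][[1L]]$rows
    if (is.null(rows_ref)) rows_ref <- rows_l
    same <- vapply(designs[[l]], function(d) identical(d$rows, rows_ref),
                   logical(1))
    if (!all(same)) {
      stop("candidates use different analysis rows; ",
           "impute or subset the data first")
    }
    if (outcome == "mtss3") {
      starts[[l]] <- lapply(designs[[l]], function(d) {
        fit_multinomial(d$X, d$y)$coefficients
      })
    }
  }
  n <- length(rows_ref)

  # factor levels to verify per replicate (checked on the first
  # completed data set; fit failures elsewhere are caught and skipped)
  cat_covs <- unique(unlist(lapply(candidates, function(sp) {
    names(sp$terms)[sp$terms == "cat"]
  })))
  tab1 <- first[rows_ref, , drop = FALSE]
  cat_vals <- lapply(cat_covs, function(v) as.character(tab1[[v]]))
  names(cat_vals) <- cat_covs
  cat_levels <- lapply(cat_vals, unique)
  y1 <- designs[[1L]][[1L]]$y
  y_chr <- as.character(y1)
  y_levels <- unique(y_chr)

  replicate_ok <- function(idx, oob) {
    if (!length(oob)) return(FALSE)
    for (v in cat_covs) {
      if (!all(cat_levels[[v]] %in% unique(cat_vals[[v]][idx]))) return(FALSE)
    }
    if (!all(y_levels %in% unique(y_chr[idx]))) return(FALSE)
    if (rule == "pdi" && !all(y_levels %in% unique(y_chr[oob]))) return(FALSE)
    TRUE
  }

  set.seed(seed)
  scores <- matrix(NA_real_, C, B)
  skipped <- integer(0)
  for (b in seq_len(B)) {
    idx <- NULL
    for (try in seq_len(max_retry + 1L)) {
      cand_idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), cand_idx)
      if (replicate_ok(cand_idx, oob)) {
        idx <- cand_idx
        break
      }
    }
    if (is.null(idx)) {
      skipped <- c(skipped, b)
      next
    }
    for (ci in seq_len(C)) {
      vals <- numeric(m)
      ok <- TRUE
      for (l in seq_len(m)) {
        d <- designs[[l]][[ci]]
        val <- tryCatch({
          if (outcome == "qa") {
            f <- suppressWarnings(fit_logistic(d$X[idx, , drop = FALSE],
                                               d$y[idx]))
            p <- stats::plogis(as.vector(d$X[oob, , drop = FALSE] %*%
                                           f$coefficients))
            score_predictions(rule, d$y[oob], p)
          } else {
            f <- suppressWarnings(fit_multinomial(
              d$X[idx, , drop = FALSE], d$y[idx], start = starts[[l]][[ci]]
            ))
            P <- predict_probs_design(f, d$X[oob, , drop = FALSE])
            score_predictions(rule, droplevels(d$y[oob]), P)
          }
        }, error = function(e) NA_real_)
        if (is.na(val)) {
          ok <- FALSE
          break
        }
        vals[l] <- val
      }
      if (ok) scores[ci, b] <- mean(vals)
    }
  }
  mean_scores <- rowMeans(scores, na.rm = TRUE)
  n_scored <- rowSums(!is.na(scores))
  if (all(n_scored == 0L)) stop("all bootstrap replicates failed or were skipped")
  mean_scores[n_scored == 0L] <- if (rule == "pdi") -Inf else Inf
  winner_index <- if (rule == "pdi") which.max(mean_scores) else which.min(mean_scores)
  structure(
    list(winner = candidates[[winner_index]], winner_index = winner_index,
         candidates = candidates, scores = scores,
         mean_scores = mean_scores, rule = rule, B = as.integer(B),
         skipped = skipped, disqualified = which(n_scored == 0L),
         labels = vapply(candidates, spec_label, character(1)),
         lr_confirmation = NULL),
    class = "selection_result"
  )
}

pooled_bic <- function(imputation_set, spec) {
  spec <- if (spec$frozen) spec else freeze_spec(spec, imputation_set$completed[[1L]])
  mean(vapply(imputation_set$completed, function(tab) {
    bic(fit_model(tab, spec))
  }, numeric(1)))
}

reduce_form <- function(form) if (is_rcs_form(form)) "linear" else NULL

#' Backward elimination under pooled BIC
#'
#' Iteratively applies the single admissible simplification that most
#' decreases the pooled BIC (mean BIC over imputed data sets), until no
#' simplification decreases it.  Admissible moves honour the model
#' hierarchy: interactions are removed before their main effects, a
#' spline is reduced to linear before its covariate may be dropped, and
#' protected (base) terms are never dropped.
#'
#' @param imputation_set An `imputation_set`.
#' @param full_spec Starting [model_spec()].
#' @param protected Covariates that may change form but are never
#'   dropped (default: urges and year).
#' @return The BIC-optimal simplified `model_spec`.
#' @export
backward_eliminate <- function(imputation_set, full_spec,
                               protected = c("urges", "year")) {
  spec <- if (full_spec$frozen) full_spec else freeze_spec(full_spec, imputation_set$completed[[1L]])
  current_bic <- pooled_bic(imputation_set, spec)
  repeat {
    moves <- list()
    for (i in seq_along(spec$interactions)) {
      cand <- spec
      cand$interactions <- spec$interactions[-i]
      moves[[length(moves) + 1L]] <- cand
    }
    in_interaction <- unique(unlist(spec$interactions))
    for (cov in names(spec$terms)) {
      form <- spec_form(spec, cov)
      red <- reduce_form(form)
      if (!is.null(red)) {
        cand <- spec
        cand$terms[[cov]] <- red
        moves[[length(moves) + 1L]] <- cand
      }
      if (!cov %in% protected && !cov %in% in_interaction &&
          !is_rcs_form(form)) {
        cand <- spec
        cand$terms <- spec$terms[names(spec$terms) != cov]
        moves[[length(moves) + 1L]] <- cand
      }
    }
    if (!length(moves)) break
    bics <- vapply(moves, function(cand) pooled_bic(imputation_set, cand),
                   numeric(1))
    best <- which.min(bics)
    if (bics[best] >= current_bic) break
    spec <- moves[[best]]
    current_bic <- bics[best]
  }
  spec
}

#' Best-subset selection via bootstrap scoring
#'
#' Exhaustively evaluates every candidate of the space with
#' [bootstrap_select()]; the route used for the multinomial outcome,
#' where stepwise selection machinery is not available.
#'
#' @inheritParams bootstrap_select
#' @param space A [candidate_space()].
#' @return A `selection_result`; `n_candidates` records the size of the
#'   enumeration.
#' @export
best_subset <- function(imputation_set, space, rule = "pdi", B = 200L,
                        seed = 1L) {
  cands <- enumerate_candidates(space)
  res <- bootstrap_select(imputation_set, cands, B = B, rule = rule,
                          seed = seed)
  res$n_candidates <- length(cands)
  res
}

#' Confirm a winning interaction by pooled likelihood-ratio test
#'
#' If the winning specification contains interaction terms, it is
#' tested against the same specification without them: by the
#' Meng-Rubin pooled likelihood-ratio test when `m >= 2`, by a plain
#' likelihood-ratio test for complete data (`m = 1`).  The interaction
#' is retained iff `p < alpha`.  A winner without interactions passes
#' vacuously.
#'
#' @param selection A `selection_result` (or a bare [model_spec()]).
#' @param imputation_set The `imputation_set` used for selection.
#' @param alpha Significance level (default 0.05).
#' @return The `selection_result` with `lr_confirmation` filled in and
#'   `final` set to the confirmed spec (interactions stripped when not
#'   retained).
#' @export
confirm_interaction <- function(selection, imputation_set, alpha = 0.05) {
  if (inherits(selection, "model_spec")) {
    selection <- structure(
      list(winner = selection, lr_confirmation = NULL),
      class = "selection_result"
    )
  }
  winner <- selection$winner
  if (!length(winner$interactions)) {
    selection$lr_confirmation <- list(statistic = NA_real_, df = NA_integer_,
                                      p = NA_real_, retained = TRUE,
                                      vacuous = TRUE)
    selection$final <- winner
    return(selection)
  }
  reduced <- winner
  reduced$interactions <- list()
  if (imputation_set$m >= 2L) {
    lt <- pool_lr(winner, reduced, imputation_set)
    conf <- list(statistic = lt$statistic, df = lt$df, p = lt$p,
                 retained = lt$p < alpha, vacuous = FALSE)
  } else {
    tab <- imputation_set$completed[[1L]]
    ff <- fit_model(tab, winner)
    fr <- fit_model(tab, reduced)
    lt <- lr_test(ff, fr)
    conf <- list(statistic = lt$statistic, df = lt$df, p = lt$p,
                 retained = lt$p < alpha, vacuous = FALSE)
  }
  selection$lr_confirmation <- conf
  selection$final <- if (conf$retained) winner else reduced
  selection
}
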