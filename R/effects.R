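# Result surfaces: pooled odds-ratio tables, marginal predicted-
# probability grids, and external validation of the winning model.

# Point estimate and variance of a continuous-covariate contrast,
# per outcome category (shared by evaluate_contrast and the pooled
# odds-ratio table).
contrast_components <- function(fit, covariate, v, reference) {
  spec <- fit$spec
  form <- spec_form(spec, covariate)
  basis_row <- function(val) {
    if (form == "linear") matrix(val, ncol = 1L) else rcs_basis(val, spec$splines[[covariate]])
  }
  L <- as.vector(basis_row(v) - basis_row(reference))
  main_cols <- fit$column_map$column[fit$column_map$term == covariate &
                                       fit$column_map$type == "main"]
  cats <- if (fit$family == "binomial") "yes" else fit$outcome_levels[-1L]
  out <- lapply(cats, function(cat) {
    if (fit$family == "binomial") {
      est <- sum(L * fit$coefficients[main_cols])
      Vm <- fit$vcov[main_cols, main_cols, drop = FALSE]
    } else {
      est <- sum(L * fit$coefficients[cat, main_cols])
      pn <- paste(cat, main_cols, sep = ":")
      Vm <- fit$vcov[pn, pn, drop = FALSE]
    }
    data.frame(category = cat, est = est,
               var = max(0, as.vector(t(L) %*% Vm %*% L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

coef_rows <- function(fit) {
  # one row per (category, column) with estimate and variance
  cm <- fit$column_map
  if (fit$family == "binomial") {
    data.frame(category = "yes", column = names(fit$coefficients),
               est = unname(fit$coefficients),
               var = unname(diag(fit$vcov)),
               stringsAsFactors = FALSE)
  } else {
    cats <- fit$outcome_levels[-1L]
    do.call(rbind, lapply(cats, function(cat) {
      pn <- paste(cat, colnames(fit$coefficients), sep = ":")
      data.frame(category = cat, column = colnames(fit$coefficients),
                 est = unname(fit$coefficients[cat, ]),
                 var = unname(diag(fit$vcov)[pn]),
                 stringsAsFactors = FALSE)
    }))
  }
}

#' Pooled odds-ratio table
#'
#' Pools each coefficient of `m` fits of one specification across
#' imputed data sets by Rubin's rules on the log-odds scale, then
#' exponentiates.  Spline-coded continuous covariates are reported as
#' contrasts at specified covariate values against a reference value,
#' pooled the same way.  Reference rows (OR exactly 1) are included for
#' categorical covariates.
#'
#' @param fits List of `fit_result`s sharing one [model_spec()] (one
#'   per imputed data set).
#' @param contrasts Optional named list: per continuous covariate a
#'   list with `values` and `ref`, e.g.
#'   `list(age = list(values = seq(30, 80, 10), ref = 20))`.
#' @param level Confidence level.
#' @return Data frame of class `pooled_or_table` with columns
#'   `category`, `term`, `label`, `or`, `lo`, `hi`, `reference`, `m`.
#' @export
pooled_or_table <- function(fits, contrasts = NULL, level = 0.95) {
  if (!length(fits)) stop("no fits supplied")
  m <- length(fits)
  spec <- fits[[1L]]$spec
  rows_list <- lapply(fits, coef_rows)
  base <- rows_list[[1L]]
  ests <- sapply(rows_list, function(r) r$est)
  vars <- sapply(rows_list, function(r) r$var)
  ests <- matrix(ests, nrow = nrow(base))
  vars <- matrix(vars, nrow = nrow(base))
  cm <- fits[[1L]]$column_map
  out <- list()
  for (i in seq_len(nrow(base))) {
    term <- cm$term[match(base$column[i], cm$column)]
    form <- if (term %in% names(spec$terms)) spec$terms[[term]] else NULL
    # spline-coded covariates are reported via contrasts, not raw
    # coefficients; skip their per-column rows here
    if (!is.null(form) && is_rcs_form(form)) next
    pl <- pool_scalar(ests[i, ], vars[i, ], level = level)
    out[[length(out) + 1L]] <- data.frame(
      category = base$category[i], term = term, label = base$column[i],
      or = exp(pl$estimate), lo = exp(pl$ci[1L]), hi = exp(pl$ci[2L]),
      reference = FALSE, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  # reference rows for categorical covariates
  cats <- unique(tab$category)
  for (cov in names(spec$terms)) {
    if (spec$terms[[cov]] != "cat") next
    ref <- spec$factor_levels[[cov]][1L]
    for (cat in cats) {
      tab <- rbind(tab, data.frame(
        category = cat, term = cov, label = paste0(cov, ref, " (ref)"),
        or = 1, lo = 1, hi = 1, reference = TRUE, stringsAsFactors = FALSE
      ))
    }
  }
  if (!is.null(contrasts)) {
    for (cov in names(contrasts)) {
      cc <- contrasts[[cov]]
      for (v in cc$values) {
        comp <- lapply(fits, contrast_components, covariate = cov, v = v,
                       reference = cc$ref)
        cats_c <- comp[[1L]]$category
        for (j in seq_along(cats_c)) {
          pl <- pool_scalar(
            vapply(comp, function(d) d$est[j], numeric(1)),
            vapply(comp, function(d) d$var[j], numeric(1)),
            level = level
          )
          tab <- rbind(tab, data.frame(
            category = cats_c[j], term = cov,
            label = paste0(cov, " ", v, " vs ", cc$ref),
            or = exp(pl$estimate), lo = exp(pl$ci[1L]),
            hi = exp(pl$ci[2L]), reference = v == cc$ref,
            stringsAsFactors = FALSE
          ))
        }
      }
    }
  }
  attr(tab, "m") <- m
  class(tab) <- c("pooled_or_table", class(tab))
  tab
}

# Average marginal prediction for one completed data set: returns, per
# grid cell and outcome category, the mean predicted probability and
# its delta-method variance.
marginal_one_dataset <- function(fit, tab, grid) {
  spec <- fit$spec
  res <- list()
  for (g in seq_len(nrow(grid))) {
    tab2 <- tab
    for (v in names(grid)) tab2[[v]] <- grid[[v]][g]
    d <- build_design(tab2, spec, require_outcome = FALSE)
    X <- d$X
    n <- nrow(X)
    if (fit$family == "binomial") {
      p <- stats::plogis(as.vector(X %*% fit$coefficients))
      pbar <- mean(p)
      grad <- crossprod(X, p * (1 - p)) / n
      vr <- as.vector(t(grad) %*% fit$vcov %*% grad)
      res[[length(res) + 1L]] <- data.frame(
        cell = g, category = "yes", probability = pbar, var = max(0, vr)
      )
    } else {
      P <- predict_probs_design(fit, X)
      K <- ncol(P)
      cats <- fit$outcome_levels
      p_cols <- ncol(X)
      for (k in seq_len(K)) {
        pbar <- mean(P[, k])
        grad <- numeric((K - 1L) * p_cols)
        for (j in 2:K) {
          w <- P[, k] * ((j == k) - P[, j])
          grad[((j - 2L) * p_cols + 1L):((j - 1L) * p_cols)] <-
            crossprod(X, w) / n
        }
        vr <- as.vector(t(grad) %*% fit$vcov %*% grad)
        res[[length(res) + 1L]] <- data.frame(
          cell = g, category = cats[k], probability = pbar, var = max(0, vr)
        )
      }
    }
  }
  do.call(rbind, res)
}

#' Marginal predicted-probability grid
#'
#' For every grid cell, the grid covariates are set to the cell values
#' for every record and the model's predicted probabilities are
#' averaged over the empirical distribution of all other covariates
#' (average marginal prediction / marginal standardisation), per
#' imputed data set; point estimates and delta-method variances are
#' pooled across imputations on the logit scale and back-transformed.
#'
#' @param fits List of `fit_result`s, one per completed data set.
#' @param imputation_set The matching `imputation_set`.
#' @param grid_axes Named list of grid values, e.g.
#'   `list(age = seq(20, 80, 10), income = c(0.5, 1.5, 2.5))`.
#' @param level Confidence level.
#' @return Data frame: grid axes, `category`, `probability`, `lo`,
#'   `hi`, `extrapolated`.
#' @export
marginal_probabilities <- function(fits, imputation_set, grid_axes,
                                   level = 0.95) {
  m <- length(fits)
  if (m != imputation_set$m) {
    stop("need exactly one fit per completed data set")
  }
  grid <- expand.grid(grid_axes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  per <- lapply(seq_len(m), function(l) {
    marginal_one_dataset(fits[[l]], imputation_set$completed[[l]], grid)
  })
  base <- per[[1L]]
  eps <- 1e-12
  out <- list()
  spec <- fits[[1L]]$spec
  for (i in seq_len(nrow(base))) {
    p_l <- vapply(per, function(d) d$probability[i], numeric(1))
    v_l <- vapply(per, function(d) d$var[i], numeric(1))
    p_l <- pmin(pmax(p_l, eps), 1 - eps)
    logit <- stats::qlogis(p_l)
    v_logit <- v_l / (p_l * (1 - p_l))^2
    pl <- pool_scalar(logit, v_logit, level = level)
    cell <- base$cell[i]
    extrap <- FALSE
    for (v in names(grid)) {
      rng <- spec$ranges[[v]]
      if (!is.null(rng) &&
          (grid[[v]][cell] < rng[1L] || grid[[v]][cell] > rng[2L])) {
        extrap <- TRUE
      }
    }
    row <- grid[cell, , drop = FALSE]
    row$category <- base$category[i]
    row$probability <- mean(p_l)
    row$lo <- stats::plogis(pl$ci[1L])
    row$hi <- stats::plogis(pl$ci[2L])
    row$extrapolated <- extrap
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

pooled_coef_fit <- function(fits) {
  pooled <- fits[[1L]]
  if (is.matrix(pooled$coefficients)) {
    arr <- simplify2array(lapply(fits, `[[`, "coefficients"))
    pooled$coefficients <- apply(arr, c(1L, 2L), mean)
  } else {
    pooled$coefficients <- rowMeans(sapply(fits, `[[`, "coefficients"))
  }
  pooled
}

#' External validation of the winning model
#'
#' Refits the winner on each learning imputation, pools the
#' coefficients, predicts every validation imputation with the pooled
#' coefficients (spline knots frozen from the learning data), and
#' reports the scoring rule on learning (in-sample) and validation
#' data together with the percent accuracy change.
#'
#' @param winner The winning [model_spec()] (error if missing).
#' @param learn_set,valid_set `imputation_set`s for learning and
#'   validation data.
#' @param rule `"pdi"` or `"brier"`.
#' @return List with `rule`, `score_learn`, `score_valid`,
#'   `change_pct`, `fits` (learning fits) and `pooled_fit`.
#' @export
external_validate <- function(winner, learn_set, valid_set,
                              rule = c("pdi", "brier")) {
  rule <- match.arg(rule)
  if (is.null(winner) || !inherits(winner, "model_spec")) {
    stop("winner specification is missing")
  }
  if (!winner$frozen) winner <- freeze_spec(winner, learn_set$completed[[1L]])
  fits <- lapply(learn_set$completed, function(tab) fit_model(tab, winner))
  pooled <- pooled_coef_fit(fits)
  score_on <- function(tab) {
    d <- build_design(tab, winner)
    pred <- predict_probs_design(pooled, d$X)
    if (rule == "brier") {
      brier_score(d$y, pred)$value
    } else {
      pdi(droplevels(d$y), pred)$value
    }
  }
  s_learn <- mean(vapply(learn_set$completed, score_on, numeric(1)))
  s_valid <- mean(vapply(valid_set$completed, score_on, numeric(1)))
  list(rule = rule, score_learn = s_learn, score_valid = s_valid,
       change_pct = accuracy_change(s_learn, s_valid, rule),
       fits = fits, pooled_fit = pooled)
}
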