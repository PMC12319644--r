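# Chained-equations multiple imputation and pooling rules.
#
# The imputation model conditions every incomplete variable on all
# intersectionality measures (age, sex, education, income, region),
# the urges confounder, survey year and the outcomes.  Continuous
# variables use predictive mean matching (5 donors, type-1 matching
# with a posterior draw of the regression coefficients), binary
# variables logistic draws, unordered categorical variables multinomial
# draws.  The collapsed 3-category motivation outcome is imputed (not
# the 7-level scale) and only for current smokers: for recent
# ex-smokers it is structurally missing and stays so.

imputable_vars <- c("age", "income", "education", "region", "urges",
                    "mtss3", "qa")
predictor_vars <- c("age", "income", "sex", "education", "region",
                    "urges", "year", "mtss3", "qa")

impute_method <- function(var) {
  switch(var,
    age = , income = "pmm",
    qa = "logistic",
    education = , region = , urges = , mtss3 = "multinomial",
    stop("no imputation method for '", var, "'")
  )
}

# Numeric design matrix (with intercept) from the current completed
# values of the predictors, excluding the target variable.  mtss3 gets
# an explicit "not_assessed" level for recent ex-smokers so it remains
# usable as a predictor.
imputation_design <- function(tab, target) {
  preds <- setdiff(intersect(predictor_vars, names(tab)), target)
  cols <- list(`(Intercept)` = rep(1, nrow(tab)))
  for (v in preds) {
    x <- tab[[v]]
    if (v == "mtss3") {
      x <- as.character(x)
      x[is.na(x)] <- "not_assessed"
      x <- factor(x, levels = c(survey_levels$mtss3, "not_assessed"))
    }
    if (is.factor(x)) {
      x <- droplevels(x)
      for (l in levels(x)[-1L]) {
        cols[[paste0(v, l)]] <- as.numeric(x == l)
      }
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  # guard against constant or collinear columns in small chains
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2, stats::sd) > 0)
  X <- X[, keep, drop = FALSE]
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

draw_mvn <- function(mean, V) {
  L <- tryCatch(chol(V), error = function(e) {
    chol(V + diag(1e-8 * mean(diag(V)) + 1e-12, nrow(V)))
  })
  as.vector(mean + t(L) %*% stats::rnorm(length(mean)))
}

# One Gibbs update of a single variable; returns the new column.
impute_one <- function(tab, target, miss_idx, donors = 5L) {
  method <- impute_method(target)
  X <- imputation_design(tab, target)
  obs <- setdiff(seq_len(nrow(tab)), miss_idx)
  # for mtss3, recent ex-smokers are neither donors nor recipients
  if (target == "mtss3") obs <- obs[tab$smoker_status[obs] == "current"]
  Xo <- X[obs, , drop = FALSE]
  Xm <- X[miss_idx, , drop = FALSE]
  # the observed-row subset can lose levels: re-prune constant or
  # collinear columns on the fitting rows (intercept always kept)
  keep <- c(TRUE, apply(Xo[, -1L, drop = FALSE], 2, stats::sd) > 0)
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- Xm[, keep, drop = FALSE]
  q <- qr(Xo)
  if (q$rank < ncol(Xo)) {
    sel <- q$pivot[seq_len(q$rank)]
    Xo <- Xo[, sel, drop = FALSE]
    Xm <- Xm[, sel, drop = FALSE]
  }
  yo <- tab[[target]][obs]
  col <- tab[[target]]

  if (method == "pmm") {
    yo <- as.numeric(yo)
    f <- stats::lm.fit(Xo, yo)
    ok <- !is.na(f$coefficients)
    beta <- f$coefficients[ok]
    Xo2 <- Xo[, ok, drop = FALSE]
    Xm2 <- Xm[, ok, drop = FALSE]
    res <- yo - as.vector(Xo2 %*% beta)
    dfres <- max(1L, length(yo) - length(beta))
    sigma2 <- sum(res^2) / stats::rchisq(1L, dfres)
    V <- sigma2 * solve(crossprod(Xo2))
    bstar <- draw_mvn(beta, V)
    pred_obs <- as.vector(Xo2 %*% beta)
    pred_mis <- as.vector(Xm2 %*% bstar)
    ord <- order(pred_obs)
    so <- pred_obs[ord]
    yo_sorted <- yo[ord]
    n_obs <- length(so)
    for (i in seq_along(miss_idx)) {
      pos <- findInterval(pred_mis[i], so)
      win <- max(1L, pos - donors):min(n_obs, pos + donors + 1L)
      d <- abs(so[win] - pred_mis[i])
      cand <- win[order(d)][seq_len(min(donors, length(win)))]
      col[miss_idx[i]] <- yo_sorted[cand[sample.int(length(cand), 1L)]]
    }
  } else if (method == "logistic") {
    yb <- as.numeric(yo) - 1
    fit <- suppressWarnings(fit_logistic(Xo, yb))
    bstar <- draw_mvn(fit$coefficients, fit$vcov)
    p <- stats::plogis(as.vector(Xm %*% bstar))
    lev <- levels(tab[[target]])
    col[miss_idx] <- factor(
      ifelse(stats::runif(length(miss_idx)) < p, lev[2L], lev[1L]),
      levels = lev
    )
  } else {
    yf <- droplevels(factor(yo))
    fit <- suppressWarnings(fit_multinomial(Xo, yf))
    vec <- as.vector(t(fit$coefficients))
    bstar <- matrix(draw_mvn(vec, fit$vcov),
                    nrow = nrow(fit$coefficients), byrow = TRUE)
    P <- softmax_probs(cbind(0, Xm %*% t(bstar)))
    u <- stats::runif(length(miss_idx))
    cum <- t(apply(P, 1L, cumsum))
    pick <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
    col[miss_idx] <- factor(levels(yf)[pick], levels = levels(tab[[target]]))
  }
  col
}

#' Chained-equations multiple imputation
#'
#' Produces `m` completed copies of a survey table by iterative
#' conditional draws, one independent chain per imputation.  Continuous
#' variables (age, income) use predictive mean matching with 5 donors;
#' the binary quit-attempt outcome uses logistic draws; education,
#' region, urges and the collapsed motivation outcome use multinomial
#' draws.  The motivation outcome is imputed only for current smokers;
#' its structural missingness among recent ex-smokers is preserved.
#' Observed cells are never altered.  Chain non-convergence is not
#' detected (documented limitation); the default of 10 iterations is a
#' conventional choice.
#'
#' @param table Survey table (after [recode_outcomes()]).
#' @param m Number of imputations (at least 2).
#' @param iterations Gibbs iterations per chain (default 10).
#' @param seed Integer seed; chain i is seeded deterministically from it.
#' @return An `imputation_set`: list with `completed` (list of m
#'   tables), `m`, `iterations`, `seed`, `variables_imputed`.
#' @export
chained_imputation <- function(table, m = 10L, iterations = 10L, seed = 1L) {
  if (m < 2L) stop("m must be at least 2")
  vars <- intersect(imputable_vars, names(table))
  miss <- lapply(vars, function(v) {
    idx <- which(is.na(table[[v]]))
    if (v == "mtss3" && "smoker_status" %in% names(table)) {
      idx <- idx[table$smoker_status[idx] == "current"]
    }
    idx
  })
  names(miss) <- vars
  n_miss <- lengths(miss)
  for (v in vars) {
    if (n_miss[[v]] == nrow(table)) {
      stop("variable '", v, "' is 100% missing and cannot be imputed")
    }
  }
  to_impute <- vars[n_miss > 0L]
  if (!length(to_impute)) {
    return(structure(
      list(completed = rep(list(table), m), m = as.integer(m),
           iterations = as.integer(iterations), seed = as.integer(seed),
           variables_imputed = character(0)),
      class = "imputation_set"
    ))
  }
  # update order: least missing first, as in standard chained equations
  to_impute <- to_impute[order(n_miss[to_impute])]
  completed <- vector("list", m)
  for (i in seq_len(m)) {
    chain_seed <- as.integer((as.double(seed) + i * 104729) %% 2147483647)
    completed[[i]] <- with_seed(chain_seed, {
      tab <- table
      for (v in to_impute) {  # initialise by sampling observed values
        idx <- miss[[v]]
        pool <- tab[[v]][!is.na(tab[[v]])]
        tab[[v]][idx] <- pool[sample.int(length(pool), length(idx),
                                         replace = TRUE)]
      }
      for (it in seq_len(iterations)) {
        for (v in to_impute) {
          tab[[v]] <- impute_one(tab, v, miss[[v]])
        }
      }
      tab
    })
  }
  structure(
    list(completed = completed, m = as.integer(m),
         iterations = as.integer(iterations), seed = as.integer(seed),
         variables_imputed = to_impute),
    class = "imputation_set"
  )
}

#' Wrap a complete table as a degenerate imputation set
#'
#' For data without missing values the downstream machinery can run on
#' a single "imputation"; every pooled quantity then equals its
#' single-fit counterpart.
#' @param table Complete survey table.
#' @return An `imputation_set` with `m = 1`.
#' @export
as_imputation_set <- function(table) {
  structure(
    list(completed = list(table), m = 1L, iterations = 0L, seed = NA_integer_,
         variables_imputed = character(0)),
    class = "imputation_set"
  )
}

#' Rubin's rules for a scalar estimate
#'
#' Pools `m` complete-data estimates and their variances: the pooled
#' estimate is the mean, total variance `T = W + (1 + 1/m) B` with `W`
#' the mean within-imputation variance and `B` the between-imputation
#' sample variance, degrees of freedom by Barnard-Rubin, and a
#' t-interval.
#'
#' @param estimates,variances Numeric vectors of length m.
#' @param dfcom Complete-data degrees of freedom (default `Inf`).
#' @param level Confidence level.
#' @return List with `estimate`, `within`, `between`, `total`, `df`,
#'   `se`, `ci`, `m`.
#' @export
pool_scalar <- function(estimates, variances, dfcom = Inf, level = 0.95) {
  m <- length(estimates)
  if (length(variances) != m) stop("estimates and variances differ in length")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- if (m > 1L) stats::var(estimates) else 0
  Tv <- W + (1 + 1 / m) * B
  if (B == 0 || m == 1L) {
    df <- Inf
  } else {
    lambda <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  tq <- stats::qt(1 - (1 - level) / 2, df)
  list(estimate = qbar, within = W, between = B, total = Tv, df = df,
       se = sqrt(Tv), ci = c(qbar - tq * sqrt(Tv), qbar + tq * sqrt(Tv)),
       m = m)
}

coef_vector <- function(fit) {
  if (is.matrix(fit$coefficients)) as.vector(t(fit$coefficients)) else fit$coefficients
}

loglik_at <- function(fit_family, X, y, theta, K = NULL) {
  if (fit_family == "binomial") {
    mu <- stats::plogis(as.vector(X %*% theta))
    mu <- pmin(pmax(mu, 1e-300), 1 - 1e-16)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  } else {
    B <- matrix(theta, nrow = K - 1L, byrow = TRUE)
    Yind <- matrix(0, length(y), K)
    Yind[cbind(seq_along(y), as.integer(y))] <- 1
    multinom_loglik_at(X, Yind, B)
  }
}

#' Pooled likelihood-ratio test across imputations (Meng-Rubin D3)
#'
#' Tests a reduced model specification against a full one under
#' multiple imputation: complete-data likelihood-ratio statistics are
#' combined with the statistic re-evaluated at the pooled coefficient
#' estimates, the average relative increase in variance `r` is
#' estimated from their difference, and the result is referred to an F
#' distribution.  With identical completed data sets (`r = 0`) the
#' p-value equals the single-data-set likelihood-ratio test.
#'
#' @param full_spec,reduced_spec Nested [model_spec()]s (the reduced
#'   model's columns must be a subset of the full model's).
#' @param imputation_set An `imputation_set` with `m >= 2`.
#' @return List with `statistic` (the F-scaled D3), `df`, `df2`, `p`,
#'   `dbar`, `dtilde`, `r`, `m`.
#' @export
pool_lr <- function(full_spec, reduced_spec, imputation_set) {
  m <- imputation_set$m
  if (m < 2L) stop("pooled likelihood-ratio test needs m >= 2 imputations")
  first <- imputation_set$completed[[1L]]
  if (!full_spec$frozen) full_spec <- freeze_spec(full_spec, first)
  if (!reduced_spec$frozen) reduced_spec <- freeze_spec(reduced_spec, first)

  lr <- numeric(m)
  thetas_f <- NULL
  thetas_r <- NULL
  designs <- vector("list", m)
  df <- NA_integer_
  K <- NULL
  fam <- if (full_spec$outcome == "qa") "binomial" else "multinomial"
  for (l in seq_len(m)) {
    tab <- imputation_set$completed[[l]]
    df_full <- build_design(tab, full_spec)
    df_red <- build_design(tab, reduced_spec)
    ff <- if (fam == "binomial") fit_logistic(df_full$X, df_full$y) else fit_multinomial(df_full$X, df_full$y)
    fr <- if (fam == "binomial") fit_logistic(df_red$X, df_red$y) else fit_multinomial(df_red$X, df_red$y)
    if (!all(unlist_cols(fr) %in% unlist_cols(ff))) {
      stop("models are not nested")
    }
    lr[l] <- 2 * (ff$loglik - fr$loglik)
    if (is.null(thetas_f)) {
      thetas_f <- matrix(0, m, ff$n_params)
      thetas_r <- matrix(0, m, fr$n_params)
      df <- ff$n_params - fr$n_params
      K <- if (fam == "multinomial") length(ff$outcome_levels) else NULL
    }
    thetas_f[l, ] <- coef_vector(ff)
    thetas_r[l, ] <- coef_vector(fr)
    designs[[l]] <- list(Xf = df_full$X, Xr = df_red$X, y = df_full$y)
  }
  if (df < 1L) stop("full and reduced models have the same dimension")
  theta_f <- colMeans(thetas_f)
  theta_r <- colMeans(thetas_r)
  d_pooled <- vapply(designs, function(d) {
    2 * (loglik_at(fam, d$Xf, d$y, theta_f, K) -
           loglik_at(fam, d$Xr, d$y, theta_r, K))
  }, numeric(1))
  dbar <- mean(lr)
  dtilde <- mean(d_pooled)
  r <- max(0, (m + 1) / (df * (m - 1)) * (dbar - dtilde))
  D <- max(0, dtilde / (df * (1 + r)))
  t <- df * (m - 1)
  v <- if (r == 0) {
    Inf
  } else if (t > 4) {
    4 + (t - 4) * (1 + (1 - 2 / t) / r)^2
  } else {
    t * (1 + 1 / df) * (1 + 1 / r)^2 / 2
  }
  p <- stats::pf(D, df, v, lower.tail = FALSE)
  list(statistic = D, df = df, df2 = v, p = p, dbar = dbar,
       dtilde = dtilde, r = r, m = m)
}
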