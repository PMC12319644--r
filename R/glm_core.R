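#' Declarative model specification
#'
#' A `model_spec` describes one candidate regression: the outcome family
#' (three-category motivation outcome, fitted by multinomial logistic
#' regression, or binary quit-attempt outcome, fitted by binary logistic
#' regression), the covariates with their functional forms, and the
#' interaction set.  Continuous covariates may enter linearly or through
#' a restricted cubic spline with 3-5 knots; knot locations are computed
#' once on the learning data (see [freeze_spec()]) and stored in the
#' spec so that validation-data predictions use the identical basis.
#'
#' @param outcome `"mtss3"` or `"qa"`.
#' @param terms Named character vector mapping covariate names to forms:
#'   `"cat"` (categorical, dummy coded against the reference level),
#'   `"linear"`, or `"rcs3"`/`"rcs4"`/`"rcs5"`.
#' @param interactions List of length-2 character vectors naming
#'   covariate pairs; every member must appear in `terms` (hierarchy).
#' @param references Named list of reference levels for categorical
#'   covariates; defaults to [default_references()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("mtss3", "qa"), terms,
                       interactions = list(),
                       references = default_references()) {
  outcome <- match.arg(outcome)
  if (is.null(names(terms)) || any(names(terms) == "") ||
      anyDuplicated(names(terms))) {
    stop("terms must be a uniquely named character vector")
  }
  ok <- terms %in% c("cat", "linear", "rcs3", "rcs4", "rcs5")
  if (!all(ok)) {
    stop("unknown term form(s): ", paste(terms[!ok], collapse = ", "))
  }
  if (length(interactions)) {
    keys <- vapply(interactions, function(pr) {
      if (length(pr) != 2L) stop("interactions must be covariate pairs")
      if (!all(pr %in% names(terms))) {
        stop("interaction members must appear among the terms (hierarchy): ",
             paste(pr, collapse = ":"))
      }
      paste(sort(pr), collapse = ":")
    }, character(1))
    if (anyDuplicated(keys)) stop("duplicate interaction pairs")
  }
  structure(
    list(outcome = outcome, terms = terms, interactions = interactions,
         references = references, splines = list(), factor_levels = list(),
         ranges = list(), frozen = FALSE),
    class = "model_spec"
  )
}

spec_form <- function(spec, cov) unname(spec$terms[[cov]])

is_rcs_form <- function(form) grepl("^rcs[345]$", form)

#' Freeze data-dependent parts of a model specification
#'
#' Computes spline knots (Harrell default quantiles via [place_knots()]),
#' records categorical level sets and observed continuous ranges on the
#' supplied (learning) data, and marks the spec frozen.  A frozen spec
#' evaluates identically on any later data set, which is required for
#' coherent external validation.
#'
#' @param spec A [model_spec()].
#' @param table Survey data frame (typically the learning data).
#' @return The frozen `model_spec`.
#' @export
freeze_spec <- function(spec, table) {
  for (cov in names(spec$terms)) {
    if (!cov %in% names(table)) {
      stop("covariate '", cov, "' not present in the data")
    }
    form <- spec_form(spec, cov)
    if (form == "cat") {
      lev <- if (cov %in% names(survey_levels)) {
        survey_levels[[cov]]
      } else {
        as.character(sort(unique(table[[cov]][!is.na(table[[cov]])])))
      }
      ref <- spec$references[[cov]]
      if (!is.null(ref) && ref %in% lev) lev <- c(ref, setdiff(lev, ref))
      spec$factor_levels[[cov]] <- lev
    } else {
      x <- table[[cov]]
      x <- x[!is.na(x)]
      spec$ranges[[cov]] <- range(x)
      if (is_rcs_form(form) && is.null(spec$splines[[cov]])) {
        spec$splines[[cov]] <- place_knots(x, as.integer(sub("rcs", "", form)))
      }
    }
  }
  spec$frozen <- TRUE
  spec
}

# Columns contributed by one covariate under its form.  Returns a matrix
# with informative colnames ("age", "age'", ..., "sexfemale", ...).
term_block <- function(table, cov, spec) {
  form <- spec_form(spec, cov)
  x <- table[[cov]]
  if (form == "cat") {
    lev <- spec$factor_levels[[cov]]
    xs <- as.character(x)
    bad <- setdiff(unique(xs[!is.na(xs)]), lev)
    if (length(bad)) {
      stop("unseen level(s) of '", cov, "' at prediction time: ",
           paste(bad, collapse = ", "))
    }
    f <- factor(xs, levels = lev)
    out <- vapply(lev[-1L], function(l) as.numeric(f == l),
                  numeric(length(x)))
    out <- matrix(out, nrow = length(x))
    colnames(out) <- paste0(cov, lev[-1L])
    out
  } else if (form == "linear") {
    out <- matrix(as.numeric(x), ncol = 1L)
    colnames(out) <- cov
    out
  } else {
    sp <- spec$splines[[cov]]
    if (is.null(sp)) stop("spline knots for '", cov, "' are not frozen")
    out <- rcs_basis(as.numeric(x), sp)
    colnames(out) <- paste0(cov, c("", strrep("'", seq_len(ncol(out) - 1L))))
    out
  }
}

#' Build a design matrix and outcome vector from a model specification
#'
#' Dummy codes categorical covariates against their reference levels,
#' expands continuous covariates through their configured form, and adds
#' interaction columns as elementwise products of the member terms'
#' columns.  Rows with a missing value in any used column (including the
#' outcome, when requested) are excluded, i.e. complete-case within each
#' imputed data set.
#'
#' @param table Survey data frame.
#' @param spec A frozen [model_spec()] (unfrozen specs are frozen on
#'   `table` itself).
#' @param require_outcome Drop rows with missing outcome and return `y`?
#' @return List with `X` (design matrix incl. intercept), `y` (numeric
#'   0/1 for the binary outcome, factor for the multinomial one; `NULL`
#'   when `require_outcome = FALSE`), `rows` (row indices of `table`
#'   used), `column_map` (data frame mapping columns to terms) and the
#'   frozen `spec`.
#' @export
build_design <- function(table, spec, require_outcome = TRUE) {
  if (!spec$frozen) spec <- freeze_spec(spec, table)
  covs <- names(spec$terms)
  used <- covs
  if (require_outcome) used <- c(used, spec$outcome)
  missing_cols <- setdiff(used, names(table))
  if (length(missing_cols)) {
    stop("column(s) absent from the data: ",
         paste(missing_cols, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(table))
  for (cl in used) keep <- keep & !is.na(table[[cl]])
  rows <- which(keep)
  tab <- table[rows, , drop = FALSE]

  blocks <- lapply(covs, function(cov) term_block(tab, cov, spec))
  names(blocks) <- covs
  X <- cbind(`(Intercept)` = rep(1, nrow(tab)), do.call(cbind, blocks))
  map <- data.frame(
    column = colnames(X),
    term = c("(Intercept)",
             rep(covs, vapply(blocks, ncol, integer(1)))),
    type = c("intercept",
             rep("main", sum(vapply(blocks, ncol, integer(1))))),
    stringsAsFactors = FALSE
  )
  for (pr in spec$interactions) {
    a <- blocks[[pr[1L]]]
    b <- blocks[[pr[2L]]]
    prod_cols <- matrix(0, nrow(tab), ncol(a) * ncol(b))
    nm <- character(ncol(a) * ncol(b))
    idx <- 1L
    for (i in seq_len(ncol(a))) {
      for (j in seq_len(ncol(b))) {
        prod_cols[, idx] <- a[, i] * b[, j]
        nm[idx] <- paste(colnames(a)[i], colnames(b)[j], sep = ":")
        idx <- idx + 1L
      }
    }
    colnames(prod_cols) <- nm
    X <- cbind(X, prod_cols)
    map <- rbind(map, data.frame(
      column = nm, term = paste(pr, collapse = ":"),
      type = "interaction", stringsAsFactors = FALSE
    ))
  }

  y <- NULL
  if (require_outcome) {
    yraw <- tab[[spec$outcome]]
    if (spec$outcome == "qa") {
      y <- if (is.factor(yraw)) as.numeric(yraw == "yes") else as.numeric(yraw)
    } else {
      y <- factor(as.character(yraw), levels = survey_levels$mtss3)
    }
  }
  list(X = X, y = y, rows = rows, column_map = map, spec = spec)
}

new_fit_result <- function(family, coefficients, vcov, loglik, n_obs,
                           n_params, converged, separation, column_map,
                           outcome_levels = NULL, spec = NULL,
                           score_max = NA_real_) {
  structure(
    list(family = family, coefficients = coefficients, vcov = vcov,
         loglik = loglik, n_obs = n_obs, n_params = n_params,
         converged = converged, separation = separation,
         column_map = column_map, outcome_levels = outcome_levels,
         spec = spec, score_max = score_max),
    class = "fit_result"
  )
}

check_rank <- function(X) {
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
}

# Solve with a small ridge fallback for numerically singular systems
# (e.g. quasi-separated sparse categories during imputation draws).
safe_solve <- function(A, b = NULL) {
  out <- tryCatch(
    if (is.null(b)) solve(A) else solve(A, b),
    error = function(e) NULL
  )
  if (is.null(out)) {
    ridge <- diag(1e-6 * mean(abs(diag(A))) + 1e-10, nrow(A))
    out <- if (is.null(b)) solve(A + ridge) else solve(A + ridge, b)
  }
  out
}

separation_flag <- function(coef_vec, X) {
  sds <- apply(X, 2, stats::sd)
  sds[!is.finite(sds)] <- 0  # constant columns (intercept) are not checked
  any(abs(coef_vec * rep(sds, length.out = length(coef_vec))) > 15)
}

#' Fit a binary logistic regression by maximum likelihood
#'
#' Thin wrapper over iteratively reweighted least squares
#' ([stats::glm.fit()]) run to a tight tolerance; the covariance is the
#' inverse observed information.  Possible separation (a coefficient
#' exceeding 15 on standardised columns) is flagged, not penalised.
#'
#' @param X Design matrix of full column rank, including the intercept.
#' @param y Binary 0/1 vector (or two-level factor; second level is the
#'   event).
#' @return A `fit_result`.
#' @export
fit_logistic <- function(X, y) {
  if (is.factor(y)) y <- as.numeric(y) - 1
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  check_rank(X)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = list(epsilon = 1e-12, maxit = 100)
  ))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  info <- crossprod(X, X * (mu * (1 - mu)))
  V <- safe_solve(info)
  dimnames(V) <- list(colnames(X), colnames(X))
  ll <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  g <- crossprod(X, y - mu)
  sep <- separation_flag(beta, X)
  if (sep) warning("possible separation: a standardised coefficient exceeds 15")
  new_fit_result(
    family = "binomial", coefficients = stats::setNames(beta, colnames(X)),
    vcov = V, loglik = ll, n_obs = length(y), n_params = ncol(X),
    converged = fit$converged, separation = sep,
    column_map = colnames(X), score_max = max(abs(g))
  )
}

softmax_probs <- function(Eta) {
  # Eta: n x K linear predictors (reference column included as zeros)
  m <- Eta[, 1L]
  for (j in seq_len(ncol(Eta))[-1L]) m <- pmax(m, Eta[, j])
  P <- exp(Eta - m)
  P / rowSums(P)
}

multinom_loglik_at <- function(X, Yind, B) {
  P <- softmax_probs(cbind(0, X %*% t(B)))
  sum(log(pmax(rowSums(P * Yind), 1e-300)))
}

#' Fit a multinomial logistic regression by Newton-Raphson
#'
#' Joint maximum likelihood over the (K-1) x p free parameters with the
#' first outcome level as reference (linear predictor 0).  Iterations
#' stop when every score coordinate is below `1e-8` in absolute value or
#' the relative log-likelihood change falls below `1e-10`; the
#' covariance is the inverse observed information.
#'
#' @param X Design matrix of full column rank, including the intercept.
#' @param y Factor (first level = reference).
#' @param start Optional (K-1) x p starting coefficient matrix.
#' @return A `fit_result` whose `coefficients` is a (K-1) x p matrix.
#' @export
fit_multinomial <- function(X, y, start = NULL) {
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  K <- nlevels(y)
  if (K < 2L) stop("outcome has fewer than 2 observed categories")
  check_rank(X)
  n <- nrow(X)
  p <- ncol(X)
  Yind <- matrix(0, n, K)
  Yind[cbind(seq_len(n), as.integer(y))] <- 1
  B <- if (is.null(start)) matrix(0, K - 1L, p) else start
  ll <- multinom_loglik_at(X, Yind, B)
  converged <- FALSE
  H <- NULL
  gmax <- Inf
  for (iter in seq_len(100L)) {
    P <- softmax_probs(cbind(0, X %*% t(B)))
    g <- unlist(lapply(2:K, function(k) crossprod(X, Yind[, k] - P[, k])))
    gmax <- max(abs(g))
    H <- matrix(0, (K - 1L) * p, (K - 1L) * p)
    for (a in 2:K) {
      for (b in a:K) {
        w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
        blk <- crossprod(X, X * w)
        ia <- ((a - 2L) * p + 1L):((a - 1L) * p)
        ib <- ((b - 2L) * p + 1L):((b - 1L) * p)
        H[ia, ib] <- blk
        if (a != b) H[ib, ia] <- t(blk)
      }
    }
    if (gmax < 1e-8) {
      converged <- TRUE
      break
    }
    step <- safe_solve(H, g)
    ll_new <- -Inf
    fac <- 1
    for (half in seq_len(30L)) {
      Bn <- B + matrix(step * fac, K - 1L, p, byrow = TRUE)
      ll_new <- multinom_loglik_at(X, Yind, Bn)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      fac <- fac / 2
    }
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    B <- Bn
    ll <- ll_new
    if (rel < 1e-10) {
      converged <- TRUE
      break
    }
  }
  V <- safe_solve(H)
  # parameter order: category 2's coefficients, then category 3's, ...
  pn <- unlist(lapply(levels(y)[-1L], function(l) paste(l, colnames(X), sep = ":")))
  dimnames(V) <- list(pn, pn)
  dimnames(B) <- list(levels(y)[-1L], colnames(X))
  sep <- separation_flag(as.vector(t(B)), X)
  if (sep) warning("possible separation: a standardised coefficient exceeds 15")
  new_fit_result(
    family = "multinomial", coefficients = B, vcov = V, loglik = ll,
    n_obs = n, n_params = (K - 1L) * p, converged = converged,
    separation = sep, column_map = colnames(X),
    outcome_levels = levels(y), score_max = gmax
  )
}

#' Fit a model specification on a survey table
#'
#' Builds the design via [build_design()] and dispatches to
#' [fit_logistic()] or [fit_multinomial()] according to the outcome.
#'
#' @param table Survey data frame.
#' @param spec A [model_spec()]; unfrozen specs are frozen on `table`.
#' @param start Optional starting coefficients (multinomial only).
#' @return A `fit_result` carrying the frozen spec.
#' @export
fit_model <- function(table, spec, start = NULL) {
  d <- build_design(table, spec)
  fit <- if (spec$outcome == "qa") {
    fit_logistic(d$X, d$y)
  } else {
    fit_multinomial(d$X, d$y, start = start)
  }
  fit$spec <- d$spec
  fit$column_map <- d$column_map
  fit
}

#' Log-likelihood and BIC of a fit
#'
#' `bic()` is \eqn{-2\,\ell + p \log n} with \eqn{p} the number of free
#' parameters and \eqn{n} the number of observations used.
#' @param fit A `fit_result`.
#' @return Numeric scalar.
#' @export
log_likelihood <- function(fit) fit$loglik

#' @rdname log_likelihood
#' @export
bic <- function(fit) -2 * fit$loglik + fit$n_params * log(fit$n_obs)

#' Likelihood-ratio test of nested fits
#'
#' @param full,reduced `fit_result`s on the same rows; the reduced
#'   model's design columns must be a subset of the full model's.
#' @return List with `statistic`, `df` and `p`.
#' @export
lr_test <- function(full, reduced) {
  if (!all(unlist_cols(reduced) %in% unlist_cols(full))) {
    stop("models are not nested: reduced design columns are not a subset")
  }
  if (full$n_obs != reduced$n_obs) {
    stop("models were fitted on different numbers of rows")
  }
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("models are not nested: reduced has more parameters")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

unlist_cols <- function(fit) {
  if (is.matrix(fit$coefficients)) colnames(fit$coefficients) else names(fit$coefficients)
}

#' Predicted probabilities
#'
#' @param fit A `fit_result` carrying a frozen spec (from [fit_model()]).
#' @param table Survey data frame to predict for (rows with missing used
#'   covariates are dropped; see the `rows` attribute of the result).
#' @return For the binary outcome a numeric vector; for the multinomial
#'   outcome an n x K matrix whose rows sum to one.
#' @export
predict_probs <- function(fit, table) {
  if (is.null(fit$spec)) stop("fit carries no model spec; use fit_model()")
  d <- build_design(table, fit$spec, require_outcome = FALSE)
  out <- predict_probs_design(fit, d$X)
  attr(out, "rows") <- d$rows
  out
}

predict_probs_design <- function(fit, X) {
  if (fit$family == "binomial") {
    as.vector(stats::plogis(X %*% fit$coefficients))
  } else {
    P <- softmax_probs(cbind(0, X %*% t(fit$coefficients)))
    colnames(P) <- fit$outcome_levels
    P
  }
}

#' Odds-ratio contrasts for a continuous covariate
#'
#' Evaluates the fitted main effect of a (possibly spline-coded)
#' continuous covariate at given values and contrasts each against a
#' reference value: OR = exp(eta(v) - eta(ref)), with a Wald confidence
#' interval from the variance of the linear combination.  Interaction
#' partners are implicitly held at zero / their reference level.  For a
#' multinomial fit one contrast row per non-reference outcome category
#' is returned.  Values outside the observed covariate range are flagged
#' as extrapolation (the spline is linear out there).
#'
#' @param fit A `fit_result` from [fit_model()].
#' @param covariate Name of a continuous covariate in the spec.
#' @param values Numeric vector of covariate values.
#' @param reference Reference value for the contrast.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `category`, `value`, `or`, `lo`,
#'   `hi`, `extrapolated`.
#' @export
evaluate_contrast <- function(fit, covariate, values, reference,
                              level = 0.95) {
  spec <- fit$spec
  if (is.null(spec)) stop("fit carries no model spec; use fit_model()")
  form <- spec_form(spec, covariate)
  if (is.null(form) || form == "cat") {
    stop("'", covariate, "' is not a continuous covariate of this model")
  }
  basis_row <- function(v) {
    if (form == "linear") matrix(v, ncol = 1L) else rcs_basis(v, spec$splines[[covariate]])
  }
  main_cols <- fit$column_map$column[fit$column_map$term == covariate &
                                       fit$column_map$type == "main"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  rng <- spec$ranges[[covariate]]
  href <- basis_row(reference)
  cats <- if (fit$family == "binomial") "yes" else fit$outcome_levels[-1L]
  rows <- list()
  for (v in values) {
    L <- as.vector(basis_row(v) - href)
    extrap <- !is.null(rng) && (v < rng[1L] || v > rng[2L])
    for (ci in seq_along(cats)) {
      if (fit$family == "binomial") {
        est <- sum(L * fit$coefficients[main_cols])
        Vm <- fit$vcov[main_cols, main_cols, drop = FALSE]
      } else {
        est <- sum(L * fit$coefficients[cats[ci], main_cols])
        pn <- paste(cats[ci], main_cols, sep = ":")
        Vm <- fit$vcov[pn, pn, drop = FALSE]
      }
      se <- sqrt(max(0, as.vector(t(L) %*% Vm %*% L)))
      rows[[length(rows) + 1L]] <- data.frame(
        category = cats[ci], value = v, or = exp(est),
        lo = exp(est - z * se), hi = exp(est + z * se),
        extrapolated = extrap, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
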