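#' Brier score
#'
#' Mean squared difference between a binary outcome and its predicted
#' probability; a proper scoring rule, lower is better.
#'
#' @param y Binary 0/1 vector (or two-level factor, second level = event).
#' @param p Predicted probabilities in `[0, 1]`, same length as `y`.
#' @return List of class `score_report` with `rule`, `value`, `n_eval`.
#' @export
brier_score <- function(y, p) {
  if (is.factor(y)) y <- as.numeric(y) - 1
  y <- as.numeric(y)
  p <- as.numeric(p)
  if (length(y) != length(p)) stop("y and p must have equal length")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities outside [0, 1]")
  structure(
    list(rule = "brier", value = mean((y - p)^2), n_eval = length(y),
         per_category = NULL),
    class = "score_report"
  )
}

#' Polytomous discrimination index (PDI)
#'
#' For K outcome categories, draw one observation from each category;
#' the category-j component is the probability that the observation
#' truly in category j has the strictly highest predicted probability
#' for category j among the K drawn.  Ties among t observations sharing
#' the maximum award credit 1/t when the category-j member is among
#' them, so uniform predictions score exactly 1/K.  The PDI is the mean
#' of the K components.  Computed by a per-category sort-and-count
#' algorithm (O(n log n) per category) rather than tuple enumeration.
#'
#' @param y3 Category vector (factor or character); every category of
#'   `P`'s columns must occur at least once.
#' @param P n x K matrix of predicted category probabilities with
#'   category names as colnames (or in the order of `levels(y3)`).
#' @return `score_report` with `value` (the PDI) and `per_category`.
#' @export
pdi <- function(y3, P) {
  P <- as.matrix(P)
  K <- ncol(P)
  lev <- colnames(P)
  y <- if (is.null(lev)) factor(y3) else factor(as.character(y3), levels = lev)
  if (is.null(lev)) lev <- levels(y)
  if (nlevels(y) != K) stop("category labels of y3 and columns of P disagree")
  counts <- table(y)
  if (any(counts == 0)) {
    stop("PDI undefined: empty category ", lev[which(counts == 0)[1L]])
  }
  if (any(is.na(y))) stop("y3 contains missing categories")
  per_cat <- numeric(K)
  n_masks <- bitwShiftL(1L, K - 1L)
  for (j in seq_len(K)) {
    vj <- P[y == lev[j], j]
    others <- lapply(lev[-j], function(cl) sort(P[y == cl, j]))
    n_oth <- lengths(others)
    lt <- vapply(others, function(s) findInterval(vj, s, left.open = TRUE),
                 numeric(length(vj)))
    le <- vapply(others, function(s) findInterval(vj, s),
                 numeric(length(vj)))
    lt <- matrix(lt, nrow = length(vj))
    eq <- matrix(le, nrow = length(vj)) - lt
    credit <- numeric(length(vj))
    for (mask in seq_len(n_masks) - 1L) {
      term <- rep(1, length(vj))
      t_size <- 1L
      for (c in seq_len(K - 1L)) {
        if (bitwAnd(mask, bitwShiftL(1L, c - 1L)) > 0L) {
          term <- term * eq[, c]
          t_size <- t_size + 1L
        } else {
          term <- term * lt[, c]
        }
      }
      credit <- credit + term / t_size
    }
    per_cat[j] <- sum(credit) / (length(vj) * prod(n_oth))
  }
  names(per_cat) <- lev
  structure(
    list(rule = "pdi", value = mean(per_cat), n_eval = length(y),
         per_category = per_cat),
    class = "score_report"
  )
}

#' Brant test of the proportional-odds assumption
#'
#' Fits the J-1 cumulative binary logistic models (outcome at or above
#' each level), assembles the joint covariance of the stacked slope
#' vectors (Brant 1990), and Wald-tests equality of the slopes across
#' the splits, globally (df = (J-2) x number of slopes) and per
#' variable.  A large statistic indicates that a single proportional
#' slope does not describe the ordinal outcome.
#'
#' @param y_ord Ordinal outcome with at least 3 observed levels
#'   (ordered factor or integer codes).
#' @param X Covariate matrix (no intercept column).
#' @return List with `global` (statistic, df, p) and `by_variable`
#'   data frame.
#' @export
brant_test <- function(y_ord, X) {
  X <- as.matrix(X)
  yi <- if (is.factor(y_ord)) as.integer(y_ord) else as.integer(factor(y_ord))
  J <- length(unique(yi))
  if (J < 3L) stop("Brant test undefined for fewer than 3 outcome levels")
  yi <- as.integer(factor(yi))  # 1..J dense codes
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  X1 <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X1)
  check_rank(X1)
  m <- J - 1L
  Pi <- matrix(0, n, m)
  beta_star <- matrix(0, m, p)
  XtWX_inv <- vector("list", m)
  for (j in seq_len(m)) {
    z <- as.numeric(yi > j)
    f <- suppressWarnings(stats::glm.fit(
      X1, z, family = stats::binomial(),
      control = list(epsilon = 1e-10, maxit = 100)
    ))
    Pi[, j] <- f$fitted.values
    beta_star[j, ] <- f$coefficients[-1L]
    XtWX_inv[[j]] <- solve(crossprod(X1, X1 * (Pi[, j] * (1 - Pi[, j]))))
  }
  # joint covariance of the stacked slope vectors
  V <- matrix(0, m * p, m * p)
  for (j in seq_len(m)) {
    for (l in j:m) {
      w <- if (j == l) Pi[, j] * (1 - Pi[, j]) else Pi[, l] - Pi[, j] * Pi[, l]
      blk <- (XtWX_inv[[j]] %*% crossprod(X1, X1 * w) %*% XtWX_inv[[l]])[-1L, -1L, drop = FALSE]
      rj <- ((j - 1L) * p + 1L):(j * p)
      rl <- ((l - 1L) * p + 1L):(l * p)
      V[rj, rl] <- blk
      if (j != l) V[rl, rj] <- t(blk)
    }
  }
  b <- as.vector(t(beta_star))
  wald <- function(keep_vars) {
    # contrast rows: beta_1[v] - beta_j[v] for j = 2..m, v in keep_vars
    rows <- list()
    for (j in 2:m) {
      for (v in keep_vars) {
        r <- numeric(m * p)
        r[v] <- 1
        r[(j - 1L) * p + v] <- -1
        rows[[length(rows) + 1L]] <- r
      }
    }
    D <- do.call(rbind, rows)
    db <- D %*% b
    stat <- as.numeric(t(db) %*% solve(D %*% V %*% t(D)) %*% db)
    df <- nrow(D)
    c(statistic = stat, df = df,
      p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  if (m < 2L) stop("Brant test undefined: only one cumulative split")
  glob <- wald(seq_len(p))
  by_var <- t(vapply(seq_len(p), function(v) wald(v), numeric(3)))
  by_variable <- data.frame(
    variable = colnames(X), statistic = by_var[, 1L],
    df = by_var[, 2L], p = by_var[, 3L], stringsAsFactors = FALSE
  )
  list(global = as.list(glob), by_variable = by_variable)
}

#' Percent change in predictive accuracy between data sets
#'
#' For the PDI the change is `100 * (learn - valid) / learn`; for the
#' Brier score the comparison is made on the accuracy scale `1 - Brier`,
#' i.e. `100 * ((1 - brier_learn) - (1 - brier_valid)) / (1 - brier_learn)`.
#' Positive values mean degradation from learning to validation data.
#'
#' @param score_learn,score_valid Scores under `rule`.
#' @param rule `"pdi"` or `"brier"`.
#' @return Percent change (positive = degradation).
#' @export
accuracy_change <- function(score_learn, score_valid, rule = c("pdi", "brier")) {
  rule <- match.arg(rule)
  if (rule == "pdi") {
    100 * (score_learn - score_valid) / score_learn
  } else {
    100 * ((1 - score_learn) - (1 - score_valid)) / (1 - score_learn)
  }
}
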