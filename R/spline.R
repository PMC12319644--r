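#' Restricted cubic spline specification
#'
#' A `spline_spec` fixes the knot locations (and the normalisation
#' constant derived from them) of a restricted cubic spline.  Freezing
#' the knots into the specification is what allows a basis computed on
#' learning data to be re-evaluated, unchanged, on validation data.
#'
#' @param knots Strictly increasing numeric vector of at least 3 knot
#'   locations, in the units of the covariate.
#' @return An object of class `spline_spec` with elements `knots` and
#'   `norm` (the scale constant \eqn{(t_k - t_1)^2}).
#' @export
spline_spec <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) {
    stop("a restricted cubic spline needs at least 3 knots")
  }
  if (any(!is.finite(knots)) || any(diff(knots) <= 0)) {
    stop("knots must be finite and strictly increasing")
  }
  structure(
    list(knots = knots, norm = (knots[length(knots)] - knots[1L])^2),
    class = "spline_spec"
  )
}

#' Place restricted cubic spline knots at Harrell's default quantiles
#'
#' Knots are placed at fixed sample quantiles of the non-missing values:
#' (0.10, 0.50, 0.90) for 3 knots, (0.05, 0.35, 0.65, 0.95) for 4 and
#' (0.05, 0.275, 0.50, 0.725, 0.95) for 5.  Quantiles use the standard
#' linear-interpolation estimator (`type = 7`).
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @param k Number of knots, one of 3, 4 or 5.
#' @return A [spline_spec()].
#' @export
place_knots <- function(x, k = 4L) {
  if (!k %in% 3:5) stop("k must be 3, 4 or 5")
  x <- x[is.finite(x)]
  if (length(unique(x)) < k) {
    stop("too few distinct finite values to place ", k, " knots")
  }
  probs <- switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95)
  )
  kn <- unname(stats::quantile(x, probs, type = 7, names = FALSE))
  if (any(diff(kn) <= 0)) {
    stop("degenerate knot placement: quantiles are not strictly increasing")
  }
  spline_spec(kn)
}

#' Restricted cubic spline basis
#'
#' Evaluates the restricted truncated-power basis.  Column 1 is the
#' covariate itself; columns \eqn{j = 1, \dots, k-2} of the nonlinear
#' part are
#' \deqn{C_j(x) = \frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3
#'   \frac{t_k - t_j}{t_k - t_{k-1}} + (x-t_k)_+^3
#'   \frac{t_{k-1} - t_j}{t_k - t_{k-1}}}{(t_k - t_1)^2}}
#' which makes the implied function linear beyond the boundary knots and
#' twice continuously differentiable at every knot.  The division by
#' \eqn{(t_k-t_1)^2} keeps the nonlinear columns on a scale comparable
#' to the linear one; it rescales coefficients but not fitted values.
#'
#' @param x Finite numeric vector.
#' @param spec A [spline_spec()].
#' @return Numeric matrix with `length(x)` rows and `k - 1` columns.
#' @export
rcs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (any(!is.finite(x))) stop("x must be finite")
  kn <- spec$knots
  k <- length(kn)
  tk <- kn[k]
  tk1 <- kn[k - 1L]
  cube <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- kn[j]
    out[, j + 1L] <- (cube(x - tj) -
      cube(x - tk1) * (tk - tj) / (tk - tk1) +
      cube(x - tk) * (tk1 - tj) / (tk - tk1)) / spec$norm
  }
  out
}
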