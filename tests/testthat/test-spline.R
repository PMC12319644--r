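test_that("knot placement uses Harrell's default quantiles", {
  sp <- place_knots(1:100, 3)
  expect_equal(sp$knots, unname(quantile(1:100, c(0.1, 0.5, 0.9))),
               tolerance = 1e-10)
  expect_equal(sp$knots, c(10.9, 50.5, 90.1), tolerance = 1e-8)
  expect_error(place_knots(rep(2, 50), 3), "distinct")
  expect_error(place_knots(1:100, 6), "3, 4 or 5")
})

test_that("hand-evaluated basis row for knots (0,1,2,3) at x = 1.5", {
  sp <- spline_spec(c(0, 1, 2, 3))
  row <- rcs_basis(1.5, sp)
  expect_equal(as.vector(row), c(1.5, 0.375, 0.125 / 9), tolerance = 1e-10)
})

test_that("nonlinear columns vanish at and below the first knot", {
  sp <- spline_spec(c(2, 5, 8, 11))
  B <- rcs_basis(c(-3, 0, 2), sp)
  expect_equal(B[, 2:3], matrix(0, 3, 2))
})

test_that("basis is C2-continuous at knots and linear beyond them", {
  set.seed(41)
  # one-sided stencils exact for cubics: between knots the basis is a
  # single cubic, so left/right limits agree up to rounding only
  d1_side <- function(sp, t, h) {
    B <- rcs_basis(t + h * (0:3), sp)
    (-11 * B[1, ] + 18 * B[2, ] - 9 * B[3, ] + 2 * B[4, ]) / (6 * h)
  }
  d2_side <- function(sp, t, h) {
    B <- rcs_basis(t + h * (0:3), sp)
    (2 * B[1, ] - 5 * B[2, ] + 4 * B[3, ] - B[4, ]) / h^2
  }
  for (k in 3:5) {
    for (rep in 1:5) {
      kn <- sort(runif(k, 0, 10))
      if (min(diff(kn)) < 0.2) next
      sp <- spline_spec(kn)
      h <- min(diff(kn)) / 5
      for (t in kn) {
        expect_lt(max(abs(rcs_basis(t + 1e-9, sp) -
                            rcs_basis(t - 1e-9, sp))), 1e-6)
        expect_lt(max(abs(d1_side(sp, t, h) - d1_side(sp, t, -h))), 1e-6)
        expect_lt(max(abs(d2_side(sp, t, h) - d2_side(sp, t, -h))), 1e-6)
      }
      # linearity outside the boundary knots: second difference ~ 0
      for (x0 in c(kn[1] - 3, kn[k] + 5)) {
        B <- rcs_basis(x0 + c(0, 1, 2), sp)
        expect_lt(max(abs(B[3, ] - 2 * B[2, ] + B[1, ])), 1e-8)
      }
    }
  }
})

test_that("degenerate specs are rejected", {
  expect_error(spline_spec(c(1, 1, 2)), "strictly increasing")
  expect_error(spline_spec(c(0, 1)), "at least 3")
  expect_error(rcs_basis(c(1, NA), spline_spec(c(0, 1, 2))), "finite")
})
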