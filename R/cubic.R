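# Real roots of a cubic polynomial, closed form with a companion-matrix
# fallback. Used for stationary points and relaxation landing points, where
# robustness near double roots (fold tangencies) matters.

#' Real roots of c3*x^3 + c2*x^2 + c1*x + c0 = 0
#'
#' Solves the depressed cubic in closed form (Cardano / trigonometric
#' branch depending on the discriminant); if that fails numerically it
#' falls back to `polyroot()`. Roots with imaginary part below `im_tol`
#' (absolute) are accepted as real, so double roots at fold tangencies are
#' returned rather than lost to rounding.
#'
#' @param c3,c2,c1,c0 real coefficients, `c3 != 0`.
#' @param im_tol absolute imaginary-part tolerance for accepting a root as
#'   real (default 1e-9).
#' @return Sorted numeric vector of the real roots (length 1-3).
#' @export
cubic_real_roots <- function(c3, c2, c1, c0, im_tol = 1e-9) {
  stopifnot(is.finite(c3), c3 != 0)
  # depressed form t^3 + p t + q with x = t - c2/(3 c3)
  p <- c1 / c3 - (c2 / c3)^2 / 3
  q <- 2 * (c2 / c3)^3 / 27 - (c2 * c1) / (3 * c3^2) + c0 / c3
  shift <- -c2 / (3 * c3)
  disc <- (q / 2)^2 + (p / 3)^3
  # near-zero discriminant: double root; Cardano would lose it to rounding
  disc_tol <- 1e-12 * max((q / 2)^2, abs(p / 3)^3, 1e-300)
  roots <- if (!is.finite(disc)) {
    numeric(0)
  } else if (abs(disc) <= disc_tol && p < 0) {
    td <- sign(q / 2) * abs(q / 2)^(1 / 3)   # double root
    c(td, td, -2 * td) + shift
  } else if (disc > 0) {
    s <- sqrt(disc)
    cbrt <- function(z) sign(z) * abs(z)^(1 / 3)
    cbrt(-q / 2 + s) + cbrt(-q / 2 - s) + shift
  } else if (p == 0 && q == 0) {
    rep(shift, 3L)
  } else {
    # three real roots (or a double root at disc == 0)
    m <- 2 * sqrt(pmax(-p / 3, 0))
    arg <- 3 * q / (p * m)
    arg <- min(1, max(-1, arg))
    theta <- acos(arg) / 3
    m * cos(theta + c(0, -2, 2) * pi / 3) + shift
  }
  if (length(roots) == 0 || any(!is.finite(roots))) {
    z <- polyroot(c(c0, c1, c2, c3))
    roots <- Re(z[abs(Im(z)) < im_tol])
  }
  # Newton polish (guards the closed form against cancellation; skipped
  # automatically near double roots where the derivative vanishes)
  for (i in seq_along(roots)) {
    for (k in 1:3) {
      x <- roots[i]
      f <- ((c3 * x + c2) * x + c1) * x + c0
      df <- (3 * c3 * x + 2 * c2) * x + c1
      if (!is.finite(df) || abs(df) < 1e-12 * max(abs(c(c3, c2, c1)))) break
      roots[i] <- x - f / df
    }
  }
  sort(unique(roots))
}
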