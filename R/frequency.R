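# Analytic oscillation frequencies: linearized (near-Hopf) angular
# frequency, closed-form Hopf frequency, harmonic solution, and
# relaxation-oscillation periods by slow-branch loop integrals.

#' Linearized angular frequency at a stationary point
#'
#' omega0 = sqrt(det J). For the S-type oscillator at constant current
#' this is sqrt(g(x)/(C0*tau_k)); valid as an oscillation frequency near
#' the Hopf boundary where the trace is small.
#'
#' @inheritParams jacobian_at
#' @return Angular frequency (rad/s).
#' @export
omega0 <- function(params, drive = NULL, point = NULL) {
  td <- trace_det(params, point, drive)
  if (td[["det"]] <= 0)
    stop("determinant <= 0: no oscillatory linearization")
  sqrt(td[["det"]])
}

#' Angular frequency at the Hopf bifurcation
#'
#' omega0 evaluated at the critical capacitance C0B. Constant current:
#' omega0H = sqrt(g'(x) u - 1)/tau_k; constant voltage:
#' omega0H = sqrt((1 - g'u + g R0)/(R0*C0B*tau_k)). Finite for any finite
#' C0B.
#'
#' @inheritParams hopf_capacitance
#' @return Angular frequency at the bifurcation (rad/s).
#' @export
hopf_frequency <- function(params, drive, point = NULL) {
  stopifnot(inherits(params, "stype_params"))
  point <- resolve_point(params, point, drive)
  C0B <- hopf_capacitance(params, drive, point)
  if (!is.finite(C0B))
    stop("stationary point outside the NDR window: no Hopf bifurcation")
  dB <- if (drive$mode == "constant_current") drive_current(drive$I0, C0B)
        else drive_voltage(drive$Va, drive$R0, C0B)
  omega0(params, dB, point)
}

#' Harmonic (near-Hopf) oscillatory solution
#'
#' At the Hopf boundary the linearized solution is
#' u(t) = A0 cos(omega0 t - phi), x(t) = g(x) a0/tau_k * cos(omega0 t),
#' with amplitude A0 = a0*sqrt(g^2/C0^2 + g/(C0*tau_k)) and phase
#' phi = atan(omega0 C0 / g). Warns when C0 is further than 5% from C0B,
#' where the linearization no longer describes the limit cycle.
#'
#' @param params an [stype_params()] object.
#' @param drive drive spec (constant current).
#' @param a0 free mode-amplitude constant (default 1).
#' @param point optional stationary point.
#' @return List with `omega0` (rad/s), `TH` (s), `A0` (V), `A0_over_a0`,
#'   `phi` (rad), `a0`.
#' @export
harmonic_solution <- function(params, drive, a0 = 1, point = NULL) {
  stopifnot(inherits(params, "stype_params"))
  point <- resolve_point(params, point, drive)
  C0B <- hopf_capacitance(params, drive, point)
  if (is.finite(C0B) && abs(drive$C0 - C0B) / C0B > 0.05)
    warning("C0 differs from the Hopf value C0B by more than 5%; ",
            "the harmonic solution is only valid near the bifurcation")
  g <- stype_g(point[["x"]], params)
  w0 <- omega0(params, drive, point)
  A0r <- sqrt(g^2 / drive$C0^2 + g / (drive$C0 * params$tau_k))
  list(omega0 = w0, TH = 2 * pi / w0, A0 = a0 * A0r, A0_over_a0 = A0r,
       phi = atan(w0 * drive$C0 / g), a0 = a0)
}

#' Corner points of the relaxation orbit
#'
#' In the singular (relaxation) limit the orbit drifts along the two
#' stable outer branches of the slow-variable nullcline and jumps at the
#' folds at constant voltage. S-type: folds at x = IF1, IF2 on u = x/g(x);
#' the landing state on the opposite branch shares the fold voltage and is
#' the remaining root of the stationary cubic, x_land = 3b - 2*x_fold.
#' FHN: folds of the fast nullcline at u = -1, +1 with
#' x = I0 -/+ 2/(3 R0); landings at u = +2, -2.
#'
#' @param params [fhn_params()] or [stype_params()].
#' @return For S-type: list of four state points `r1`, `r2`, `t1`, `t2`
#'   (r1 -> r2 drift on the low-x branch ending at fold IF2; t1 -> t2
#'   drift on the high-x branch ending at fold IF1) plus `folds`. For FHN:
#'   list with `p1`, `p2` (folds) and landing points `q1`, `q2`.
#' @export
relaxation_orbit <- function(params) {
  if (inherits(params, "fhn_params")) {
    fp <- fhn_fold_points(params)
    return(list(p1 = fp$p1, p2 = fp$p2,
                q1 = state_point(2, fp$p1[["x"]]),
                q2 = state_point(-2, fp$p2[["x"]])))
  }
  stopifnot(inherits(params, "stype_params"))
  if (params$c <= 0) stop("no NDR window (c <= 0): no relaxation orbit")
  fp <- fold_points(params)
  b <- params$b
  x_land1 <- 3 * b - 2 * fp$IF1   # same voltage as fold IF1, low-x branch
  x_land2 <- 3 * b - 2 * fp$IF2   # same voltage as fold IF2, high-x branch
  list(r1 = state_point(fp$uF1, x_land1),  # arrive from fold 1
       r2 = state_point(fp$uF2, fp$IF2),   # leave at fold 2
       t1 = state_point(fp$uF2, x_land2),  # arrive from fold 2
       t2 = state_point(fp$uF1, fp$IF1),   # leave at fold 1
       folds = fp)
}

#' Closed-form antiderivative for the constant-current period integral
#'
#' B(x) = integral of du/(I0 - x) along the slow-variable nullcline
#' u = x/g(x):
#' B(x) = -(3a/2) x (-4b + 2 I0 + x) + (c - 3a (b - I0)^2) log|x - I0|.
#' The logarithm is taken of |x - I0|; each slow branch keeps a constant
#' sign of (x - I0), so within-branch differences are well defined.
#'
#' @param x internal state (A), vectorized; must not equal `I0`.
#' @param I0 drive current (A).
#' @param params an [stype_params()] object.
#' @return Dimensionless time factor; period contributions are C0 times
#'   within-branch differences of B.
#' @export
B_antiderivative <- function(x, I0, params) {
  stopifnot(inherits(params, "stype_params"))
  if (any(x == I0)) stop("B(x) has a pole at x = I0")
  a <- params$a; b <- params$b
  -1.5 * a * x * (-4 * b + 2 * I0 + x) +
    (params$c - 3 * a * (b - I0)^2) * log(abs(x - I0))
}

#' Relaxation-oscillation period, constant current
#'
#' Loop integral of the slow drift along the two outer branches,
#' TR = C0 * loop-integral of du/|I0 - x|, taken between the fold states
#' and the same-voltage landing states. `method = "closed_form"` uses the
#' antiderivative [B_antiderivative()]; `"quadrature"` integrates du/|I0 -
#' x(u)| adaptively along each branch (cross-check; agrees to ~1e-6
#' relative).
#'
#' @param I0 drive current (A), strictly inside the NDR window (IF2, IF1).
#' @param C0 capacitance (F).
#' @param params an [stype_params()] object.
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @return Period TR (s); exactly linear in C0.
#' @export
relaxation_period_cc <- function(I0, C0, params, method = c("closed_form",
                                                            "quadrature")) {
  method <- match.arg(method)
  fp <- fold_points(params)
  if (I0 <= fp$IF2 || I0 >= fp$IF1)
    stop("I0 outside the NDR window: no relaxation oscillation")
  orb <- relaxation_orbit(params)
  # branch 1 (low x): x from r1 to fold IF2; branch 2 (high x): t1 -> IF1
  if (method == "closed_form") {
    Bv <- function(x) B_antiderivative(x, I0, params)
    tb1 <- abs(Bv(orb$r2[["x"]]) - Bv(orb$r1[["x"]]))
    tb2 <- abs(Bv(orb$t2[["x"]]) - Bv(orb$t1[["x"]]))
    C0 * (tb1 + tb2)
  } else {
    C0 * (branch_time_quadrature(params, orb$r1[["x"]], orb$r2[["x"]],
                                 function(x, u) abs(I0 - x)) +
          branch_time_quadrature(params, orb$t1[["x"]], orb$t2[["x"]],
                                 function(x, u) abs(I0 - x)))
  }
}

#' Relaxation-oscillation period, constant voltage
#'
#' Adaptive quadrature of TR = C0*R0 * loop-integral of
#' du/|Va - (1 + g(x) R0) u| along the two slow outer branches between the
#' fold voltages. Valid in the singular limit eps = tau_k/(R0 C0) << 1;
#' the result is exactly proportional to tau0 = R0*C0. Requires the
#' (unique) stationary point to lie on the NDR branch, i.e. R0 strictly
#' between the two singular-limit Hopf resistances.
#'
#' @param Va applied voltage (V).
#' @param R0 series resistance (Ohm).
#' @param C0 capacitance (F).
#' @param params an [stype_params()] object.
#' @param rel_tol quadrature relative tolerance.
#' @return Period TR (s).
#' @export
relaxation_period_cv <- function(Va, R0, C0, params, rel_tol = 1e-10) {
  fp <- fold_points(params)
  pts <- stationary_points(params, drive_voltage(Va, R0, C0))
  on_ndr <- vapply(pts, function(p)
    p[["x"]] > fp$IF2 && p[["x"]] < fp$IF1, logical(1))
  if (!any(on_ndr))
    stop("stationary point not on the NDR branch: no relaxation oscillation")
  orb <- relaxation_orbit(params)
  denom <- function(x, u) abs(Va - (1 + stype_g(x, params) * R0) * u)
  t1 <- branch_time_quadrature(params, orb$r1[["x"]], orb$r2[["x"]], denom,
                               rel_tol = rel_tol)
  t2 <- branch_time_quadrature(params, orb$t1[["x"]], orb$t2[["x"]], denom,
                               rel_tol = rel_tol)
  C0 * R0 * (t1 + t2)
}

# Time integral along a slow branch of u = x/g(x), parameterized by x:
# integral of |du/dx| / denom(x, u) dx between x_from and x_to.
# du/dx = Rd vanishes at folds, so the integrand has an integrable zero
# there and plain adaptive quadrature suffices.
branch_time_quadrature <- function(params, x_from, x_to, denom,
                                   rel_tol = 1e-10) {
  f <- function(x) {
    u <- stype_stationary_voltage(x, params)
    abs(differential_resistance(x, params)) / denom(x, u)
  }
  abs(stats::integrate(Vectorize(f), x_from, x_to, rel.tol = rel_tol,
                       abs.tol = 0)$value)
}

#' Relaxation-oscillation period of the FHN model
#'
#' Slow-branch loop integral in the singular limit eps -> 0. The default
#' (`exact = FALSE`) is the symmetric two-segment approximation
#' TR = 2 * |integral from u = 1 to 2 of
#' (1 - u^2) * tauL / ((r0a - 1) u + u^3/3 - R0 I0) du|,
#' which treats the two slow branches as mirror images. With
#' `exact = TRUE` the two branches are integrated separately over their
#' actual voltage ranges (u in [1, 2] and [-2, -1], drift direction
#' signs), which differs slightly for I0 != 0.
#'
#' @param params an [fhn_params()] object (uses `I0`, `R0`, `Ra`, `tauL`).
#' @param exact use the exact asymmetric loop instead of the symmetric
#'   approximation.
#' @param rel_tol quadrature relative tolerance.
#' @return Period TR (s); linear in tauL.
#' @export
fhn_relaxation_period <- function(params, exact = FALSE, rel_tol = 1e-10) {
  stopifnot(inherits(params, "fhn_params"))
  den <- function(u) (params$r0a - 1) * u + u^3 / 3 - params$R0 * params$I0
  f <- function(u) (1 - u^2) * params$tauL / den(u)
  if (any(abs(den(seq(1, 2, length.out = 41))) < 1e-12) ||
      any(abs(den(seq(-2, -1, length.out = 41))) < 1e-12))
    stop("slow-branch integrand denominator vanishes in the range")
  if (!exact) {
    2 * abs(stats::integrate(f, 1, 2, rel.tol = rel_tol, abs.tol = 0)$value)
  } else {
    abs(stats::integrate(f, 1, 2, rel.tol = rel_tol, abs.tol = 0)$value) +
      abs(stats::integrate(f, -2, -1, rel.tol = rel_tol, abs.tol = 0)$value)
  }
}
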