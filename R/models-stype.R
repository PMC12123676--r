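#' Internal-state conductance of the S-type element
#'
#' g(x) = 1 / (a*(x^2 - 3*b*x + 3*b^2) - c). The reciprocal form is the
#' one consistent with the cubic stationary curve: u(x)*g(x) = x
#' identically on the stationary branch. The denominator must stay
#' positive; outside that domain the model is undefined and an error is
#' raised (clamping would silently corrupt period integrals).
#'
#' @param x internal state (A), vectorized.
#' @param params an [stype_params()] object.
#' @return Conductance(s) in 1/Ohm (`stype_g`) or its derivative in
#'   1/(Ohm*A) (`stype_g_prime`).
#' @examples
#' stype_g(0.2, stype_params())        # 1
#' stype_g_prime(0.2, stype_params())  # 10
#' @export
stype_g <- function(x, params) {
  stopifnot(inherits(params, "stype_params"))
  den <- params$a * (x^2 - 3 * params$b * x + 3 * params$b^2) - params$c
  if (any(den <= 0))
    stop(sprintf("conductance undefined: denominator <= 0 at x = %g",
                 x[which(den <= 0)[1]]))
  1 / den
}

#' @rdname stype_g
#' @export
stype_g_prime <- function(x, params) {
  g <- stype_g(x, params)
  -params$a * (2 * x - 3 * params$b) * g^2
}

#' Stationary voltage of the S-type element
#'
#' The cubic current-voltage characteristic
#' u(I0) = a*((I0 - b)^3 + b^3) - c*I0. At constant current the
#' stationary state is x = I0 with u = x/g(x); the closed form and the
#' conductance form agree identically.
#'
#' @param I0 current (A), vectorized.
#' @param params an [stype_params()] object.
#' @return Voltage(s) in V.
#' @export
stype_stationary_voltage <- function(I0, params) {
  stopifnot(inherits(params, "stype_params"))
  params$a * ((I0 - params$b)^3 + params$b^3) - params$c * I0
}

#' S-type oscillator vector field
#'
#' Constant current: du/dt = (I0 - g(x)*u)/C0.
#' Constant voltage: du/dt = (Va/R0 - (1/R0 + g(x))*u)/C0.
#' In both modes dx/dt = (g(x)*u - x)/tau_k.
#'
#' @param p state point `c(u=, x=)`.
#' @param params an [stype_params()] object.
#' @param drive a [drive_current()] or [drive_voltage()] object.
#' @return Named numeric vector `c(F =, G =)` (V/s, A/s).
#' @export
stype_rhs <- function(p, params, drive) {
  stopifnot(inherits(params, "stype_params"), inherits(drive, "drive_spec"))
  u <- p[["u"]]; x <- p[["x"]]
  g <- stype_g(x, params)
  Fv <- if (drive$mode == "constant_current") {
    (drive$I0 - g * u) / drive$C0
  } else {
    (drive$Va / drive$R0 - (1 / drive$R0 + g) * u) / drive$C0
  }
  c(F = Fv, G = (g * u - x) / params$tau_k)
}

#' Fold (turning) points of the S-type stationary curve
#'
#' The folds of u(I0) satisfy g'(x)*u(x) = 1; for the cubic characteristic
#' they sit at IF1 = b + sqrt(c/(3a)) and IF2 = b - sqrt(c/(3a)), with
#' voltages from the stationary curve. They bound the NDR window
#' (IF2 < x < IF1) where du/dx < 0.
#'
#' @param params an [stype_params()] object with `c >= 0`; `c > 0` for a
#'   genuine (non-degenerate) window.
#' @return List with `IF1`, `IF2` (A) and `uF1`, `uF2` (V), IF1 >= IF2.
#' @export
fold_points <- function(params) {
  stopifnot(inherits(params, "stype_params"))
  if (params$c < 0)
    stop("c < 0: no NDR window, fold points undefined")
  d <- sqrt(params$c / (3 * params$a))
  IF1 <- params$b + d
  IF2 <- params$b - d
  list(IF1 = IF1, IF2 = IF2,
       uF1 = stype_stationary_voltage(IF1, params),
       uF2 = stype_stationary_voltage(IF2, params))
}

#' Differential resistance of the stationary curve
#'
#' Rd = du/dx = (1 - g'(x)*u)/g(x) with u = x/g(x); negative exactly on
#' the NDR branch IF2 < x < IF1, zero at the folds.
#'
#' @inheritParams stype_g
#' @return Resistance(s) in Ohm.
#' @export
differential_resistance <- function(x, params) {
  g <- stype_g(x, params)
  u <- stype_stationary_voltage(x, params)
  (1 - stype_g_prime(x, params) * u) / g
}

#' Nullclines of a planar oscillator model
#'
#' Samples the u-values of the F = 0 (voltage) and G = 0 (internal state)
#' nullclines on a grid of x. S-type: F = 0 gives u = I0/g(x) (current
#' mode) or u = Va/(1 + g(x)*R0) (voltage mode); G = 0 gives u = x/g(x).
#' FHN: F = 0 is solved as x(u) and returned on a grid of u mapped to x by
#' the G = 0 relation; here both curves are reported as u(x) with the
#' F = 0 curve inverted numerically being unnecessary -- the FHN F = 0
#' curve is single-valued in u, so it is returned as `x_of_u` instead.
#' Nullclines are independent of C0, La and tau_k.
#'
#' @param params [fhn_params()] or [stype_params()].
#' @param x_grid numeric grid of the internal variable (S-type), or of
#'   voltage u (FHN).
#' @param drive drive spec (S-type only).
#' @return Data frame. S-type: columns `x`, `u_F0`, `u_G0`. FHN: columns
#'   `u`, `x_F0`, `x_G0`.
#' @export
nullclines <- function(params, x_grid, drive = NULL) {
  if (inherits(params, "stype_params")) {
    stopifnot(inherits(drive, "drive_spec"))
    g <- stype_g(x_grid, params)
    uF0 <- if (drive$mode == "constant_current") drive$I0 / g
           else drive$Va / (1 + g * drive$R0)
    data.frame(x = x_grid, u_F0 = uF0, u_G0 = x_grid / g)
  } else if (inherits(params, "fhn_params")) {
    u <- x_grid
    data.frame(u = u,
               x_F0 = params$I0 + (u - u^3 / 3) / params$R0,
               x_G0 = u / params$Ra)
  } else stop("params must be fhn_params or stype_params")
}

#' Stationary points of a model/drive combination
#'
#' Constant current (S-type): the unique stationary state x = I0,
#' u = stationary voltage. Constant voltage: real roots of
#' Va = a*((x-b)^3 + b^3) + (R0 - c)*x (1 to 3 points). FHN: real roots in
#' u of the stationary-current cubic at the drive current I0, with
#' x = u/Ra.
#'
#' @param params [fhn_params()] or [stype_params()].
#' @param drive drive spec (S-type only).
#' @return List of state points sorted by x, each with vector-field
#'   residual below 1e-10.
#' @export
stationary_points <- function(params, drive = NULL) {
  if (inherits(params, "fhn_params")) {
    # (1/(3 R0)) u^3 + (1/Ra - 1/R0) u - I0 = 0
    us <- cubic_real_roots(1 / (3 * params$R0), 0,
                           1 / params$Ra - 1 / params$R0, -params$I0)
    return(lapply(us, function(u) state_point(u, u / params$Ra)))
  }
  stopifnot(inherits(params, "stype_params"), inherits(drive, "drive_spec"))
  if (drive$mode == "constant_current") {
    x <- drive$I0
    list(state_point(stype_stationary_voltage(x, params), x))
  } else {
    # a (x-b)^3 + a b^3 + (R0 - c) x - Va = 0; the constant terms of the
    # expansion cancel to -Va
    a <- params$a; b <- params$b
    xs <- cubic_real_roots(a, -3 * a * b, 3 * a * b^2 + drive$R0 - params$c,
                           -drive$Va)
    lapply(xs, function(x) state_point(stype_stationary_voltage(x, params), x))
  }
}
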