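#' FitzHugh-Nagumo vector field
#'
#' Time derivatives of the FHN circuit:
#' du/dt = (u - u^3/3)/tau0 + (I0 - x)/C0,
#' dx/dt = u/(tauL*Ra) - x/tauL.
#'
#' @param p state point, named vector `c(u=, x=)` (see [state_point()]).
#' @param params an [fhn_params()] object.
#' @return Named numeric vector `c(F =, G =)`: du/dt (V/s) and dx/dt (A/s).
#' @export
fhn_rhs <- function(p, params) {
  stopifnot(inherits(params, "fhn_params"))
  u <- p[["u"]]; x <- p[["x"]]
  c(F = (u - u^3 / 3) / params$tau0 + (params$I0 - x) / params$C0,
    G = u / (params$tauL * params$Ra) - x / params$tauL)
}

#' Stationary drive current of the FHN circuit
#'
#' Current I0 that makes (u, x = u/Ra) a stationary point:
#' I0(u) = (u^3/3 - u)/R0 + u/Ra. Odd in u.
#'
#' @param u voltage (V), vectorized.
#' @param params an [fhn_params()] object.
#' @return Current(s) in A.
#' @examples
#' p <- fhn_params(R0 = 0.5, Ra = 0.417, tau0 = 0.01, eps = 0.4)
#' fhn_stationary_current(0.7, p)   # 0.5073 A
#' @export
fhn_stationary_current <- function(u, params) {
  stopifnot(inherits(params, "fhn_params"))
  (u^3 / 3 - u) / params$R0 + u / params$Ra
}

#' Hopf-bifurcation voltages of the FHN model
#'
#' The trace of the linearization, T = (1 - u^2 - eps)/tau0, vanishes at
#' u = +/- sqrt(1 - eps); between these voltages the stationary point is
#' unstable and a limit cycle exists. For eps >= 1 the window closes.
#'
#' @param params an [fhn_params()] object with `eps < 1`.
#' @return Numeric vector `c(-uH, +uH)`.
#' @export
fhn_hopf_voltage <- function(params) {
  stopifnot(inherits(params, "fhn_params"))
  if (params$eps >= 1)
    stop("eps >= 1: no oscillation window (trace never positive)")
  uH <- sqrt(1 - params$eps)
  c(-uH, uH)
}

# Fold points of the FHN fast (F = 0) nullcline
# x = I0 + (u - u^3/3)/R0: dx/du = 0 at u = +/- 1, giving
# p1 = (-1, I0 - 2/(3 R0)) and p2 = (1, I0 + 2/(3 R0)).
fhn_fold_points <- function(params) {
  list(p1 = state_point(-1, params$I0 - 2 / (3 * params$R0)),
       p2 = state_point(1, params$I0 + 2 / (3 * params$R0)))
}
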