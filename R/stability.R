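# Linear stability: Jacobians, trace/determinant, eigenvalue
# classification, and the closed-form Hopf boundaries of both models.

rhs_at <- function(p, params, drive = NULL) {
  if (inherits(params, "fhn_params")) fhn_rhs(p, params)
  else stype_rhs(p, params, drive)
}

#' Jacobian of the linearized system at a point
#'
#' Analytic Jacobian of the vector field evaluated at (u, x); for a
#' stationary point this is the matrix governing small displacements.
#' S-type constant current:
#' `[[-g/C0, -g'(x) u/C0], [g/tau_k, (g'(x) u - 1)/tau_k]]`;
#' constant voltage replaces the (1,1) entry by -(1/R0 + g)/C0.
#' A warning is issued when the supplied point is not stationary
#' (residual above `warn_tol`), since classification then has no meaning.
#'
#' @param params [fhn_params()] or [stype_params()].
#' @param point state point `c(u=, x=)`; default: the stationary point
#'   (unique, or error if ambiguous).
#' @param drive drive spec (S-type only).
#' @param warn_tol residual above which a non-stationary warning fires.
#' @return 2x2 numeric matrix (rows: dF, dG; columns: du, dx), units 1/s
#'   per respective state unit.
#' @export
jacobian_at <- function(params, point = NULL, drive = NULL,
                        warn_tol = 1e-8) {
  point <- resolve_point(params, point, drive)
  r <- rhs_at(point, params, drive)
  scale <- max(abs(point[["u"]]), abs(point[["x"]]), 1)
  if (max(abs(r)) > warn_tol * scale)
    warning(sprintf("point is not stationary (residual %.3g)", max(abs(r))))
  u <- point[["u"]]; x <- point[["x"]]
  if (inherits(params, "fhn_params")) {
    matrix(c((1 - u^2) / params$tau0, -1 / params$C0,
             1 / (params$tauL * params$Ra), -1 / params$tauL),
           2, 2, byrow = TRUE)
  } else {
    g <- stype_g(x, params); gp <- stype_g_prime(x, params)
    f_u <- if (drive$mode == "constant_current") -g / drive$C0
           else -(1 / drive$R0 + g) / drive$C0
    matrix(c(f_u, -gp * u / drive$C0,
             g / params$tau_k, (gp * u - 1) / params$tau_k),
           2, 2, byrow = TRUE)
  }
}

#' Trace and determinant of the linearization
#'
#' Closed forms: S-type constant current T = -g/C0 + (g'u - 1)/tau_k,
#' D = g/(C0*tau_k) (always positive); constant voltage
#' T = -(1/R0 + g)/C0 + (g'u - 1)/tau_k,
#' D = (1 - g'u + g*R0)/(R0*C0*tau_k); FHN T = (1 - u^2 - eps)/tau0,
#' D = (u^2 - 1 + r0a)/(tau0*tauL).
#'
#' @inheritParams jacobian_at
#' @return Named vector `c(trace =, det =)` (1/s, 1/s^2).
#' @export
trace_det <- function(params, point = NULL, drive = NULL) {
  point <- resolve_point(params, point, drive)
  u <- point[["u"]]; x <- point[["x"]]
  if (inherits(params, "fhn_params")) {
    c(trace = (1 - u^2 - params$eps) / params$tau0,
      det = (u^2 - 1 + params$r0a) / (params$tau0 * params$tauL))
  } else {
    g <- stype_g(x, params); gp <- stype_g_prime(x, params)
    tk <- params$tau_k
    if (drive$mode == "constant_current") {
      c(trace = -g / drive$C0 + (gp * u - 1) / tk,
        det = g / (drive$C0 * tk))
    } else {
      c(trace = -(1 / drive$R0 + g) / drive$C0 + (gp * u - 1) / tk,
        det = (1 - gp * u + g * drive$R0) / (drive$R0 * drive$C0 * tk))
    }
  }
}

#' Eigenvalues and qualitative class from trace and determinant
#'
#' lambda = (T +/- sqrt(T^2 - 4D))/2. Classes follow the standard
#' trace-determinant chart: saddle (D < 0); stable/unstable node (real
#' pair); stable/unstable focus (complex pair); `nonhyperbolic_hopf` when
#' the trace vanishes (scale-aware tolerance) with D > 0; `degenerate`
#' when D is (numerically) zero.
#'
#' @param trace trace of the Jacobian (1/s).
#' @param det determinant (1/s^2).
#' @param tol relative zero tolerance for the trace/determinant tests.
#' @param scale magnitude used for the zero test (defaults to values
#'   derived from `trace` and `det`).
#' @return List with complex `lambda` (length 2, lambda+ first) and
#'   character `class`.
#' @export
classify_eigen <- function(trace, det, tol = 1e-9, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(trace), sqrt(abs(det)), 1e-300)
  disc <- trace^2 - 4 * det
  lam <- if (disc >= 0) {
    s <- sqrt(disc)
    complex(real = c(trace + s, trace - s) / 2, imaginary = c(0, 0))
  } else {
    s <- sqrt(-disc) / 2
    complex(real = trace / 2, imaginary = c(s, -s))
  }
  cls <- if (abs(det) <= tol * scale^2) "degenerate"
    else if (det < 0) "saddle"
    else if (abs(trace) <= tol * scale) "nonhyperbolic_hopf"
    else if (disc >= 0) { if (trace < 0) "stable_node" else "unstable_node" }
    else { if (trace < 0) "stable_focus" else "unstable_focus" }
  list(lambda = lam, class = cls)
}

#' Full linear-stability report at a stationary point
#'
#' Convenience wrapper bundling the point, Jacobian, trace, determinant,
#' eigenvalues and class, plus the applicable Hopf boundary quantities
#' (critical capacitance `C0B` and critical ratio `eps_B`, where defined).
#'
#' @inheritParams jacobian_at
#' @return Object of class `"stability_report"`.
#' @export
stability_report <- function(params, point = NULL, drive = NULL) {
  point <- resolve_point(params, point, drive)
  J <- jacobian_at(params, point, drive)
  td <- trace_det(params, point, drive)
  eig <- classify_eigen(td[["trace"]], td[["det"]],
                        scale = max(abs(J[1, 1]), abs(J[2, 2]), 1e-300))
  C0B <- tryCatch(hopf_capacitance(params, drive, point),
                  error = function(e) NA_real_)
  epsB <- tryCatch(critical_epsilon(params, drive, point),
                   error = function(e) NA_real_)
  structure(list(point = point, jacobian = J, trace = td[["trace"]],
                 det = td[["det"]], lambda = eig$lambda, class = eig$class,
                 C0B = C0B, eps_B = epsB),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stationary point: u = %.6g V, x = %.6g A  [%s]\n",
              x$point[["u"]], x$point[["x"]], x$class))
  cat(sprintf("  trace = %.6g 1/s, det = %.6g 1/s^2\n", x$trace, x$det))
  cat(sprintf("  lambda = %.6g %+.6gi, %.6g %+.6gi\n",
              Re(x$lambda[1]), Im(x$lambda[1]),
              Re(x$lambda[2]), Im(x$lambda[2])))
  if (is.finite(x$C0B)) cat(sprintf("  C0B = %.6g F\n", x$C0B))
  if (is.finite(x$eps_B)) cat(sprintf("  eps_B = %.6g\n", x$eps_B))
  invisible(x)
}

#' Hopf-bifurcation capacitance of the S-type oscillator
#'
#' The capacitance at which the trace vanishes. Constant current:
#' C0B = tau_k * g(x) / (g'(x) u - 1); constant voltage:
#' C0B = (1/R0) * (g R0 + 1)/(g'u - 1) * tau_k. Oscillation requires
#' C0 > C0B. Defined only when the stationary point lies in the NDR
#' window (g'u > 1); outside it `NA` is returned with the `"no
#' bifurcation"` attribute-free convention of a plain NA.
#'
#' @param params an [stype_params()] object.
#' @param drive drive spec (its `C0` is irrelevant here).
#' @param point optional stationary point (computed if missing; voltage
#'   mode uses the unique stationary point and errors if there are
#'   several).
#' @return Critical capacitance C0B (F), or `NA` outside the NDR window.
#' @export
hopf_capacitance <- function(params, drive, point = NULL) {
  stopifnot(inherits(params, "stype_params"))
  point <- resolve_point(params, point, drive)
  u <- point[["u"]]; x <- point[["x"]]
  g <- stype_g(x, params)
  k <- stype_g_prime(x, params) * u - 1
  if (k <= 0) return(NA_real_)  # no bifurcation: point outside NDR window
  if (drive$mode == "constant_current") params$tau_k * g / k
  else (1 / drive$R0) * (g * drive$R0 + 1) / k * params$tau_k
}

#' Critical time-constant ratio for oscillation
#'
#' S-type voltage mode: eps_B = (g'u - 1)/(g R0 + 1); oscillation is
#' impossible for eps = tau_k/(R0 C0) > eps_B. Current mode: the analogous
#' ratio tau_k/(C0/g) gives eps_B = g'u - 1. FHN: eps_B = 1 - u^2.
#'
#' @inheritParams hopf_capacitance
#' @param params [fhn_params()] or [stype_params()].
#' @return Critical ratio (dimensionless); may be <= 0 (no window).
#' @export
critical_epsilon <- function(params, drive = NULL, point = NULL) {
  point <- resolve_point(params, point, drive)
  if (inherits(params, "fhn_params")) return(1 - point[["u"]]^2)
  u <- point[["u"]]; x <- point[["x"]]
  g <- stype_g(x, params)
  k <- stype_g_prime(x, params) * u - 1
  if (drive$mode == "constant_voltage") k / (g * drive$R0 + 1) else k
}

#' Singular-limit Hopf resistances at constant voltage
#'
#' In the relaxation limit eps -> 0 the Hopf bifurcations of the
#' voltage-driven S-type oscillator sit where the load line passes through
#' the fold points: R0H = (Va - u(IF))/IF for each fold. Oscillation
#' occurs for R0 strictly between the two values.
#'
#' @param params an [stype_params()] object.
#' @param Va applied voltage (V), above both fold voltages.
#' @return Named vector `c(R0H1 =, R0H2 =)` (Ohm), R0H1 < R0H2
#'   (R0H1 belongs to the upper fold current IF1).
#' @export
hopf_resistances <- function(params, Va) {
  fp <- fold_points(params)
  r <- c(R0H1 = (Va - fp$uF1) / fp$IF1, R0H2 = (Va - fp$uF2) / fp$IF2)
  if (any(r <= 0))
    stop("Va below a fold voltage: no oscillation window")
  r
}

# Resolve a possibly-missing point to the (unique) stationary point.
resolve_point <- function(params, point, drive) {
  if (!is.null(point)) return(point)
  pts <- stationary_points(params, drive)
  if (length(pts) != 1)
    stop(sprintf("%d stationary points; pass `point` explicitly", length(pts)))
  pts[[1]]
}
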