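# One-parameter sweeps: Hopf boundary curves, simulated amplitude
# envelopes, and frequency-versus-capacitance overlays.

#' Hopf-boundary sweep (critical capacitance vs a swept parameter)
#'
#' Evaluates the closed-form critical capacitance C0B along a sweep of
#' `I0` (constant current) or `R0` (constant voltage). Points whose
#' stationary state falls outside the NDR window are masked (`C0B = NA`,
#' `inside = FALSE`). C0B diverges towards the window edges.
#'
#' @param params an [stype_params()] object.
#' @param sweep_param `"I0"` or `"R0"`.
#' @param values numeric vector of swept values.
#' @param Va applied voltage (V), required when sweeping `R0`.
#' @return Data frame (class `"bifurcation_curve"`) with columns
#'   `value`, `C0B`, `inside`.
#' @export
hopf_boundary_sweep <- function(params, sweep_param = c("I0", "R0"),
                                values, Va = NULL) {
  sweep_param <- match.arg(sweep_param)
  C0B <- vapply(values, function(v) {
    d <- if (sweep_param == "I0") drive_current(v, C0 = 1)
         else drive_voltage(Va, v, C0 = 1)
    tryCatch({
      pts <- stationary_points(params, d)
      fp <- fold_points(params)
      ndr <- Filter(function(p) p[["x"]] > fp$IF2 && p[["x"]] < fp$IF1, pts)
      if (length(ndr) == 0) NA_real_
      else hopf_capacitance(params, d, ndr[[1]])
    }, error = function(e) NA_real_)
  }, numeric(1))
  structure(data.frame(value = values, C0B = C0B, inside = is.finite(C0B)),
            sweep_param = sweep_param,
            class = c("bifurcation_curve", "data.frame"))
}

#' Simulated amplitude envelope along a parameter sweep
#'
#' For each swept value the model is integrated and the post-transient
#' envelope (max/min of u) recorded together with the long-term verdict.
#' Consecutive points are warm-started from the previous final state to
#' shorten transients; the first point starts from the stationary point
#' perturbed by 1%.
#'
#' @param params an [stype_params()] object.
#' @param drive_template a drive spec whose `C0` (or other field) is
#'   replaced by the swept values.
#' @param sweep_param name of the drive field to sweep (e.g. `"C0"`).
#' @param values numeric vector of swept values.
#' @param t_end integration horizon per point (s); chosen automatically
#'   per point if NULL (30 linearized periods, min 20 tau_k).
#' @param ... passed to [integrate_model()].
#' @return Data frame (class `"amplitude_envelope"`) with columns
#'   `value`, `u_max`, `u_min`, `verdict`, `period`.
#' @export
amplitude_sweep <- function(params, drive_template, sweep_param = "C0",
                            values, t_end = NULL, ...) {
  init <- NULL
  rows <- lapply(values, function(v) {
    d <- drive_template
    d[[sweep_param]] <- v
    if (d$mode == "constant_voltage") d$tau0 <- d$R0 * d$C0
    pts <- stationary_points(params, d)
    st <- pts[[which.min(vapply(pts, function(p)
      abs(p[["x"]] - params$b), numeric(1)))]]
    # first point, or a warm start that converged onto the stationary
    # point (which may now be unstable): restart from a 1% perturbation
    if (is.null(init) ||
        max(abs(init - st)) < 1e-4 * max(abs(st), 1))
      init <<- state_point(st[["u"]] * 1.01 + 1e-4, st[["x"]] * 1.01 + 1e-4)
    te <- t_end
    if (is.null(te)) {
      td <- trace_det(params, st, d)
      tlin <- if (td[["det"]] > 0) 2 * pi / sqrt(td[["det"]]) else params$tau_k
      trel <- tryCatch(
        if (d$mode == "constant_current")
          relaxation_period_cc(d$I0, d$C0, params)
        else relaxation_period_cv(d$Va, d$R0, d$C0, params),
        error = function(e) 0)
      te <- max(30 * tlin, 20 * trel, 20 * params$tau_k)
    }
    traj <- integrate_model(params, init, te, d, ...)
    est <- estimate_period(traj)
    n <- nrow(traj)
    init <<- state_point(traj$u[n], traj$x[n])   # warm start
    if (est$verdict == "fixed_point") {
      data.frame(value = v, u_max = st[["u"]], u_min = st[["u"]],
                 verdict = est$verdict, period = NA_real_)
    } else {
      data.frame(value = v, u_max = est$u_max, u_min = est$u_min,
                 verdict = est$verdict, period = est$period)
    }
  })
  structure(do.call(rbind, rows), sweep_param = sweep_param,
            class = c("amplitude_envelope", "data.frame"))
}

#' Simulated and analytic frequency versus capacitance
#'
#' Sweeps `C0` (log-spaced grids are typical: the oscillatory window can
#' span four decades) at a fixed drive, measuring the simulated angular
#' frequency and tabulating the two analytic limits: the linearized
#' frequency omega0 = sqrt(det J) (valid near the Hopf boundary) and the
#' relaxation frequency 2*pi/TR (valid at large C0).
#'
#' @param params an [stype_params()] object.
#' @param drive_template drive spec; its `C0` is replaced per point.
#' @param C0_values capacitances to sweep (F).
#' @param t_end horizon per point (s), automatic if NULL.
#' @param ... passed to [integrate_model()].
#' @return Data frame with columns `C0`, `omega_sim`, `omega_harmonic`,
#'   `omega_relax`, `verdict`.
#' @export
frequency_vs_C0 <- function(params, drive_template, C0_values,
                            t_end = NULL, ...) {
  env <- amplitude_sweep(params, drive_template, "C0", C0_values,
                         t_end = t_end, ...)
  d1 <- drive_template
  omega_h <- vapply(C0_values, function(C0) {
    d1$C0 <- C0
    tryCatch(omega0(params, d1), error = function(e) NA_real_)
  }, numeric(1))
  TR1 <- if (drive_template$mode == "constant_current") {
    tryCatch(relaxation_period_cc(drive_template$I0, 1, params),
             error = function(e) NA_real_)
  } else {
    tryCatch(relaxation_period_cv(drive_template$Va, drive_template$R0, 1,
                                  params) / drive_template$R0,
             error = function(e) NA_real_)
  }
  data.frame(C0 = C0_values,
             omega_sim = 2 * pi / env$period,
             omega_harmonic = omega_h,
             omega_relax = 2 * pi / (TR1 * C0_values),
             verdict = env$verdict)
}
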