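#' FitzHugh-Nagumo circuit parameters
#'
#' Builds the parameter set of the FitzHugh-Nagumo (FHN) neuron circuit:
#' a fast voltage variable `u` with cubic nonlinearity (series resistance
#' `R0`, membrane capacitance `C0`) coupled to a slow recovery current `x`
#' (inductive branch with resistance `Ra`, inductance `La`), driven by a
#' constant current `I0`. The battery offset and control current are fixed
#' to zero.
#'
#' Two equivalent parameterizations are accepted: either the primitive
#' elements (`C0`, `La`) or the time constants (`tau0`, `eps`), matching
#' how parameter values are usually reported (tau0 = R0*C0, tauL = La/Ra,
#' eps = tau0/tauL). Derived values are always recomputed consistently.
#'
#' @param R0 series resistance of the fast branch (Ohm), > 0.
#' @param Ra resistance of the recovery branch (Ohm), > 0.
#' @param tau0 voltage response time R0*C0 (s). Give either (`tau0`,`eps`)
#'   or (`C0`,`La`).
#' @param eps dimensionless time-constant ratio tau0/tauL.
#' @param C0 capacitance (F), alternative to `tau0`.
#' @param La inductance (H), alternative to `eps`.
#' @param I0 drive current (A).
#' @return An object of class `"fhn_params"`: a list with fields `R0`,
#'   `Ra`, `C0`, `La`, `I0` and derived `tau0`, `tauL`, `eps`, `r0a`.
#' @examples
#' p <- fhn_params(R0 = 0.5, Ra = 0.417, tau0 = 0.01, eps = 0.4, I0 = 0.507)
#' p$C0        # tau0 / R0
#' p$r0a       # R0 / Ra
#' @export
fhn_params <- function(R0, Ra, tau0 = NULL, eps = NULL, C0 = NULL,
                       La = NULL, I0 = 0) {
  stopifnot(is.numeric(R0), R0 > 0, is.numeric(Ra), Ra > 0,
            is.numeric(I0), is.finite(I0))
  from_times <- !is.null(tau0) && !is.null(eps)
  from_elems <- !is.null(C0) && !is.null(La)
  if (from_times == from_elems)
    stop("give exactly one of (tau0, eps) or (C0, La)")
  if (from_times) {
    stopifnot(tau0 > 0, eps > 0)
    C0 <- tau0 / R0
    tauL <- tau0 / eps
    La <- tauL * Ra
  } else {
    stopifnot(C0 > 0, La > 0)
    tau0 <- R0 * C0
    tauL <- La / Ra
    eps <- tau0 / tauL
  }
  structure(list(R0 = R0, Ra = Ra, C0 = C0, La = La, I0 = I0,
                 tau0 = tau0, tauL = tauL, eps = eps, r0a = R0 / Ra),
            class = "fhn_params")
}

#' S-type oscillator device parameters
#'
#' Parameters of the S-type (voltage-multivalued) NDR element. The
#' stationary current-voltage curve is the cubic
#' u = a*((I - b)^3 + b^3) - c*I, realized by the internal-state
#' conductance g(x) = 1 / (a*(x^2 - 3*b*x + 3*b^2) - c); the state `x`
#' relaxes towards g(x)*u with time constant `tau_k`. A negative
#' differential resistance window (distinct fold points) exists iff c > 0.
#'
#' @param a cubic coefficient (V/A^3), > 0.
#' @param b current offset at the center of the S (A).
#' @param c series resistive term (Ohm).
#' @param tau_k internal relaxation time (s), > 0.
#' @return Object of class `"stype_params"`.
#' @examples
#' stype_params()   # the canonical a = 50, b = 0.2, c = 1, tau_k = 0.01 set
#' @export
stype_params <- function(a = 50, b = 0.2, c = 1, tau_k = 0.01) {
  stopifnot(is.numeric(a), a > 0, is.numeric(b), is.finite(b),
            is.numeric(c), is.finite(c), is.numeric(tau_k), tau_k > 0)
  structure(list(a = a, b = b, c = c, tau_k = tau_k),
            class = "stype_params")
}

#' Drive specification for the S-type oscillator
#'
#' The external circuit drives the device either at constant current
#' (galvanostatic; the series resistor plays no role) or at constant
#' voltage `Va` through a series resistor `R0` (potentiostatic), in both
#' cases with a parallel capacitor `C0`. In voltage mode the external time
#' constant is tau0 = R0*C0 and the slow/fast ratio is eps = tau_k/tau0.
#'
#' @param I0 applied current (A), current mode.
#' @param Va applied voltage (V), voltage mode.
#' @param R0 series resistance (Ohm), voltage mode, > 0.
#' @param C0 parallel capacitance (F), > 0.
#' @param tau_k optional internal relaxation time (s); when given, `eps`
#'   is derived for voltage mode.
#' @return Object of class `"drive_spec"` with field `mode` equal to
#'   `"constant_current"` or `"constant_voltage"` plus the fields of the
#'   active mode (`I0`, or `Va`, `R0`, `tau0` and possibly `eps`).
#' @examples
#' drive_current(I0 = 0.2, C0 = 0.0101)
#' drive_voltage(Va = 1, R0 = 4, C0 = 1, tau_k = 0.01)
#' @export
drive_current <- function(I0, C0) {
  stopifnot(is.numeric(I0), is.finite(I0), is.numeric(C0), C0 > 0)
  structure(list(mode = "constant_current", I0 = I0, C0 = C0),
            class = "drive_spec")
}

#' @rdname drive_current
#' @export
drive_voltage <- function(Va, R0, C0, tau_k = NULL) {
  stopifnot(is.numeric(Va), is.finite(Va), is.numeric(R0), R0 > 0,
            is.numeric(C0), C0 > 0)
  d <- list(mode = "constant_voltage", Va = Va, R0 = R0, C0 = C0,
            tau0 = R0 * C0)
  if (!is.null(tau_k)) d$eps <- tau_k / d$tau0
  structure(d, class = "drive_spec")
}

#' @export
print.fhn_params <- function(x, ...) {
  cat("FitzHugh-Nagumo parameters\n")
  cat(sprintf("  R0 = %g Ohm, Ra = %g Ohm, C0 = %g F, La = %g H\n",
              x$R0, x$Ra, x$C0, x$La))
  cat(sprintf("  tau0 = %g s, tauL = %g s, eps = %g, r0a = %g, I0 = %g A\n",
              x$tau0, x$tauL, x$eps, x$r0a, x$I0))
  invisible(x)
}

#' @export
print.stype_params <- function(x, ...) {
  cat(sprintf(
    "S-type NDR parameters: a = %g V/A^3, b = %g A, c = %g Ohm, tau_k = %g s\n",
    x$a, x$b, x$c, x$tau_k))
  invisible(x)
}

#' @export
print.drive_spec <- function(x, ...) {
  if (x$mode == "constant_current") {
    cat(sprintf("Drive: constant current I0 = %g A, C0 = %g F\n", x$I0, x$C0))
  } else {
    cat(sprintf("Drive: constant voltage Va = %g V, R0 = %g Ohm, C0 = %g F (tau0 = %g s)\n",
                x$Va, x$R0, x$C0, x$tau0))
  }
  invisible(x)
}

#' State point of a planar oscillator
#'
#' @param u voltage (V).
#' @param x internal variable (A): recovery/inductor current for the FHN
#'   model, conductance state for the S-type element.
#' @return Named numeric vector `c(u =, x =)`.
#' @export
state_point <- function(u, x) {
  stopifnot(is.finite(u), is.finite(x))
  c(u = as.numeric(u), x = as.numeric(x))
}
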