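# Shared fixtures and independent numerical oracles.

# canonical S-type parameter set used throughout the worked examples
sp_default <- function() stype_params(a = 50, b = 0.2, c = 1, tau_k = 0.01)

# FHN set of the worked examples (eps as in the oscillatory figure)
fhn_default <- function(eps = 0.4, I0 = 0.507)
  fhn_params(R0 = 0.5, Ra = 0.417, tau0 = 0.01, eps = eps, I0 = I0)

# central-difference derivative oracle
fd_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# finite-difference Jacobian oracle for any rhs(u, x) -> c(F, G)
fd_jacobian <- function(rhs, u, x, h = 1e-6) {
  unname(cbind((rhs(u + h, x) - rhs(u - h, x)) / (2 * h),
               (rhs(u, x + h) - rhs(u, x - h)) / (2 * h)))
}

# rhs closures for the oracle above
stype_rhs_fun <- function(params, drive) function(u, x)
  stype_rhs(state_point(u, x), params, drive)
fhn_rhs_fun <- function(params) function(u, x)
  fhn_rhs(state_point(u, x), params)

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * max(abs(expected), 1e-300))
}
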