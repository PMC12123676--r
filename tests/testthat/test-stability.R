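test_that("analytic Jacobians match hand values and finite differences", {
  sp <- sp_default()
  d <- drive_current(0.2, 0.01)
  J <- jacobian_at(sp, state_point(0.2, 0.2), d)
  expect_equal(J, matrix(c(-100, -200, 100, 100), 2, 2, byrow = TRUE),
               tolerance = 1e-12)
  # FHN at u = 0: F_u = 1/tau0
  p <- fhn_default(I0 = 0)
  Jf <- jacobian_at(p, state_point(0, 0))
  expect_equal(Jf[1, 1], 1 / p$tau0)
  # randomized finite-difference cross-check, all three model/mode cases
  set.seed(21)
  for (i in 1:7) {
    I0 <- runif(1, 0.13, 0.27)
    dcc <- drive_current(I0, runif(1, 0.005, 2))
    pt <- stationary_points(sp, dcc)[[1]]
    expect_equal(jacobian_at(sp, pt, dcc),
                 fd_jacobian(stype_rhs_fun(sp, dcc), pt[["u"]], pt[["x"]]),
                 tolerance = 1e-6)
  }
  for (i in 1:7) {
    dcv <- drive_voltage(runif(1, 0.9, 1.2), runif(1, 3.2, 6), runif(1, 0.01, 1))
    pts <- stationary_points(sp, dcv)
    pt <- pts[[1]]
    expect_equal(jacobian_at(sp, pt, dcv),
                 fd_jacobian(stype_rhs_fun(sp, dcv), pt[["u"]], pt[["x"]]),
                 tolerance = 1e-6)
  }
  pf <- fhn_default(I0 = 0.3)
  ptf <- stationary_points(pf)[[1]]
  expect_equal(jacobian_at(pf, ptf),
               fd_jacobian(fhn_rhs_fun(pf), ptf[["u"]], ptf[["x"]]),
               tolerance = 1e-6)
  # warns away from a stationary point
  expect_warning(jacobian_at(sp, state_point(0.5, 0.9), d),
                 "not stationary")
})

test_that("trace/determinant closed forms equal the Jacobian's", {
  sp <- sp_default()
  d10 <- drive_current(0.2, 10)
  td <- trace_det(sp, state_point(0.2, 0.2), d10)
  expect_equal(td[["det"]], 10)
  expect_equal(td[["trace"]], 100 - 0.1)
  p <- fhn_default(I0 = 0)
  expect_equal(trace_det(p, state_point(0, 0))[["trace"]], 60)
  # identity with the matrix, and positivity of det in current mode
  set.seed(22)
  for (i in 1:10) {
    I0 <- runif(1, 0.05, 0.35)
    d <- drive_current(I0, runif(1, 1e-3, 10))
    pt <- stationary_points(sp, d)[[1]]
    td <- trace_det(sp, pt, d)
    J <- suppressWarnings(jacobian_at(sp, pt, d))
    expect_rel_equal(td[["trace"]], J[1, 1] + J[2, 2], 1e-12)
    expect_rel_equal(td[["det"]], J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1],
                     1e-12)
    expect_gt(td[["det"]], 0)   # no saddle at constant current, ever
  }
})

test_that("eigenvalue computation and trace-determinant classification", {
  r <- classify_eigen(0, 4)
  expect_equal(r$lambda, c(2i, -2i))
  expect_equal(r$class, "nonhyperbolic_hopf")
  r <- classify_eigen(-3, 2)
  expect_equal(sort(Re(r$lambda)), c(-2, -1))
  expect_equal(r$class, "stable_node")
  expect_equal(classify_eigen(1, -1)$class, "saddle")
  expect_equal(classify_eigen(2, 2)$class, "unstable_focus")
  expect_equal(classify_eigen(-1, 5)$class, "stable_focus")
  expect_equal(classify_eigen(3, 2)$class, "unstable_node")
  expect_equal(classify_eigen(1, 0)$class, "degenerate")
  # sum/product identities on random (T, D)
  set.seed(23)
  for (i in 1:50) {
    T <- rnorm(1, sd = 10); D <- rnorm(1, sd = 10)
    lam <- classify_eigen(T, D)$lambda
    expect_lt(abs(sum(lam) - T), 1e-12 * max(abs(T), 1))
    expect_lt(abs(prod(lam) - D), 1e-12 * max(abs(D), 1))
  }
})

test_that("Hopf capacitance is the exact zero of the trace", {
  sp <- sp_default()
  dcc <- drive_current(0.2, 1)
  expect_equal(hopf_capacitance(sp, dcc), 0.01, tolerance = 1e-12)
  dcv <- drive_voltage(1, 4, 1)
  expect_equal(hopf_capacitance(sp, dcv), 0.0125, tolerance = 1e-12)
  # outside the NDR window: no bifurcation
  expect_true(is.na(hopf_capacitance(sp, drive_current(0.05, 1))))
  # trace vanishes at C0B; sign(T) = sign(C0 - C0B), both modes
  for (mk in list(function(C0) drive_current(0.2, C0),
                  function(C0) drive_voltage(1, 4, C0))) {
    C0B <- hopf_capacitance(sp, mk(1))
    expect_lt(abs(trace_det(sp, drive = mk(C0B))[["trace"]]),
              1e-10 / C0B)
    expect_gt(trace_det(sp, drive = mk(1.1 * C0B))[["trace"]], 0)
    expect_lt(trace_det(sp, drive = mk(0.9 * C0B))[["trace"]], 0)
  }
  # divergence toward the fold: C0B grows without bound
  fp <- fold_points(sp)
  near <- hopf_capacitance(sp, drive_current(fp$IF1 - 1e-6, 1))
  expect_gt(near, 1e2 * hopf_capacitance(sp, drive_current(0.2, 1)))
})

test_that("critical epsilon: closed forms and consistency with C0B", {
  sp <- sp_default()
  dcv <- drive_voltage(1, 4, 1)
  expect_equal(critical_epsilon(sp, dcv), 0.2, tolerance = 1e-12)
  expect_equal(critical_epsilon(fhn_default(I0 = 0), point = state_point(0, 0)), 1)
  # eps_B = tau_k / (R0 * C0B)
  C0B <- hopf_capacitance(sp, dcv)
  expect_rel_equal(critical_epsilon(sp, dcv), sp$tau_k / (4 * C0B), 1e-12)
})

test_that("singular-limit Hopf resistances pass through the folds", {
  sp <- sp_default()
  r <- hopf_resistances(sp, 1)
  expect_equal(unname(r[1]), 3.03, tolerance = 0.005 * 3.03)
  expect_equal(unname(r[2]), 6.30, tolerance = 0.005 * 6.30)
  # the load line at R0H passes exactly through the fold point
  fp <- fold_points(sp)
  expect_rel_equal((1 - fp$uF1) / r[["R0H1"]], fp$IF1, 1e-12)
  expect_rel_equal((1 - fp$uF2) / r[["R0H2"]], fp$IF2, 1e-12)
  # for R0 strictly between the pair the stationary point is on the NDR
  for (R0 in c(3.5, 4.5, 6)) {
    pts <- stationary_points(sp, drive_voltage(1, R0, 1))
    xs <- vapply(pts, `[[`, numeric(1), "x")
    expect_true(any(xs > fp$IF2 & xs < fp$IF1))
  }
  expect_error(hopf_resistances(sp, 0.1), "no oscillation window")
})

test_that("FHN Hopf voltages and the oscillation window", {
  p <- fhn_default()  # eps = 0.4
  uH <- fhn_hopf_voltage(p)
  expect_equal(uH, c(-1, 1) * sqrt(0.6), tolerance = 1e-12)
  expect_equal(uH[2], 0.7746, tolerance = 1e-4)
  # trace vanishes at u_Hopf, positive inside the window
  for (u in uH)
    expect_lt(abs(trace_det(p, state_point(u, u / p$Ra))[["trace"]]),
              1e-9 / p$tau0)
  expect_gt(trace_det(p, state_point(0.5, 0.5 / p$Ra))[["trace"]], 0)
  expect_lt(trace_det(p, state_point(0.9, 0.9 / p$Ra))[["trace"]], 0)
  expect_error(fhn_hopf_voltage(fhn_default(eps = 1)), "no oscillation")
})

test_that("opposite capacitance roles: FHN needs small C0, S-type large", {
  # FHN: increasing C0 at fixed R0, Ra, La raises eps and kills the window
  p_small <- fhn_params(R0 = 0.5, Ra = 0.417, C0 = 0.02, La = 0.417 / 40)
  p_large <- fhn_params(R0 = 0.5, Ra = 0.417, C0 = 0.08, La = 0.417 / 40)
  expect_lt(p_small$eps, 1)   # oscillation possible
  expect_gt(p_large$eps, 1)   # window closed
  # S-type: trace positive only above C0B
  sp <- sp_default()
  expect_lt(trace_det(sp, drive = drive_current(0.2, 0.005))[["trace"]], 0)
  expect_gt(trace_det(sp, drive = drive_current(0.2, 0.02))[["trace"]], 0)
})

test_that("stability_report bundles a consistent classification", {
  sp <- sp_default()
  rep <- stability_report(sp, drive = drive_current(0.2, 0.0101))
  expect_s3_class(rep, "stability_report")
  expect_equal(rep$class, "unstable_focus")
  expect_equal(rep$C0B, 0.01, tolerance = 1e-12)
  expect_rel_equal(Re(rep$lambda[1]) + Re(rep$lambda[2]), rep$trace, 1e-12)
  rep2 <- stability_report(sp, drive = drive_current(0.1, 1))
  expect_match(rep2$class, "stable")
  out <- capture.output(print(rep))
  expect_true(any(grepl("unstable_focus", out)))
})
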