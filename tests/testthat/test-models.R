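test_that("FHN vector field and stationary current are consistent", {
  p <- fhn_default()
  # u = 0: F reduces to (I0 - x)/C0, G to -x/tauL scaled by the drive
  r <- fhn_rhs(state_point(0, p$I0), p)
  expect_equal(r[["F"]], 0)
  expect_equal(r[["G"]], -p$I0 / p$tauL)
  # the true stationary point at u_app = 0.7 is (u, u/Ra) with I0 from
  # the stationary curve; residual vanishes in both components
  u <- 0.7
  p2 <- fhn_default(I0 = fhn_stationary_current(u, p))
  expect_equal(fhn_stationary_current(u, p), 0.507, tolerance = 1e-3)
  r2 <- fhn_rhs(state_point(u, u / p2$Ra), p2)
  expect_lt(max(abs(r2)), 1e-10)
  # stationary current is odd in u
  us <- seq(-2, 2, length.out = 17)
  expect_equal(fhn_stationary_current(-us, p),
               -fhn_stationary_current(us, p))
})

test_that("FHN parameterizations (tau0, eps) and (C0, La) agree", {
  p1 <- fhn_default()
  p2 <- fhn_params(R0 = 0.5, Ra = 0.417, C0 = p1$C0, La = p1$La,
                   I0 = 0.507)
  for (f in c("tau0", "tauL", "eps", "r0a", "C0", "La"))
    expect_rel_equal(p2[[f]], p1[[f]], 1e-12)
})

test_that("S-type conductance: values, closed forms, derivative oracle", {
  sp <- sp_default()
  expect_equal(stype_g(0.2, sp), 1.0)
  expect_equal(stype_g_prime(0.2, sp), 10.0)
  # c = 0 closed form at x = b
  sp0 <- stype_params(a = 50, b = 0.2, c = 0)
  expect_equal(stype_g(sp0$b, sp0), 1 / (sp0$a * sp0$b^2))
  # derivative matches central differences over the valid domain
  set.seed(11)
  xs <- runif(20, 0.4, 1.5)  # safely inside the domain (denominator > 0)
  for (x in xs)
    expect_rel_equal(stype_g_prime(x, sp),
                     fd_deriv(function(z) stype_g(z, sp), x), 1e-6)
  # out-of-domain error names the offending x (c large enough that the
  # denominator dips below zero near x = 3b/2)
  expect_error(stype_g(0.3, stype_params(a = 50, b = 0.2, c = 2)),
               "denominator")
})

test_that("stationary voltage satisfies u(x) * g(x) = x identically", {
  sp <- sp_default()
  expect_equal(stype_stationary_voltage(0.2, sp), 0.2)
  # at I0 = 0 the two cubic terms cancel exactly: u(0) = a((-b)^3+b^3) = 0
  expect_equal(stype_stationary_voltage(0, sp), 0)
  set.seed(12)
  xs <- c(runif(25, -0.5, 0.05), runif(25, 0.35, 1.2))
  for (x in xs)
    expect_rel_equal(stype_stationary_voltage(x, sp) * stype_g(x, sp),
                     x, 1e-12)
})

test_that("S-type rhs vanishes at stationary points in both modes", {
  sp <- sp_default()
  dcc <- drive_current(0.2, 1)
  expect_equal(unname(stype_rhs(state_point(0.2, 0.2), sp, dcc)), c(0, 0))
  dcv <- drive_voltage(1, 4, 1)
  expect_lt(max(abs(stype_rhs(state_point(0.2, 0.2), sp, dcv))), 1e-12)
  # G = 0 whenever x = g(x) u
  set.seed(13)
  for (x in runif(10, 0.4, 1)) {
    u <- x / stype_g(x, sp)
    expect_equal(stype_rhs(state_point(u, x), sp, dcc)[["G"]], 0)
  }
})

test_that("nullclines cross at stationary points and ignore C0/tau_k", {
  sp <- sp_default()
  xg <- seq(0.35, 1.2, length.out = 200)
  nc <- nullclines(sp, xg, drive_current(0.2, 1))
  # each sampled point solves its rate equation
  for (i in c(1, 100, 200)) {
    expect_lt(abs(stype_rhs(state_point(nc$u_F0[i], nc$x[i]), sp,
                            drive_current(0.2, 1))[["F"]]), 1e-10)
    expect_lt(abs(stype_rhs(state_point(nc$u_G0[i], nc$x[i]), sp,
                            drive_current(0.2, 1))[["G"]]), 1e-10)
  }
  # crossing at x = I0 (current mode), (0.2, 0.2) in voltage mode
  ncI <- nullclines(sp, 0.2, drive_current(0.2, 1))
  expect_equal(ncI$u_F0, ncI$u_G0)
  ncV <- nullclines(sp, 0.2, drive_voltage(1, 4, 1))
  expect_equal(ncV$u_F0, 0.2)
  expect_equal(ncV$u_G0, 0.2)
  # independence of C0 (and, for FHN, of the inductor)
  nc2 <- nullclines(sp, xg, drive_current(0.2, 123))
  expect_identical(nc$u_F0, nc2$u_F0)
  p1 <- fhn_default()
  p2 <- fhn_params(R0 = 0.5, Ra = 0.417, C0 = p1$C0 * 7, La = p1$La * 3,
                   I0 = p1$I0)
  expect_identical(nullclines(p1, seq(-2, 2, 0.1)),
                   nullclines(p2, seq(-2, 2, 0.1)))
})

test_that("fold points: values, tangency condition, NDR bracketing", {
  sp <- sp_default()
  fp <- fold_points(sp)
  expect_equal(fp$IF1, 0.2 + sqrt(1 / 150), tolerance = 1e-12)
  expect_equal(fp$IF2, 0.2 - sqrt(1 / 150), tolerance = 1e-12)
  expect_equal(fp$uF1, 0.1456, tolerance = 1e-3)
  expect_equal(fp$uF2, 0.2544, tolerance = 1e-3)
  # g'(xF) u(xF) = 1 at both folds
  for (xF in c(fp$IF1, fp$IF2))
    expect_lt(abs(stype_g_prime(xF, sp) *
                    stype_stationary_voltage(xF, sp) - 1), 1e-10)
  # differential resistance changes sign across each fold
  h <- 1e-3
  expect_lt(differential_resistance(fp$IF1 - h, sp), 0)
  expect_gt(differential_resistance(fp$IF1 + h, sp), 0)
  expect_gt(differential_resistance(fp$IF2 - h, sp), 0)
  expect_lt(differential_resistance(fp$IF2 + h, sp), 0)
  # degenerate window at c = 0; error for c < 0
  fp0 <- fold_points(stype_params(a = 50, b = 0.2, c = 0))
  expect_equal(fp0$IF1, fp0$IF2)
  expect_error(fold_points(stype_params(a = 50, b = 0.2, c = -1)), "NDR")
})

test_that("differential resistance values on and off the NDR branch", {
  sp <- sp_default()
  expect_equal(differential_resistance(0.2, sp), -1)
  expect_gt(differential_resistance(0.05, sp), 0)
  fp <- fold_points(sp)
  expect_lt(abs(differential_resistance(fp$IF1, sp)), 1e-10)
})

test_that("stationary points: all modes, sorted, zero residual", {
  sp <- sp_default()
  # voltage mode, single intersection
  pts <- stationary_points(sp, drive_voltage(1, 4, 1))
  expect_length(pts, 1)
  expect_equal(unname(pts[[1]]), c(0.2, 0.2), tolerance = 1e-12)
  # current mode
  pcc <- stationary_points(sp, drive_current(0.2, 1))
  expect_equal(pcc[[1]][["x"]], 0.2)
  # FHN: u_app = 0.7 current recovers the stationary state
  p <- fhn_default(I0 = fhn_stationary_current(0.7, fhn_default()))
  pts_f <- stationary_points(p)
  u_near <- vapply(pts_f, `[[`, numeric(1), "u")
  expect_true(any(abs(u_near - 0.7) < 1e-9))
  # residuals vanish everywhere
  for (q in pts_f) expect_lt(max(abs(fhn_rhs(q, p))), 1e-10)
  for (q in pts) expect_lt(max(abs(stype_rhs(q, sp,
                                             drive_voltage(1, 4, 1)))), 1e-10)
  # a low-R0 load line cuts the S three times
  pts3 <- stationary_points(sp, drive_voltage(0.45, 0.5, 1))
  expect_true(length(pts3) %in% c(1, 2, 3))
  expect_equal(vapply(pts3, `[[`, numeric(1), "x"),
               sort(vapply(pts3, `[[`, numeric(1), "x")))
})

test_that("cubic solver matches polyroot on random cubics", {
  set.seed(14)
  for (i in 1:25) {
    co <- rnorm(4); co[1] <- co[1] + sign(co[1]) * 0.5
    r <- cubic_real_roots(co[1], co[2], co[3], co[4])
    z <- polyroot(rev(co))
    r_ref <- sort(Re(z[abs(Im(z)) < 1e-7]))
    expect_equal(length(r), length(r_ref))
    expect_equal(r, r_ref, tolerance = 1e-6)
    # residuals at the polished roots
    for (x in r)
      expect_lt(abs(((co[1] * x + co[2]) * x + co[3]) * x + co[4]),
                1e-10 * max(abs(co)))
  }
  # double root at a fold tangency is recovered
  r2 <- cubic_real_roots(1, -2, 1, 0)  # x (x - 1)^2
  expect_equal(r2, c(0, 1), tolerance = 1e-6)
})
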