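test_that("Newton septum volume matches a bisection oracle on a grid", {
  p <- default_params()
  set.seed(21)
  cases <- expand.grid(V_lv = seq(45, 115, length.out = 5),
                       V_rv = seq(45, 115, length.out = 5),
                       e = c(0.01, 0.2, 0.6, 1.0))
  for (i in seq_len(nrow(cases))) {
    V_lv <- cases$V_lv[i]; V_rv <- cases$V_rv[i]; e <- cases$e[i]
    v <- septum_volume(V_lv, V_rv, e, p)
    # independent oracle: stats::uniroot at tight tolerance
    oracle <- stats::uniroot(function(x) septum_residual(x, V_lv, V_rv, e, p),
                             lower = -V_rv + 1e-6, upper = V_lv - 1e-6,
                             tol = 1e-12)$root
    expect_lt(abs(v - oracle), 1e-8)
    expect_lt(abs(septum_residual(v, V_lv, V_rv, e, p)), 1e-9)
  }
})

test_that("warm-started Newton agrees with cold start", {
  p <- default_params()
  v_cold <- septum_volume(100, 90, 0.5, p)
  v_warm <- septum_volume(100, 90, 0.5, p, septum_options(guess = v_cold))
  expect_lt(abs(v_cold - v_warm), 1e-8)
})

test_that("symmetric free walls with equal volumes give a zero septum volume", {
  # make the right free wall identical to the left and remove the septum
  # wall's offset volumes: the trans-septal balance is then exactly symmetric
  p <- default_params()
  p_sym <- cvs_params(E_rvf = p$E_lvf, P0_rvf = p$P0_lvf,
                      lambda_rvf = p$lambda_lvf, V0_rvf = p$V0_lvf,
                      Vd_rvf = p$Vd_lvf, V0_spt = 0, Vd_spt = 0)
  for (e in c(0.05, 0.5, 1)) {
    expect_equal(septum_residual(0, 80, 80, e, p_sym), 0, tolerance = 1e-12)
    expect_lt(abs(septum_volume(80, 80, e, p_sym)), 1e-8)
  }
})

test_that("the residual brackets exactly one root in the physiological range", {
  p <- default_params()
  grid <- seq(-80, 80, length.out = 401)
  r <- septum_residual(grid, 90, 85, 0.3, p)
  signs <- sign(r)
  expect_identical(sum(diff(signs) != 0), 1L)  # one sign change
  expect_true(all(diff(r) > 0))                # strictly increasing
})

test_that("pericardium pressure equals P_th at the unstressed volume and is monotone", {
  p <- default_params()
  expect_equal(pericardium_pressure(p$V0_pcd / 2, p$V0_pcd / 2, p), p$P_th,
               tolerance = 1e-12)
  expect_equal(pericardium_pressure(p$V0_pcd / 2, p$V0_pcd / 2, p), -4,
               tolerance = 1e-12)
  V <- seq(120, 260, by = 5)
  pp <- pericardium_pressure(V / 2, V / 2, p)
  expect_true(all(diff(pp) > 0))
})

test_that("pericardium pressure matches a hand evaluation of the chamber law", {
  p <- default_params()
  V_lv <- 102.3; V_rv <- 96.1
  hand <- p$P0_pcd * (exp(p$lambda_pcd * ((V_lv + V_rv) - p$V0_pcd)) - 1) +
    p$P_th
  expect_equal(pericardium_pressure(V_lv, V_rv, p), hand, tolerance = 1e-14)
  expect_error(pericardium_pressure(-1, 90, p), "positive")
})
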