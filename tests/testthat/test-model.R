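test_that("the six volume derivatives always sum to zero (closed loop)", {
  p <- default_params()
  set.seed(31)
  for (i in 1:25) {
    u <- cvs_state(Q_mt = runif(1, 0, 300), Q_av = runif(1, 0, 500),
                   Q_tc = runif(1, 0, 300), Q_pv = runif(1, 0, 500),
                   V_lv = runif(1, 50, 120), V_rv = runif(1, 50, 120),
                   V_ao = runif(1, 100, 170), V_vc = runif(1, 280, 380),
                   V_pa = runif(1, 30, 90), V_pu = runif(1, 700, 900))
    du <- cvs_rhs(u, runif(1, 0, 0.75), p)
    expect_lt(abs(sum(du[5:10])), 1e-10)
  }
})

test_that("callback mode wrapping the mechanistic pair reproduces mechanistic rhs", {
  p <- default_params()
  # the callback sees only volumes, so capture the driver phase per time point
  for (t in c(0.05, 0.27, 0.5)) {
    e <- cardiac_driver(t, p)
    vi_wrap <- vi_callback(function(V_lv, V_rv, V_ao, V_vc, V_pa) {
      c(septum_volume(V_lv, V_rv, e, p),
        pericardium_pressure(V_lv, V_rv, p))
    })
    u <- cvs_initial_state()
    expect_identical(cvs_rhs(u, t, p, vi_wrap),
                     cvs_rhs(u, t, p, vi_mechanistic()))
  }
})

test_that("derived quantities respect their defining identities", {
  p <- default_params()
  u <- cvs_initial_state()
  for (t in c(0, 0.15, 0.3)) {
    d <- derived_quantities(u, t, p)
    expect_identical(d[["V_pcd"]], unname(u["V_lv"] + u["V_rv"]))
    expect_identical(sign(d[["Q_sys"]]), sign(d[["P_ao"]] - d[["P_vc"]]))
    expect_equal(d[["Q_sys"]], (d[["P_ao"]] - d[["P_vc"]]) / p$R_sys,
                 tolerance = 1e-14)
    expect_equal(d[["P_peri"]],
                 pericardium_pressure(u[["V_lv"]], u[["V_rv"]], p),
                 tolerance = 1e-14)
  }
})

test_that("in no-VI mode the interaction terms are omitted", {
  p <- default_params()
  d <- derived_quantities(cvs_initial_state(), 0.1, p, vi_none())
  expect_identical(d[["V_spt"]], 0)
  expect_identical(d[["P_peri"]], 0)
})

test_that("a closed valve under an adverse gradient has zero flow derivative", {
  p <- default_params()
  # at beat onset the aortic valve is shut: P_lv << P_ao
  u <- cvs_initial_state()
  d <- derived_quantities(u, 0, p)
  expect_lt(d[["P_lv"]], d[["P_ao"]])
  expect_identical(unname(u["Q_av"]), 0)
  du <- cvs_rhs(u, 0, p)
  expect_identical(du[["Q_av"]], 0)
  # and the pulmonary valve likewise
  expect_lt(d[["P_rv"]], d[["P_pa"]])
  expect_identical(du[["Q_pv"]], 0)
})

test_that("rhs is consistent with the integrator over one small step", {
  p <- default_params()
  h <- 1e-4  # below the millisecond L/R decay scale of the valve flows
  tr <- cvs_integrate(p, t_end = 10 * h,
                      settings = solver_settings(dt = h))
  fd <- (tr$states[2, ] - tr$states[1, ]) / h
  du <- cvs_rhs(cvs_initial_state(), 0, p)
  # finite-difference oracle: agreement to O(h) relative error
  scale <- pmax(abs(du), 1)
  expect_lt(max(abs(fd - du) / scale), 0.05)
})
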