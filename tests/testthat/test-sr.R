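test_that("expression parsing, canonical serialization and evaluation round-trip", {
  set.seed(61)
  data <- data.frame(V_lv = runif(200, 50, 120), V_rv = runif(200, 50, 120),
                     V_ao = runif(200, 110, 170), V_vc = runif(200, 280, 380),
                     V_pa = runif(200, 30, 90))
  cfg <- sr_config(seed = 1)
  for (i in 1:50) {
    e <- sr_expression(cvsude:::random_tree(3, cfg))
    s <- format_expression(e)
    e2 <- parse_expression(s)
    v1 <- eval_expression(e, data)
    v2 <- eval_expression(e2, data)
    ok <- is.finite(v1)
    expect_identical(v1[ok], v2[ok])
    # canonical form is a fixed point of parse/serialize
    expect_identical(format_expression(e2), s)
  }
})

test_that("the grammar is enforced on parse", {
  expect_error(parse_expression("sin(V_lv)"), "grammar")
  expect_error(parse_expression("V_lv + V_bogus"), "unknown variable")
  expect_error(parse_expression("V_lv +"), "parse error")
  expect_error(parse_expression("V_lv ^ V_rv"), "integer powers")
  # integer powers expand into products
  e <- parse_expression("V_pa^2")
  expect_identical(format_expression(e), "(V_pa * V_pa)")
  # unary minus folds into constants
  expect_identical(format_expression(parse_expression("-3.5 + V_lv")),
                   "(-3.5 + V_lv)")
})

test_that("all six shipped reference expressions parse and evaluate", {
  vols <- volume_matrix(short_gt())
  for (nz in c(0, 0.02, 0.05)) {
    ex <- reference_learned_expressions(nz)
    expect_named(ex, c("V_spt", "P_peri"))
    for (e in ex) {
      v <- eval_expression(e, vols)
      expect_true(all(is.finite(v)))
    }
    # the pericardial expressions all carry a constant near the
    # intrathoracic pressure of -4 mmHg
    pp <- eval_expression(ex$P_peri, vols)
    expect_true(all(pp > -6 & pp < -2))
  }
})

test_that("candidate scores follow the log-loss-per-complexity trade-off", {
  cands <- list(sr_expression("1.5", loss = 4),
                sr_expression("V_rv", loss = 1),
                sr_expression("(V_rv + (V_pa * 0.5))", loss = 0.25))
  scored <- score_candidates(cands, baseline = 4)
  by_str <- function(s) {
    scored[[which(vapply(scored, format_expression, "") == s)]]
  }
  # the complexity-1 variable improves on the baseline: log(4/1)/1
  expect_equal(by_str("V_rv")$score, log(4), tolerance = 1e-12)
  # the complexity-1 constant ties the baseline: dominated, score 0
  expect_identical(by_str("1.5")$score, 0)
  # complexity 5 frontier member: (log 1 - log 0.25)/(5 - 1)
  expect_equal(by_str("((0.5 * V_pa) + V_rv)")$score, log(4) / 4,
               tolerance = 1e-12)
  best <- select_best(scored)
  expect_identical(format_expression(best), "V_rv")
})

test_that("select_best breaks ties toward simplicity", {
  cands <- list(sr_expression("(V_rv + 1)", loss = 1, score = 2),
                sr_expression("V_rv", loss = 1, score = 2))
  expect_identical(format_expression(select_best(cands)), "V_rv")
  expect_error(select_best(list()), "empty")
})

test_that("the engine recovers a planted linear law in most seeded runs", {
  vols <- volume_matrix(short_gt())
  y <- 2 * vols[, "V_rv"] - 4
  hits <- 0L
  for (s in 1:10) {
    ds <- structure(list(inputs = vols,
                         targets = list(V_spt = y)), class = "sr_dataset")
    cands <- fit_expressions(ds, sr_config(population = 150, generations = 8,
                                           seed = s))
    best <- select_best(cands$V_spt)
    if (max(abs(eval_expression(best, vols) - y)) < 1e-3) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("a constant target is recovered as a complexity-1 constant", {
  vols <- volume_matrix(short_gt())
  ds <- structure(list(inputs = vols,
                       targets = list(P_peri = rep(-4.2, nrow(vols)))),
                  class = "sr_dataset")
  cands <- fit_expressions(ds, sr_config(population = 100, generations = 3,
                                         seed = 2))
  best <- select_best(cands$P_peri)
  expect_identical(best$complexity, 1L)
  expect_equal(eval_expression(best, vols)[1], -4.2, tolerance = 1e-6)
})

test_that("SR dataset extraction averages members and drops the initial row", {
  p <- default_params()
  sc <- scaling_from_trajectory(short_gt())
  m <- hybrid_model(p, init_network(1), sc)
  ds <- extract_sr_dataset(list(m, m), horizon = 0.3)
  ds1 <- extract_sr_dataset(list(m), horizon = 0.3)
  expect_identical(nrow(ds$inputs), 30L)
  expect_equal(ds$targets$V_spt, ds1$targets$V_spt, tolerance = 1e-14)
  expect_identical(colnames(ds$inputs),
                   c("V_lv", "V_rv", "V_ao", "V_vc", "V_pa"))
  # construction cross-check: inputs are the member's own volume series
  tr <- cvs_integrate(p, cvs_initial_state(), 0.3, as_vi_provider(m))
  expect_equal(unname(ds1$inputs), unname(tr$states[-1, 5:9]),
               tolerance = 1e-14)
})

test_that("degenerate SR datasets are rejected", {
  ds <- structure(list(inputs = matrix(1, 2, 5),
                       targets = list(V_spt = c(1, 2))), class = "sr_dataset")
  expect_error(fit_expressions(ds), "degenerate")
  ds2 <- structure(list(inputs = matrix(rnorm(50), 10, 5),
                        targets = list(V_spt = c(NaN, rep(1, 9)))),
                   class = "sr_dataset")
  expect_error(fit_expressions(ds2), "non-finite")
})

test_that("partially learned models integrate and enforce the grammar", {
  p <- default_params()
  ex <- reference_learned_expressions(0)
  plm <- make_partially_learned_model(ex$V_spt, ex$P_peri, p)
  tr <- cvs_integrate(p, cvs_initial_state(), 1, plm, derived = TRUE)
  expect_true(all(is.finite(tr$states)))
  # the distilled V_spt stays in the physiological range of the reference
  expect_true(all(tr$derived[, "V_spt"] > 0 & tr$derived[, "V_spt"] < 12))
  expect_error(make_partially_learned_model("V_lv + * 2", ex$P_peri, p),
               "parse error")
  # substituting the closed-form pericardial law recovers it exactly
  pp_expr <- sprintf("(%.6g * (exp(%.6g * ((V_lv + V_rv) - %.6g)) - 1)) + %.6g",
                     p$P0_pcd, p$lambda_pcd, p$V0_pcd, p$P_th)
  plm2 <- make_partially_learned_model(ex$V_spt, pp_expr, p)
  d <- cvs_integrate(p, cvs_initial_state(), 0.1, plm2, derived = TRUE)
  expect_equal(d$derived[, "P_peri"],
               pericardium_pressure(d$states[, 5], d$states[, 6], p),
               tolerance = 1e-9)
})

test_that("expression files round-trip with target metadata", {
  ex <- reference_learned_expressions(0.05)
  f <- withr::local_tempfile(fileext = ".txt")
  write_expressions(ex, f, noise = 0.05)
  back <- read_expressions(f)
  expect_identical(format_expression(back$V_spt), format_expression(ex$V_spt))
  expect_identical(format_expression(back$P_peri),
                   format_expression(ex$P_peri))
})
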