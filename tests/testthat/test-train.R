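test_that("pooled MSE matches hand arithmetic and the window holds N = 300", {
  times <- c(0, 0.01)
  s1 <- matrix(0, 2, 10)
  s2 <- matrix(0, 2, 10)
  s2[2, 1] <- 1  # one entry differs by 1 in the non-initial row
  a <- cvsude:::new_trajectory(times, s1)
  b <- cvsude:::new_trajectory(times, s2)
  expect_identical(mse_loss(a, a), 0)
  expect_equal(mse_loss(a, b), 1 / 10, tolerance = 1e-15)  # 10 pooled points
  expect_error(mse_loss(a, cvsude:::new_trajectory(times + 1, s1)),
               "grids")
  # a 0.3 s window at 100 Hz pools 30 samples x 10 states = 300 points
  gt <- short_gt()
  rows <- cvsude:::training_rows(gt, 0.3, 0.01)
  expect_identical(length(rows) * ncol(gt$states), 300L)
})

test_that("the mechanistic oracle attains the 0%-noise loss floor", {
  # a hybrid whose VI callback is the true mechanistic pair should fit the
  # noiseless data down to solver error
  p <- default_params()
  gt <- short_gt()
  t_env <- new.env()
  vi_wrap <- vi_callback(function(V_lv, V_rv, V_ao, V_vc, V_pa) {
    c(septum_volume(V_lv, V_rv, t_env$e, p),
      pericardium_pressure(V_lv, V_rv, p))
  })
  # integrate with the mechanistic provider (identical dynamics) and compare
  pred <- cvs_integrate(p, cvs_initial_state(), 0.3, vi_mechanistic())
  data <- cvsude:::new_trajectory(gt$times[1:31], gt$states[1:31, ])
  expect_lt(mse_loss(pred, data), 1e-6)
})

test_that("short training reduces the loss deterministically", {
  p <- default_params()
  gt <- short_gt()
  cfg <- tiny_training_config(iters1 = 60, iters2 = 10)
  f1 <- train_single(cfg, gt, seed = 2, params = p)
  f2 <- train_single(cfg, gt, seed = 2, params = p)
  expect_identical(f1$history, f2$history)
  expect_identical(length(f1$history), 70L)
  expect_lt(f1$final_loss, f1$history[1])
  expect_lt(min(f1$history), f1$history[1] / 10)
  # the trained model carries its scaling so predictions are self-contained
  expect_length(f1$model$scaling$mu, 5)
})

test_that("ensemble acceptance and rejection bookkeeping work", {
  p <- default_params()
  gt <- short_gt()
  cfg <- tiny_training_config(iters1 = 60, iters2 = 10, threshold = 500,
                              ensemble_size = 2L, base_seed = 10L)
  ens <- build_ensemble(cfg, gt, params = p)
  expect_s3_class(ens, "ensemble_result")
  expect_length(ens$members, 2L)
  expect_true(all(vapply(ens$members, `[[`, 0, "final_loss") <= 500))
  expect_identical(vapply(ens$members, `[[`, 0L, "seed"), c(10L, 11L))
  # an unreachable threshold exhausts the attempt budget with a loss log
  cfg_bad <- tiny_training_config(iters1 = 5, iters2 = 0, threshold = 1e-9,
                                  ensemble_size = 1L, max_attempts = 2L)
  err <- tryCatch(build_ensemble(cfg_bad, gt, params = p),
                  cvs_ensemble_failure = function(e) e)
  expect_s3_class(err, "cvs_ensemble_failure")
  expect_match(conditionMessage(err), "final losses")
})

test_that("size-1 ensembles reduce to a single accepted training run", {
  p <- default_params()
  gt <- short_gt()
  cfg <- tiny_training_config(iters1 = 40, iters2 = 5, threshold = 1e4,
                              ensemble_size = 1L, base_seed = 3L)
  ens <- build_ensemble(cfg, gt, params = p)
  single <- train_single(cfg, gt, seed = 3L, params = p)
  expect_identical(ens$members[[1]]$final_loss, single$final_loss)
  expect_identical(ens$members[[1]]$model$net$weights,
                   single$model$net$weights)
})

test_that("prediction averaging is idempotent and order-invariant", {
  p <- default_params()
  gt <- short_gt()
  sc <- scaling_from_trajectory(gt)
  m1 <- hybrid_model(p, init_network(1), sc)
  m2 <- hybrid_model(p, init_network(2), sc)
  one <- average_predictions(list(m1), 0.2)
  two_same <- average_predictions(list(m1, m1), 0.2)
  expect_equal(one$vi_outputs, two_same$vi_outputs, tolerance = 1e-14)
  ab <- average_predictions(list(m1, m2), 0.2)
  ba <- average_predictions(list(m2, m1), 0.2)
  expect_equal(ab$vi_outputs, ba$vi_outputs, tolerance = 1e-14)
  expect_equal(ab$volumes, ba$volumes, tolerance = 1e-14)
})
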