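test_that("network initialization is seeded and fan-scaled", {
  n1 <- init_network(5)
  n2 <- init_network(5)
  n3 <- init_network(6)
  expect_identical(n1, n2)
  expect_false(identical(n1$weights, n3$weights))
  expect_true(all(vapply(n1$biases, function(b) all(b == 0), TRUE)))
  expect_true(all(vapply(n1$weights, function(w) all(is.finite(w)), TRUE)))
  # Glorot bound for the first layer (fan_in 5, fan_out 10)
  expect_lt(max(abs(n1$weights[[1]])), sqrt(6 / 15) + 1e-12)
  # flatten/unflatten is a lossless round trip
  expect_equal(unflatten_network(flatten_network(n1), seed = 5L)$weights,
               n1$weights, tolerance = 0)
})

test_that("an all-zero network outputs (0, 0) through the linear head", {
  net <- init_network(1)
  for (l in 1:4) net$weights[[l]][] <- 0
  out <- nn_forward(c(90, 90, 130, 320, 60), net)
  expect_identical(unname(out), c(0, 0))
})

test_that("ELU activations are bounded below by -1", {
  expect_gte(cvsude:::elu(-1e6), -1)
  expect_equal(cvsude:::elu(-50), -1, tolerance = 1e-12)
  expect_identical(cvsude:::elu(3), 3)
  # visible through the network: drive the first hidden layer to -Inf
  net <- init_network(2)
  net$weights[[1]][] <- 0
  net$biases[[1]][] <- -1e6
  h1 <- rep(-1, 10)  # elu floor
  ref <- nn_forward(c(1, 1, 1, 1, 1), net)
  net2 <- net
  net2$biases[[1]][] <- -1e7  # even more negative: same floor
  expect_equal(unname(nn_forward(c(1, 1, 1, 1, 1), net2)), unname(ref),
               tolerance = 1e-12)
})

test_that("R and compiled forward passes agree", {
  net <- init_network(9)
  sc <- list(mu = c(90, 90, 130, 320, 60), sd = c(10, 10, 15, 5, 12))
  set.seed(55)
  X <- cbind(runif(20, 60, 120), runif(20, 60, 120), runif(20, 110, 170),
             runif(20, 300, 360), runif(20, 35, 85))
  r_out <- nn_forward(X, net, scaling = sc)
  c_out <- cvsude:::.nn_eval_cpp(flatten_network(net), sc$mu, sc$sd, X)
  expect_lt(max(abs(r_out - c_out)), 1e-12)
  expect_error(nn_forward(c(1, NA, 1, 1, 1), net), "non-finite")
})

test_that("training-loss gradients match a finite-difference oracle", {
  p <- default_params()
  gt <- short_gt()
  sc <- scaling_from_trajectory(gt)
  theta <- flatten_network(init_network(3))
  pvec <- unlist(p, use.names = FALSE)
  u0 <- cvs_initial_state()
  Y <- gt$states[2:4, , drop = FALSE]  # 3-sample window
  g <- cvsude:::.hode_loss_grad_cpp(theta, sc$mu, sc$sd, u0, Y, pvec,
                                    0, 0.01, 4L, TRUE)
  expect_true(g$ok)
  set.seed(17)
  idx <- sample(302, 15)
  h <- 1e-6
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    lp <- cvsude:::.hode_loss_grad_cpp(tp, sc$mu, sc$sd, u0, Y, pvec,
                                       0, 0.01, 4L, FALSE)$loss
    lm <- cvsude:::.hode_loss_grad_cpp(tm, sc$mu, sc$sd, u0, Y, pvec,
                                       0, 0.01, 4L, FALSE)$loss
    fd <- (lp - lm) / (2 * h)
    expect_lt(abs(fd - g$grad[i]) / max(abs(fd), 1e-6), 1e-4)
  }
})

test_that("network weight files round-trip exactly", {
  net <- init_network(12)
  sc <- list(mu = c(1, 2, 3, 4, 5), sd = c(9, 8, 7, 6, 5))
  f <- withr::local_tempfile(fileext = ".net")
  write_network(net, f, scaling = sc)
  back <- read_network(f)
  expect_identical(back$net$weights, net$weights)
  expect_identical(back$net$biases, net$biases)
  expect_identical(back$net$seed, 12L)
  expect_identical(back$scaling, sc)
})
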