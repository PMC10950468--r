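test_that("total blood volume is conserved over 10 s", {
  gt <- long_gt()
  tv <- total_volume(gt)
  expect_lt(max(abs(tv - tv[1])), 1e-4)
})

test_that("sampled valve flows are never negative", {
  gt <- long_gt()
  expect_true(all(gt$states[, 1:4] >= 0))
})

test_that("integration is deterministic and tolerance-converged", {
  p <- default_params()
  a <- cvs_integrate(p, t_end = 2)
  b <- cvs_integrate(p, t_end = 2)
  expect_identical(a$states, b$states)
  tight <- cvs_integrate(p, t_end = 2,
                         settings = solver_settings(atol = 1e-8, rtol = 1e-5))
  # the smooth volume states converge pointwise; the valve flows switch
  # discontinuously, so their error localizes at the opening instants and is
  # summarized in the pooled RMS instead
  expect_lt(max(abs(a$states[, 5:10] - tight$states[, 5:10])), 1e-3)
  expect_lt(sqrt(mean((a$states - tight$states)^2)), 5e-3)
})

test_that("the simulated dynamics are periodic with the driver period", {
  p <- default_params()
  gt <- long_gt()
  per <- round(p$period / 0.01)
  i1 <- 801:900            # beat starting at t = 8.0
  expect_lt(max(abs(gt$states[i1, ] - gt$states[i1 + per, ])), 0.25)
  # and the pressure ranges are physiological (aortic 75-125 mmHg)
  expect_gt(min(gt$derived[, "P_ao"]), 60)
  expect_lt(max(gt$derived[, "P_ao"]), 130)
})

test_that("measurement noise is calibrated per state and reproducible", {
  gt <- long_gt()
  n1 <- add_noise(gt, 0.05, seed = 7)
  n2 <- add_noise(gt, 0.05, seed = 7)
  n3 <- add_noise(gt, 0.05, seed = 8)
  expect_identical(n1$states, n2$states)
  expect_false(identical(n1$states, n3$states))
  expect_identical(add_noise(gt, 0, seed = 1)$states, gt$states)
  expect_error(add_noise(gt, -0.1), "non-negative")
  sds <- apply(gt$states, 2, sd)
  err_sd <- apply(n1$states - gt$states, 2, sd)
  expect_true(all(err_sd >= 0.9 * 0.05 * sds))
  expect_true(all(err_sd <= 1.1 * 0.05 * sds))
  expect_identical(n1$meta$noise, 0.05)
  expect_identical(n1$meta$seed, 7L)
})

test_that("trajectory CSV round trip preserves values and metadata", {
  p <- default_params()
  tr <- cvs_integrate(p, t_end = 0.5)
  tr <- add_noise(tr, 0.02, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_lt(max(abs(tr2$states - tr$states) / pmax(abs(tr$states), 1)), 1e-12)
  expect_lt(max(abs(tr2$times - tr$times)), 1e-12)
  expect_equal(tr2$meta$noise, 0.02)
  expect_equal(tr2$meta$seed, 3)
  expect_identical(tr2$meta$vi_mode, "mechanistic")
})

test_that("reading is header-driven and schema-enforcing", {
  p <- default_params()
  tr <- cvs_integrate(p, t_end = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  lines <- readLines(f)
  hdr_i <- which(!startsWith(lines, "#"))[1]
  cols <- strsplit(lines[hdr_i], ",")[[1]]
  set.seed(41)
  perm <- c(1, sample(2:length(cols)))
  shuffle <- function(ln) {
    paste(strsplit(ln, ",")[[1]][perm], collapse = ",")
  }
  lines[hdr_i:length(lines)] <- vapply(lines[hdr_i:length(lines)], shuffle, "")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, f2)
  tr2 <- read_trajectory(f2)
  expect_equal(tr2$states, tr$states, tolerance = 1e-12)
  # drop a state column entirely -> schema error naming it
  keep <- cols != "V_pa"
  lines3 <- readLines(f)
  lines3[hdr_i:length(lines3)] <- vapply(lines3[hdr_i:length(lines3)],
    function(ln) paste(strsplit(ln, ",")[[1]][keep], collapse = ","), "")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines3, f3)
  expect_error(read_trajectory(f3), "V_pa")
})
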