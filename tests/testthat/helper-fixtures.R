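# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- maker()
  .fixture_cache[[name]]
}

default_params <- function() fixture("params", cvs_params)

# 1 s mechanistic ground truth with derived quantities (about 1.3 beats)
short_gt <- function() fixture("short_gt", function() {
  cvs_integrate(default_params(), t_end = 1, derived = TRUE)
})

# 10 s mechanistic ground truth (the canonical synthetic dataset)
long_gt <- function() fixture("long_gt", function() {
  cvs_integrate(default_params(), t_end = 10, derived = TRUE)
})

# a quick, reduced-schedule training configuration for unit tests
tiny_training_config <- function(noise = 0, iters1 = 40, iters2 = 10, ...) {
  training_config(noise = noise,
                  schedule = list(c(lr = 0.01, iters = iters1),
                                  c(lr = 1e-4, iters = iters2)), ...)
}

# volumes matrix with SR column names from a trajectory
volume_matrix <- function(traj) {
  X <- traj$states[, 5:9, drop = FALSE]
  colnames(X) <- c("V_lv", "V_rv", "V_ao", "V_vc", "V_pa")
  X
}
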