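# Metrics and the comparison experiments: extrapolation of the hybrid,
# partially learned and no-VI models against the ground truth, and MSEs of
# the ventricular-interaction surrogates against their mechanistic
# references.

#' Pooled root-mean-squared error between two trajectories
#'
#' Square root of the mean of squared differences pooled over all 10 state
#' variables and all samples (unnormalized: states keep their own units, so
#' the volume states dominate). Requires identical grids.
#'
#' @param a,b `cvs_trajectory` objects on the same grid.
#' @return scalar RMSE.
#' @export
pooled_rmse <- function(a, b) {
  stopifnot(inherits(a, "cvs_trajectory"), inherits(b, "cvs_trajectory"))
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9) {
    stop("time grids do not match", call. = FALSE)
  }
  sqrt(mean((a$states - b$states)^2))
}

#' MSE of ventricular-interaction surrogates against mechanistic references
#'
#' Separate mean squared errors of a `(V_spt, P_peri)` series pair -- network
#' outputs or distilled expressions evaluated along a trajectory -- against
#' the mechanistic references (the Newton-Raphson septum volume and the
#' pericardial pressure law) over an evaluation window.
#'
#' @param outputs two-column matrix (`V_spt`, `P_peri`) aligned with `times`.
#' @param reference two-column matrix of the mechanistic values on the same
#'   grid.
#' @param times sample times (s).
#' @param window evaluation window (s) over `[0, window]`; `NULL` uses the
#'   full series.
#' @return named numeric vector `c(V_spt = ..., P_peri = ...)`.
#' @export
vi_term_mse <- function(outputs, reference, times, window = NULL) {
  outputs <- as.matrix(outputs); reference <- as.matrix(reference)
  if (nrow(outputs) != nrow(reference) || nrow(outputs) != length(times)) {
    stop("series are not aligned", call. = FALSE)
  }
  keep <- if (is.null(window)) rep(TRUE, length(times)) else
    times <= window + 1e-9
  d <- outputs[keep, , drop = FALSE] - reference[keep, , drop = FALSE]
  c(V_spt = mean(d[, 1]^2), P_peri = mean(d[, 2]^2))
}

#' Extrapolation experiment against ground truth
#'
#' Integrates each candidate model (a named list of `vi_provider`s, e.g. a
#' trained hybrid, a partially learned model, and the no-VI variant) from the
#' shared initial condition over the horizon and reports per-state and pooled
#' RMSE against the ground-truth trajectory, with the training window
#' flagged. A model that fails to integrate is reported with `NA` metrics;
#' the others are still evaluated.
#'
#' @param models named list of `vi_provider` objects.
#' @param ground_truth a `cvs_trajectory` covering the horizon (noiseless).
#' @param train_window training-window length (s), recorded and flagged.
#' @param horizon comparison horizon (s); defaults to the ground-truth span.
#' @param params mechanistic constants.
#' @param init shared initial state.
#' @param settings [solver_settings()].
#' @return object of class `evaluation_report`: per-model list of per-state
#'   RMSE, pooled RMSE and any integration error, plus the horizon and
#'   window.
#' @export
run_extrapolation_experiment <- function(models, ground_truth,
                                         train_window = 0.3, horizon = NULL,
                                         params = cvs_params(),
                                         init = cvs_initial_state(),
                                         settings = solver_settings()) {
  stopifnot(is.list(models), !is.null(names(models)),
            inherits(ground_truth, "cvs_trajectory"))
  if (is.null(horizon)) horizon <- ground_truth$times[length(ground_truth$times)]
  n <- round(horizon / settings$dt) + 1L
  if (length(ground_truth$times) < n) {
    stop("ground truth does not cover the horizon", call. = FALSE)
  }
  gts <- ground_truth$states[seq_len(n), , drop = FALSE]
  results <- lapply(names(models), function(nm) {
    tr <- tryCatch(cvs_integrate(params, init, horizon, models[[nm]], settings),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      return(list(model = nm, error = conditionMessage(tr),
                  per_state_rmse = stats::setNames(rep(NA_real_, 10),
                                                   cvs_state_names()),
                  pooled_rmse = NA_real_))
    }
    d <- tr$states - gts
    list(model = nm, error = NULL,
         per_state_rmse = stats::setNames(sqrt(colMeans(d^2)),
                                          cvs_state_names()),
         pooled_rmse = sqrt(mean(d^2)))
  })
  names(results) <- names(models)
  structure(list(results = results, horizon = horizon,
                 train_window = train_window,
                 times = ground_truth$times[seq_len(n)]),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> horizon %g s (training window %g s)\n",
              x$horizon, x$train_window))
  for (r in x$results) {
    if (!is.null(r$error)) {
      cat(sprintf("  %-20s integration failed: %s\n", r$model, r$error))
    } else {
      cat(sprintf("  %-20s pooled RMSE %.4f\n", r$model, r$pooled_rmse))
    }
  }
  invisible(x)
}

#' Per-state metrics of a report as a data frame
#'
#' @param report an `evaluation_report`.
#' @return data frame with one row per (model, state) pair.
#' @export
report_metrics <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  do.call(rbind, lapply(report$results, function(r) {
    data.frame(model = r$model, state = names(r$per_state_rmse),
               rmse = unname(r$per_state_rmse),
               pooled_rmse = r$pooled_rmse, row.names = NULL)
  }))
}
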