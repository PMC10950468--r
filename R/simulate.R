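# Numerical integration, uniform sampling, measurement noise and CSV
# persistence of trajectories: the synthetic-data generator of the pipeline.

#' Solver settings
#'
#' Settings of the adaptive explicit Runge-Kutta 5(4) (Dormand-Prince)
#' integration used for all ground-truth and callback-mode simulations. The
#' defaults cap the step at 1e-2 s (the valve diodes make the dynamics
#' non-smooth) with absolute tolerance 1e-7 and relative tolerance 1e-4, and
#' sample the dense solution at 100 Hz.
#'
#' @param method deSolve integrator tag; the order-5(4) pair `"ode45"`.
#' @param hmax maximum internal step (s).
#' @param atol,rtol absolute / relative tolerances.
#' @param dt uniform output step (s).
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(method = "ode45", hmax = 1e-2, atol = 1e-7,
                            rtol = 1e-4, dt = 0.01) {
  stopifnot(hmax > 0, atol > 0, rtol > 0, dt > 0)
  structure(list(method = method, hmax = hmax, atol = atol, rtol = rtol,
                 dt = dt), class = "solver_settings")
}

new_trajectory <- function(times, states, derived = NULL, meta = list()) {
  states <- as.matrix(states)
  colnames(states) <- cvs_state_names()
  stopifnot(length(times) == nrow(states))
  if (length(times) > 1) {
    dts <- diff(times)
    if (any(dts <= 0) || max(abs(dts - dts[1])) > 1e-12) {
      stop("trajectory time grid must be uniform and strictly increasing",
           call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times), states = states,
                 derived = derived, meta = meta),
            class = "cvs_trajectory")
}

#' @export
print.cvs_trajectory <- function(x, ...) {
  cat(sprintf("<cvs_trajectory> %d samples, t in [%g, %g] s, dt = %g s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              if (length(x$times) > 1) x$times[2] - x$times[1] else NA))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Integrate the cardiovascular model
#'
#' Solves the closed-loop system from an initial state over `[0, t_end]`
#' with the adaptive Dormand-Prince 5(4) integrator, sampling the dense
#' solution on the uniform output grid. Any transient negative valve flow
#' (the diode law switches within a step) is clamped to zero in the sampled
#' output. Deterministic given its inputs.
#'
#' @param params a [cvs_params()] set.
#' @param init initial state ([cvs_state()]); default [cvs_initial_state()].
#' @param t_end end time (s).
#' @param vi a `vi_provider` selecting the ventricular-interaction mode.
#' @param settings a [solver_settings()] list.
#' @param derived if `TRUE`, also evaluate the derived quantities (pressures,
#'   `V_spt`, `P_peri`, circulation flows) at every sample.
#' @return a `cvs_trajectory`: uniform `times`, a samples-by-10 `states`
#'   matrix in canonical order, optionally a `derived` matrix, and metadata
#'   (parameter checksum, VI mode, noise fraction, seed).
#' @export
cvs_integrate <- function(params, init = cvs_initial_state(), t_end,
                          vi = vi_mechanistic(),
                          settings = solver_settings(), derived = FALSE) {
  params <- validate_cvs_params(params)
  init <- validate_cvs_state(init)
  stopifnot(t_end > 0)
  times <- seq(0, t_end, by = settings$dt)
  cache <- new.env(parent = emptyenv())
  func <- function(t, y, parms) {
    list(cvs_rhs(y, t, params, vi, cache))
  }
  sol <- tryCatch(
    deSolve::ode(y = init, times = times, func = func, parms = NULL,
                 method = settings$method, hmax = settings$hmax,
                 atol = settings$atol, rtol = settings$rtol),
    error = function(e) stop("integration failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(sol) < length(times) || !all(is.finite(sol))) {
    t_fail <- if (nrow(sol) >= 1) sol[nrow(sol), 1] else 0
    stop(sprintf("integration failed near t = %.4f s", t_fail), call. = FALSE)
  }
  states <- unname(sol[, -1, drop = FALSE])
  states[, 1:4][states[, 1:4] < 0] <- 0
  der <- NULL
  if (derived) {
    cache2 <- new.env(parent = emptyenv())
    der <- t(vapply(seq_along(times), function(i) {
      derived_quantities(states[i, ], times[i], params, vi, cache2)
    }, numeric(length(.derived_names))))
    colnames(der) <- .derived_names
  }
  new_trajectory(times, states, der,
                 meta = list(params_checksum = params_checksum(params),
                             vi_mode = vi$mode, noise = 0, seed = NA_integer_))
}

#' Add measurement noise to a trajectory
#'
#' Adds i.i.d. zero-mean Gaussian noise to every state series. The noise
#' standard deviation is `fraction` times that state's own sample standard
#' deviation over the full series (each state has its own units, so the
#' scaling is per state, not pooled). The noise is drawn once, so the result
#' is a fixed noisy dataset, reproducible from `seed`.
#'
#' @param traj a `cvs_trajectory`.
#' @param fraction non-negative noise fraction (e.g. 0.05 for 5%).
#' @param seed integer RNG seed recorded in the metadata.
#' @return a new `cvs_trajectory` with noisy states; `derived` is dropped.
#' @export
add_noise <- function(traj, fraction, seed = 1L) {
  stopifnot(inherits(traj, "cvs_trajectory"))
  if (!is.finite(fraction) || fraction < 0) {
    stop("noise fraction must be non-negative", call. = FALSE)
  }
  if (fraction == 0) {
    out <- traj
    out$meta$noise <- 0
    out$meta$seed <- as.integer(seed)
    return(out)
  }
  sds <- apply(traj$states, 2, stats::sd)
  states <- traj$states
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(states))) {
    states[, j] <- states[, j] +
      stats::rnorm(nrow(states), 0, fraction * sds[j])
  }
  meta <- traj$meta
  meta$noise <- fraction
  meta$seed <- as.integer(seed)
  new_trajectory(traj$times, states, NULL, meta)
}

#' Write / read a trajectory as CSV
#'
#' Plain CSV with header `t,Q_mt,...,V_pu` (plus any derived columns),
#' preceded by `#key=value` metadata lines. Values are written with 15
#' significant digits so a round trip preserves them to better than 1e-12
#' relative. Reading is header-driven (columns may appear in any order) and
#' enforces the schema: the time column and all 10 state columns must be
#' present.
#'
#' @param traj a `cvs_trajectory`.
#' @param path file path.
#' @return `read_trajectory()` returns a `cvs_trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cvs_trajectory"))
  meta <- traj$meta
  hdr <- vapply(names(meta), function(k) {
    sprintf("#%s=%s", k, format(meta[[k]], digits = 17))
  }, "")
  m <- cbind(t = traj$times, traj$states)
  if (!is.null(traj$derived)) m <- cbind(m, traj$derived)
  cols <- colnames(m)
  body <- apply(m, 1, function(r) paste(sprintf("%.15g", r), collapse = ","))
  writeLines(c(hdr, paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  n_meta <- match(FALSE, is_meta) - 1L
  if (is.na(n_meta)) stop("parse error: no header row found", call. = FALSE)
  meta <- list()
  if (n_meta > 0) {
    for (ln in lines[seq_len(n_meta)]) {
      kv <- regmatches(ln, regexec("^#([^=]+)=(.*)$", ln))[[1]]
      if (length(kv) == 3) {
        val <- suppressWarnings(as.numeric(kv[3]))
        meta[[kv[2]]] <- if (is.na(val)) kv[3] else val
      }
    }
  }
  header <- strsplit(lines[n_meta + 1L], ",", fixed = TRUE)[[1]]
  need <- c("t", cvs_state_names())
  miss <- setdiff(need, header)
  if (length(miss)) {
    stop(sprintf("parse error at line %d: missing column(s) %s",
                 n_meta + 1L, paste(miss, collapse = ", ")), call. = FALSE)
  }
  body <- lines[-seq_len(n_meta + 1L)]
  body <- body[nzchar(body)]
  rows <- strsplit(body, ",", fixed = TRUE)
  nc <- length(header)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != nc) {
      stop(sprintf("parse error at line %d: expected %d columns, found %d",
                   n_meta + 1L + i, nc, length(rows[[i]])), call. = FALSE)
    }
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = nc, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("parse error at line %d, column %d ('%s'): not a number",
                 n_meta + 1L + bad[1], bad[2], header[bad[2]]), call. = FALSE)
  }
  colnames(m) <- header
  states <- m[, cvs_state_names(), drop = FALSE]
  dnames <- intersect(.derived_names, header)
  der <- if (length(dnames)) m[, dnames, drop = FALSE] else NULL
  new_trajectory(m[, "t"], states, der, meta)
}

#' Pooled total blood volume of each sample
#'
#' Sum of the six chamber volumes at every sample; constant in a closed loop.
#' @param traj a `cvs_trajectory`.
#' @return numeric vector of total volumes (mL).
#' @export
total_volume <- function(traj) {
  rowSums(traj$states[, 5:10, drop = FALSE])
}
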