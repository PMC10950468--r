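# Ventricular interaction: septum free-wall volume (implicit, Newton-Raphson)
# and pericardium pressure.

# Free-wall pressure law shared by the actively contracting chambers:
# a driver-weighted blend of the linear ESPVR and the exponential EDPVR.
#   P(V, e) = e * E * (V - Vd) + (1 - e) * P0 * (exp(lambda * (V - V0)) - 1)
wall_pressure <- function(V, e, E, P0, lambda, V0, Vd) {
  e * E * (V - Vd) + (1 - e) * P0 * (exp(lambda * (V - V0)) - 1)
}

wall_pressure_dV <- function(V, e, E, P0, lambda, V0) {
  e * E + (1 - e) * P0 * lambda * exp(lambda * (V - V0))
}

#' Trans-septal pressure residual
#'
#' The septum free-wall volume `V_spt` is defined implicitly: the septum wall
#' pressure must balance the difference between the left and right
#' ventricular free-wall pressures,
#' \deqn{P_{spt}(V_{spt}) = P_{lvf}(V_{lv} - V_{spt}) - P_{rvf}(V_{rv} + V_{spt}).}
#' This function returns the residual of that balance,
#' `P_spt(V_spt) - P_lvf(V_lv - V_spt) + P_rvf(V_rv + V_spt)`, a strictly
#' increasing, smooth function of `V_spt` whose unique root is the septum
#' volume. Each wall pressure blends its linear end-systolic and exponential
#' end-diastolic law through the cardiac driver value `e`.
#'
#' @param V_spt candidate septum free-wall volume (mL); vectorized.
#' @param V_lv,V_rv ventricular volumes (mL), positive scalars.
#' @param e cardiac-driver activation in `(0, A_drv]`.
#' @param params a [cvs_params()] set.
#' @return residual pressure (mmHg), same length as `V_spt`.
#' @export
septum_residual <- function(V_spt, V_lv, V_rv, e, params) {
  params <- validate_cvs_params(params)
  stopifnot(is.finite(V_lv), is.finite(V_rv), V_lv > 0, V_rv > 0,
            is.finite(e), e > 0, e <= params$A_drv)
  wall_pressure(V_spt, e, params$E_spt, params$P0_spt, params$lambda_spt,
                params$V0_spt, params$Vd_spt) -
    wall_pressure(V_lv - V_spt, e, params$E_lvf, params$P0_lvf,
                  params$lambda_lvf, params$V0_lvf, params$Vd_lvf) +
    wall_pressure(V_rv + V_spt, e, params$E_rvf, params$P0_rvf,
                  params$lambda_rvf, params$V0_rvf, params$Vd_rvf)
}

# d(residual)/dV_spt; strictly positive for valid parameters.
septum_residual_dV <- function(V_spt, V_lv, V_rv, e, params) {
  wall_pressure_dV(V_spt, e, params$E_spt, params$P0_spt, params$lambda_spt,
                   params$V0_spt) +
    wall_pressure_dV(V_lv - V_spt, e, params$E_lvf, params$P0_lvf,
                     params$lambda_lvf, params$V0_lvf) +
    wall_pressure_dV(V_rv + V_spt, e, params$E_rvf, params$P0_rvf,
                     params$lambda_rvf, params$V0_rvf)
}

#' Septum root-solver options
#'
#' @param guess initial Newton iterate (mL). Within an integration the solver
#'   warm-starts from the previously accepted root; 0 on the first call.
#' @param tol absolute residual tolerance (mmHg).
#' @param maxit maximum Newton iterations before the bisection fallback.
#' @return list of options for [septum_volume()].
#' @export
septum_options <- function(guess = 0, tol = 1e-9, maxit = 50L) {
  stopifnot(is.finite(guess), tol > 0, maxit >= 1)
  list(guess = guess, tol = tol, maxit = as.integer(maxit))
}

#' Septum free-wall volume by Newton-Raphson
#'
#' Solves the trans-septal pressure balance (see [septum_residual()]) for the
#' septum free-wall volume. Newton-Raphson with an analytic derivative; if it
#' fails to converge (or leaves the physiological bracket), a guarded
#' bisection over `(-V_rv, V_lv)` (the interval on which both free-wall
#' volumes stay positive) is used as a fallback. The residual is strictly
#' increasing in `V_spt`, so the root is unique.
#'
#' @inheritParams septum_residual
#' @param opts solver options from [septum_options()].
#' @return the septum volume (mL) with `|residual| < opts$tol`.
#' @export
septum_volume <- function(V_lv, V_rv, e, params, opts = septum_options()) {
  params <- validate_cvs_params(params)
  # inlined residual/derivative (hot path: called once per RHS evaluation)
  ce <- 1 - e
  f <- function(v) {
    e * params$E_spt * (v - params$Vd_spt) +
      ce * params$P0_spt * (exp(params$lambda_spt * (v - params$V0_spt)) - 1) -
      e * params$E_lvf * (V_lv - v - params$Vd_lvf) -
      ce * params$P0_lvf * (exp(params$lambda_lvf * (V_lv - v - params$V0_lvf)) - 1) +
      e * params$E_rvf * (V_rv + v - params$Vd_rvf) +
      ce * params$P0_rvf * (exp(params$lambda_rvf * (V_rv + v - params$V0_rvf)) - 1)
  }
  fp <- function(v) {
    e * (params$E_spt + params$E_lvf + params$E_rvf) +
      ce * (params$P0_spt * params$lambda_spt * exp(params$lambda_spt * (v - params$V0_spt)) +
            params$P0_lvf * params$lambda_lvf * exp(params$lambda_lvf * (V_lv - v - params$V0_lvf)) +
            params$P0_rvf * params$lambda_rvf * exp(params$lambda_rvf * (V_rv + v - params$V0_rvf)))
  }
  lo <- -V_rv + 1e-9 * V_rv
  hi <- V_lv - 1e-9 * V_lv
  v <- min(max(opts$guess, lo), hi)
  last <- v
  for (i in seq_len(opts$maxit)) {
    fv <- f(v)
    if (is.finite(fv) && abs(fv) < opts$tol) return(v)
    step <- fv / fp(v)
    vn <- v - step
    if (!is.finite(vn) || vn <= lo || vn >= hi) break
    last <- v
    v <- vn
  }
  # bisection fallback over the physiological bracket
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop(structure(class = c("cvs_root_error", "error", "condition"),
                   list(message = sprintf(
                     "septum root solve failed: no sign change on bracket; last iterate %.6g, residual %.6g",
                     v, f(v)), call = NULL)))
  }
  a <- lo; b <- hi
  for (i in seq_len(200L)) {
    m <- 0.5 * (a + b)
    fm <- f(m)
    if (is.finite(fm) && abs(fm) < opts$tol) return(m)
    if (!is.finite(fm)) break
    if (flo * fm <= 0) b <- m else { a <- m; flo <- fm }
    if (b - a < 1e-14 * max(1, abs(m))) {
      if (abs(fm) < opts$tol) return(m) else break
    }
  }
  stop(structure(class = c("cvs_root_error", "error", "condition"),
                 list(message = sprintf(
                   "septum root solve failed: last iterate %.6g, residual %.6g",
                   last, f(last)), call = NULL)))
}

#' Pericardium pressure
#'
#' The pericardial sac encloses both ventricles; its pressure is a nonlinear
#' (exponential EDPVR) function of the total ventricular volume
#' `V_pcd = V_lv + V_rv`, offset by the intrathoracic pressure:
#' \deqn{P_{peri} = P_{0,pcd}\,(e^{\lambda_{pcd}(V_{pcd} - V_{0,pcd})} - 1) + P_{th}.}
#' At `V_pcd = V_0,pcd` the exponential term vanishes and
#' `P_peri = P_th` (-4 mmHg at defaults). Strictly increasing in
#' `V_lv + V_rv`.
#'
#' @inheritParams septum_residual
#' @return pericardium pressure (mmHg); vectorized over `V_lv`/`V_rv`.
#' @export
pericardium_pressure <- function(V_lv, V_rv, params) {
  params <- validate_cvs_params(params)
  if (any(V_lv <= 0) || any(V_rv <= 0)) {
    stop("ventricular volumes must be positive", call. = FALSE)
  }
  V_pcd <- V_lv + V_rv
  params$P0_pcd * (exp(params$lambda_pcd * (V_pcd - params$V0_pcd)) - 1) +
    params$P_th
}

#' Ventricular-interaction providers
#'
#' The model's right-hand side resolves the two ventricular-interaction (VI)
#' quantities -- the septum free-wall volume `V_spt` and the pericardium
#' pressure `P_peri` -- through a provider object with one of three modes:
#'
#' * `vi_mechanistic()`: `V_spt` from the embedded Newton-Raphson solve
#'   ([septum_volume()]) and `P_peri` from [pericardium_pressure()].
#' * `vi_none()`: the interaction terms are omitted literally
#'   (`V_spt = 0`, `P_peri = 0`), the common simplification in models that
#'   ignore VI.
#' * `vi_callback(fn)`: `fn(V_lv, V_rv, V_ao, V_vc, V_pa)` must return
#'   `c(V_spt, P_peri)`; used to embed a neural network or a distilled
#'   closed-form expression. The callback must be pure and defined for all
#'   positive volumes.
#'
#' @param fn callback function of the five volumes, returning a numeric
#'   2-vector `(V_spt, P_peri)`.
#' @return an object of class `vi_provider`.
#' @export
vi_mechanistic <- function() {
  structure(list(mode = "mechanistic", fn = NULL), class = "vi_provider")
}

#' @rdname vi_mechanistic
#' @export
vi_none <- function() {
  structure(list(mode = "none", fn = NULL), class = "vi_provider")
}

#' @rdname vi_mechanistic
#' @export
vi_callback <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(mode = "callback", fn = fn), class = "vi_provider")
}

# Resolve (V_spt, P_peri) for a provider. `cache` (an environment) carries the
# warm-start Newton iterate across calls within one integration.
resolve_vi <- function(vi, V_lv, V_rv, V_ao, V_vc, V_pa, e, params,
                       cache = NULL) {
  switch(vi$mode,
    mechanistic = {
      guess <- if (!is.null(cache) && !is.null(cache$v_spt)) cache$v_spt else 0
      v <- septum_volume(V_lv, V_rv, e, params, septum_options(guess = guess))
      if (!is.null(cache)) cache$v_spt <- v
      c(v, pericardium_pressure(V_lv, V_rv, params))
    },
    none = c(0, 0),
    callback = {
      out <- vi$fn(V_lv, V_rv, V_ao, V_vc, V_pa)
      if (length(out) != 2L || !all(is.finite(out))) {
        stop("VI callback must return two finite values (V_spt, P_peri)",
             call. = FALSE)
      }
      as.numeric(out)
    },
    stop("unknown VI mode: ", vi$mode, call. = FALSE)
  )
}
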