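# The closed-loop ODE right-hand side and its derived (non-state) quantities.

#' State variable names
#'
#' The 10 state variables, in canonical order: the four valve flows (mitral,
#' aortic, tricuspid, pulmonary; mL/s) followed by the six chamber volumes
#' (left/right ventricle, aorta, vena cava, pulmonary artery, pulmonary vein;
#' mL).
#' @export
cvs_state_names <- function() {
  c("Q_mt", "Q_av", "Q_tc", "Q_pv",
    "V_lv", "V_rv", "V_ao", "V_vc", "V_pa", "V_pu")
}

.derived_names <- c("e", "P_lv", "P_rv", "P_ao", "P_vc", "P_pa", "P_pu",
                    "P_peri", "V_spt", "V_pcd", "Q_sys", "Q_pul")

#' Construct a state vector
#'
#' @param Q_mt,Q_av,Q_tc,Q_pv valve flows (mL/s), non-negative.
#' @param V_lv,V_rv,V_ao,V_vc,V_pa,V_pu chamber volumes (mL), positive.
#' @return named numeric 10-vector in canonical order.
#' @export
cvs_state <- function(Q_mt, Q_av, Q_tc, Q_pv,
                      V_lv, V_rv, V_ao, V_vc, V_pa, V_pu) {
  u <- c(Q_mt = Q_mt, Q_av = Q_av, Q_tc = Q_tc, Q_pv = Q_pv,
         V_lv = V_lv, V_rv = V_rv, V_ao = V_ao, V_vc = V_vc,
         V_pa = V_pa, V_pu = V_pu)
  validate_cvs_state(u)
}

validate_cvs_state <- function(u) {
  u <- as.numeric(u)[1:10]
  names(u) <- cvs_state_names()
  if (!all(is.finite(u))) stop("non-finite state", call. = FALSE)
  if (any(u[5:10] <= 0)) stop("chamber volumes must be positive", call. = FALSE)
  if (any(u[1:4] < 0)) stop("valve flows must be non-negative", call. = FALSE)
  u
}

#' Default initial state
#'
#' The canonical initial condition of the simulator: a periodic-steady-state
#' snapshot of the mechanistic model at beat onset (driver phase 0), obtained
#' once by a 30 s burn-in from a physiological cold start with a total
#' stressed blood volume of about 1.5 L. Starting from this state the
#' simulated dynamics are periodic from `t = 0`.
#'
#' @return named numeric 10-vector.
#' @export
cvs_initial_state <- function() {
  validate_cvs_state(c(
    Q_mt = 90.5864325, Q_av = 0, Q_tc = 125.6057466, Q_pv = 0,
    V_lv = 111.6600986, V_rv = 107.4457054, V_ao = 125.5735603,
    V_vc = 321.4888529, V_pa = 36.9506478, V_pu = 796.0011350))
}

#' Derived (non-state) quantities of the model
#'
#' Computes every intermediate quantity of the model at one state and time:
#' the driver activation `e`, all six chamber pressures, the pericardium
#' pressure, the septum free-wall volume, the total pericardial volume
#' `V_pcd = V_lv + V_rv`, and the systemic and pulmonary circulation flows.
#' The ventricular-interaction terms are resolved through the supplied
#' provider (see [vi_mechanistic()]); in mode `none` their contribution is
#' omitted (`V_spt = 0`, `P_peri = 0`).
#'
#' @param state named 10-vector (see [cvs_state()]).
#' @param t time (s).
#' @param params a [cvs_params()] set.
#' @param vi a `vi_provider`.
#' @param cache optional environment carrying the Newton warm start.
#' @return named numeric vector of derived quantities.
#' @export
derived_quantities <- function(state, t, params, vi = vi_mechanistic(),
                               cache = NULL) {
  params <- validate_cvs_params(params)
  u <- as.numeric(state)
  e <- cardiac_driver(t, params)
  V_lv <- u[5]; V_rv <- u[6]; V_ao <- u[7]; V_vc <- u[8]
  V_pa <- u[9]; V_pu <- u[10]
  sp <- resolve_vi(vi, V_lv, V_rv, V_ao, V_vc, V_pa, e, params, cache)
  V_spt <- sp[1]; P_peri <- sp[2]
  P_lvf <- wall_pressure(V_lv - V_spt, e, params$E_lvf, params$P0_lvf,
                         params$lambda_lvf, params$V0_lvf, params$Vd_lvf)
  P_rvf <- wall_pressure(V_rv + V_spt, e, params$E_rvf, params$P0_rvf,
                         params$lambda_rvf, params$V0_rvf, params$Vd_rvf)
  P_lv <- P_lvf + P_peri
  P_rv <- P_rvf + P_peri
  P_ao <- params$E_ao * (V_ao - params$Vd_ao)
  P_vc <- params$E_vc * (V_vc - params$Vd_vc)
  P_pa <- params$E_pa * (V_pa - params$Vd_pa) + params$P_th
  P_pu <- params$E_pu * (V_pu - params$Vd_pu) + params$P_th
  c(e = e, P_lv = P_lv, P_rv = P_rv, P_ao = P_ao, P_vc = P_vc, P_pa = P_pa,
    P_pu = P_pu, P_peri = P_peri, V_spt = V_spt, V_pcd = V_lv + V_rv,
    Q_sys = (P_ao - P_vc) / params$R_sys,
    Q_pul = (P_pa - P_pu) / params$R_pul)
}

# Diode valve law: a valve conducts when its flow is positive or its
# upstream-minus-downstream pressure gradient is favourable; otherwise the
# flow is pinned at zero.
valve_dQ <- function(Q, dP, R, L) {
  if (Q > 0 || dP > 0) (dP - R * Q) / L else 0
}

#' ODE right-hand side
#'
#' The time derivative of the 10-dimensional state: inertial valve-flow
#' dynamics through a diode valve law (a closed valve's flow stays pinned at
#' zero under an adverse gradient) and conservation-of-volume bookkeeping for
#' the six chambers. A pure function of its arguments; the six volume
#' derivatives sum to zero exactly (closed loop).
#'
#' @inheritParams derived_quantities
#' @return named numeric 10-vector of derivatives (per second).
#' @export
cvs_rhs <- function(state, t, params, vi = vi_mechanistic(), cache = NULL) {
  u <- as.numeric(state)
  d <- derived_quantities(u, t, params, vi, cache)
  Q_mt <- u[1]; Q_av <- u[2]; Q_tc <- u[3]; Q_pv <- u[4]
  # clamp transient negative flows out of the volume bookkeeping
  q_mt <- max(Q_mt, 0); q_av <- max(Q_av, 0)
  q_tc <- max(Q_tc, 0); q_pv <- max(Q_pv, 0)
  du <- c(
    valve_dQ(Q_mt, d[["P_pu"]] - d[["P_lv"]], params$R_mt, params$L_mt),
    valve_dQ(Q_av, d[["P_lv"]] - d[["P_ao"]], params$R_av, params$L_av),
    valve_dQ(Q_tc, d[["P_vc"]] - d[["P_rv"]], params$R_tc, params$L_tc),
    valve_dQ(Q_pv, d[["P_rv"]] - d[["P_pa"]], params$R_pv, params$L_pv),
    q_mt - q_av,                    # V_lv
    q_tc - q_pv,                    # V_rv
    q_av - d[["Q_sys"]],            # V_ao
    d[["Q_sys"]] - q_tc,            # V_vc
    q_pv - d[["Q_pul"]],            # V_pa
    d[["Q_pul"]] - q_mt             # V_pu
  )
  names(du) <- cvs_state_names()
  du
}
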