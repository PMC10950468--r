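#' Cardiac driver function
#'
#' Periodic activation of the actively contracting chambers: a Gaussian pulse
#' per heart beat,
#' \deqn{e(t) = A \exp\{-B\,(\mathrm{mod}(t, T) - C)^2\},}
#' with amplitude `A_drv`, width constant `B_drv` (1/s^2), peak offset `C_drv`
#' (s) and heart period `period` (s). `e(t)` blends the linear end-systolic
#' and exponential end-diastolic chamber laws: `e = A` at peak systole,
#' `e -> 0` in diastole.
#'
#' @param t time (s), vectorized; must be finite.
#' @param params a [cvs_params()] set.
#' @return activation values in `(0, A_drv]`, same length as `t`.
#' @export
#' @examples
#' p <- cvs_params()
#' cardiac_driver(p$C_drv, p) # == A_drv at the peak offset
cardiac_driver <- function(t, params) {
  params <- validate_cvs_params(params)
  if (!all(is.finite(t))) stop("t must be finite", call. = FALSE)
  tau <- t %% params$period
  params$A_drv * exp(-params$B_drv * (tau - params$C_drv)^2)
}
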