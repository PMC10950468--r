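#' @useDynLib cvsude, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical parameter names, grouped as in the shipped parameter file.
.cvs_param_groups <- list(
  valve_resistance   = c("R_mt", "R_av", "R_tc", "R_pv"),
  circulation        = c("R_sys", "R_pul"),
  valve_inertance    = c("L_mt", "L_av", "L_tc", "L_pv"),
  elastance          = c("E_lvf", "E_rvf", "E_spt", "E_ao", "E_vc", "E_pa", "E_pu"),
  edpvr_P0           = c("P0_lvf", "P0_rvf", "P0_spt", "P0_pcd"),
  edpvr_lambda       = c("lambda_lvf", "lambda_rvf", "lambda_spt", "lambda_pcd"),
  edpvr_V0           = c("V0_lvf", "V0_rvf", "V0_spt", "V0_pcd"),
  dead_space         = c("Vd_lvf", "Vd_rvf", "Vd_spt", "Vd_ao", "Vd_vc", "Vd_pa", "Vd_pu"),
  thorax             = c("P_th"),
  driver             = c("A_drv", "B_drv", "C_drv", "period")
)

.cvs_param_names <- unname(unlist(.cvs_param_groups))

#' Constants of the closed-loop cardiovascular model
#'
#' Returns the full constant-parameter set of the six-chamber closed-loop
#' pressure--volume model: valve resistances and inertances, systemic and
#' pulmonary circulation resistances, end-systolic elastances, the
#' end-diastolic pressure--volume relationship (EDPVR) constants of the
#' ventricular free walls, septum and pericardium, chamber dead-space
#' volumes, the intrathoracic pressure and the Gaussian cardiac-driver
#' constants. Units are mmHg, mL and s throughout; pressures are relative to
#' atmosphere.
#'
#' The defaults are read from the parameter file shipped with the package
#' (see [read_cvs_params()]), which transcribes the "normal human" constants
#' of the minimal haemodynamic model of Smith et al. (2004).
#'
#' @param ... named overrides of individual constants, e.g. `P_th = -4`.
#' @param file path to a parameter file; defaults to the shipped file.
#' @return A named list of class `cvs_params`.
#' @export
#' @examples
#' p <- cvs_params()
#' p$P_th
cvs_params <- function(..., file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "cvs_params_default.txt", package = "cvsude")
  }
  p <- read_cvs_params(file)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), .cvs_param_names)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(ov)] <- vapply(ov, as.numeric, numeric(1))
  }
  validate_cvs_params(p)
}

#' Validate a cardiovascular parameter set
#'
#' Checks completeness (every constant present, no unknown names), finiteness,
#' strict positivity of resistances, inertances, elastances, EDPVR gradients
#' and the heart period.
#'
#' @param p named list or vector of parameters.
#' @return the validated parameter list, classed `cvs_params`, invisibly usable.
#' @export
validate_cvs_params <- function(p) {
  if (inherits(p, "cvs_params")) return(p)  # already validated
  p <- as.list(p)
  missing <- setdiff(.cvs_param_names, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(p), .cvs_param_names)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- p[.cvs_param_names]
  vals <- vapply(p, as.numeric, numeric(1))
  if (!all(is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(names(p)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  pos <- c(.cvs_param_groups$valve_resistance, .cvs_param_groups$circulation,
           .cvs_param_groups$valve_inertance, .cvs_param_groups$elastance,
           .cvs_param_groups$edpvr_P0, .cvs_param_groups$edpvr_lambda,
           "A_drv", "B_drv", "period")
  notpos <- pos[vals[pos] <= 0]
  if (length(notpos)) {
    stop("parameter(s) must be strictly positive: ",
         paste(notpos, collapse = ", "), call. = FALSE)
  }
  p <- as.list(vals)
  class(p) <- c("cvs_params", "list")
  p
}

#' Read a parameter file
#'
#' Parses a structured-text parameter file: one `name = value` pair per line,
#' `#` comments and blank lines ignored. The schema is strict: the file must
#' define exactly the canonical constant set (see [cvs_params()]).
#'
#' @param file path.
#' @return a validated `cvs_params` list.
#' @export
read_cvs_params <- function(file) {
  if (!file.exists(file)) stop("parameter file not found: ", file, call. = FALSE)
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(\\S+)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) {
    stop("malformed parameter line: '", lines[bad[1]], "'", call. = FALSE)
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 3L)))
  if (anyNA(vals)) {
    stop("non-numeric value for parameter(s): ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicated parameter(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  validate_cvs_params(stats::setNames(as.list(vals), keys))
}

#' Write a parameter file
#'
#' Writes the canonical `name = value` parameter file, grouped by model
#' component, readable by [read_cvs_params()].
#'
#' @param p a `cvs_params` list.
#' @param file output path.
#' @export
write_cvs_params <- function(p, file) {
  p <- validate_cvs_params(p)
  out <- c("# closed-loop cardiovascular model constants (mmHg / mL / s)")
  for (g in names(.cvs_param_groups)) {
    out <- c(out, "", paste0("# ", gsub("_", " ", g)))
    for (nm in .cvs_param_groups[[g]]) {
      out <- c(out, sprintf("%s = %.17g", nm, p[[nm]]))
    }
  }
  writeLines(out, file)
  invisible(file)
}

# Short stable checksum of a parameter set, recorded in trajectory metadata.
params_checksum <- function(p) {
  p <- validate_cvs_params(p)
  s <- paste(sprintf("%s=%.17g", names(p), unlist(p)), collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
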