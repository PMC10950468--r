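# Run configuration: a YAML file with sections mirroring the module
# configurations, schema-validated (unknown keys rejected) before any
# computation.

default_run_config <- function() {
  yaml::read_yaml(system.file("extdata", "default_config.yaml",
                              package = "cvsude"))
}

check_config_keys <- function(cfg, ref, prefix = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(ref)) {
    if (is.list(ref[[k]])) {
      if (!is.null(cfg[[k]]) && !is.list(cfg[[k]])) {
        stop("config key '", prefix, k, "' must be a section", call. = FALSE)
      }
      cfg[[k]] <- check_config_keys(
        if (is.null(cfg[[k]])) list() else cfg[[k]],
        ref[[k]], paste0(prefix, k, "."))
    } else if (is.null(cfg[[k]]) && !(k %in% names(cfg))) {
      cfg[k] <- ref[k]
    }
  }
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (sections `paths`, `solver`, `training`, `sr`,
#' `evaluation`, plus the global `seed` and `log_level`), validates it
#' strictly against the schema -- unknown keys are rejected -- and fills
#' omitted keys from the shipped defaults.
#'
#' All stage seeds derive from the single global `seed` by fixed offsets:
#' measurement noise uses `seed + 1000`, ensemble training uses `seed` as its
#' base member seed, and symbolic regression uses `seed + 2000`.
#'
#' @param path YAML file; `NULL` for the shipped defaults.
#' @param seed optional override of the global seed.
#' @return validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, seed = NULL) {
  ref <- default_run_config()
  cfg <- if (is.null(path)) ref else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    check_config_keys(yaml::read_yaml(path), ref)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stopifnot(is.numeric(cfg$seed), cfg$solver$dt > 0, cfg$training$window > 0)
  class(cfg) <- c("run_config", "list")
  cfg
}

config_params <- function(cfg) {
  if (is.null(cfg$paths$params)) cvs_params() else
    read_cvs_params(cfg$paths$params)
}

config_solver <- function(cfg) {
  solver_settings(method = cfg$solver$method, hmax = cfg$solver$hmax,
                  atol = cfg$solver$atol, rtol = cfg$solver$rtol,
                  dt = cfg$solver$dt)
}

config_training <- function(cfg, noise = NULL, seed = NULL) {
  tr <- cfg$training
  training_config(
    window = tr$window, dt = cfg$solver$dt,
    noise = if (is.null(noise)) tr$noise else noise,
    schedule = list(c(lr = tr$stage1_lr, iters = tr$stage1_iters),
                    c(lr = tr$stage2_lr, iters = tr$stage2_iters)),
    threshold = tr$threshold, ensemble_size = tr$ensemble_size,
    max_attempts = tr$max_attempts,
    base_seed = if (is.null(seed)) cfg$seed else seed, nsub = tr$nsub)
}

config_sr <- function(cfg) {
  s <- cfg$sr
  sr_config(population = s$population, generations = s$generations,
            tournament = s$tournament, p_crossover = s$p_crossover,
            p_subtree = s$p_subtree, p_point = s$p_point,
            max_complexity = s$max_complexity, p_exp = s$p_exp,
            optimize_constants = s$optimize_constants,
            subsample = s$subsample, seed = cfg$seed + 2000L)
}
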