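# The neural surrogate for ventricular interaction: a fully connected
# 5 -> 10 -> 10 -> 10 -> 2 network (ELU hidden activations, linear output
# head) mapping (V_lv, V_rv, V_ao, V_vc, V_pa) to (V_spt, P_peri).

.net_widths <- c(5L, 10L, 10L, 10L, 2L)

#' Initialize network parameters
#'
#' Seeded Glorot (fan-in/fan-out) uniform initialization of the
#' 5-10-10-10-2 fully connected network: weights drawn from
#' `U(-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out)))`, biases zero.
#' Reproducible: the same seed yields identical parameters and the caller's
#' RNG state is restored.
#'
#' @param seed integer seed.
#' @return object of class `network_params`: per-layer weight matrices
#'   (`n_out x n_in`) and bias vectors, plus the creation seed.
#' @export
init_network <- function(seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  W <- list(); b <- list()
  for (l in seq_len(length(.net_widths) - 1L)) {
    n_in <- .net_widths[l]; n_out <- .net_widths[l + 1L]
    lim <- sqrt(6 / (n_in + n_out))
    W[[l]] <- matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
    b[[l]] <- numeric(n_out)
  }
  structure(list(weights = W, biases = b, seed = as.integer(seed)),
            class = "network_params")
}

validate_network <- function(net) {
  stopifnot(inherits(net, "network_params"),
            length(net$weights) == 4L, length(net$biases) == 4L)
  for (l in 1:4) {
    stopifnot(all(dim(net$weights[[l]]) ==
                    c(.net_widths[l + 1L], .net_widths[l])),
              length(net$biases[[l]]) == .net_widths[l + 1L],
              all(is.finite(net$weights[[l]])), all(is.finite(net$biases[[l]])))
  }
  net
}

# flat parameter vector in the layout the compiled core expects
# (column-major weights, layer by layer, each followed by its bias)
flatten_network <- function(net) {
  net <- validate_network(net)
  unlist(lapply(1:4, function(l) c(as.vector(net$weights[[l]]),
                                   net$biases[[l]])), use.names = FALSE)
}

unflatten_network <- function(theta, seed = NA_integer_) {
  stopifnot(length(theta) == 302L, all(is.finite(theta)))
  W <- list(); b <- list(); off <- 0L
  for (l in 1:4) {
    n_in <- .net_widths[l]; n_out <- .net_widths[l + 1L]
    W[[l]] <- matrix(theta[off + seq_len(n_out * n_in)], n_out, n_in)
    off <- off + n_out * n_in
    b[[l]] <- theta[off + seq_len(n_out)]
    off <- off + n_out
  }
  structure(list(weights = W, biases = b, seed = seed),
            class = "network_params")
}

elu <- function(x) ifelse(x > 0, x, expm1(x))

#' Network forward pass
#'
#' Evaluates the ventricular-interaction surrogate at one or more volume
#' states. Inputs are the five volumes `(V_lv, V_rv, V_ao, V_vc, V_pa)` in
#' mL (`V_pu` and the valve flows are deliberately not inputs); outputs are
#' the estimates of the septum free-wall volume (mL) and the pericardium
#' pressure (mmHg). Deterministic and differentiable in inputs and
#' parameters.
#'
#' @param volumes numeric 5-vector, or a matrix with 5 columns.
#' @param net a `network_params` object.
#' @param scaling affine input scaling `list(mu, sd)` applied as
#'   `(x - mu)/sd` before the first layer; default identity.
#' @return numeric 2-vector `(V_spt, P_peri)`, or an n-by-2 matrix.
#' @export
nn_forward <- function(volumes, net, scaling = identity_scaling()) {
  net <- validate_network(net)
  X <- if (is.matrix(volumes)) volumes else matrix(volumes, nrow = 1)
  if (ncol(X) != 5L) stop("network input must have 5 columns", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite network input", call. = FALSE)
  H <- sweep(sweep(X, 2, scaling$mu, "-"), 2, scaling$sd, "/")
  for (l in 1:4) {
    H <- H %*% t(net$weights[[l]])
    H <- sweep(H, 2, net$biases[[l]], "+")
    if (l < 4) H <- elu(H)
  }
  colnames(H) <- c("V_spt", "P_peri")
  if (is.matrix(volumes)) H else drop(H)
}

#' Input scaling descriptors
#'
#' `identity_scaling()` leaves the raw volumes untouched;
#' `scaling_from_trajectory()` computes per-input mean/standard deviation of
#' the five volume series over a (training) trajectory, the default used by
#' [train_single()]. The descriptor is stored inside the hybrid model so
#' that its predictions are self-contained.
#'
#' @param traj a `cvs_trajectory`.
#' @return `list(mu, sd)` of length-5 numeric vectors.
#' @export
identity_scaling <- function() {
  list(mu = rep(0, 5), sd = rep(1, 5))
}

#' @rdname identity_scaling
#' @export
scaling_from_trajectory <- function(traj) {
  stopifnot(inherits(traj, "cvs_trajectory"))
  X <- traj$states[, 5:9, drop = FALSE]
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = unname(mu), sd = unname(sd))
}

#' Hybrid model: mechanistic constants + neural ventricular interaction
#'
#' Bundles the mechanistic constant set, the network parameters and the input
#' scaling descriptor. When embedded through [as_vi_provider()], the model's
#' right-hand side never solves the nonlinear septum equation: both
#' interaction terms come from the network.
#'
#' @param params a [cvs_params()] set.
#' @param net a `network_params` object.
#' @param scaling input scaling (see [identity_scaling()]).
#' @return object of class `hybrid_model`.
#' @export
hybrid_model <- function(params, net, scaling = identity_scaling()) {
  structure(list(params = validate_cvs_params(params),
                 net = validate_network(net),
                 scaling = scaling),
            class = "hybrid_model")
}

#' Embed a hybrid model as a VI provider
#'
#' Returns a callback-mode [vi_callback()] provider that applies the stored
#' input scaling and the network forward pass. The hybrid system is then
#' integrable with [cvs_integrate()]; no Newton-Raphson call occurs anywhere
#' on this path.
#'
#' @param model a [hybrid_model()].
#' @return a `vi_provider` of mode `callback`.
#' @export
as_vi_provider <- function(model) {
  stopifnot(inherits(model, "hybrid_model"))
  theta <- flatten_network(model$net)
  mu <- model$scaling$mu; sd <- model$scaling$sd
  vi_callback(function(V_lv, V_rv, V_ao, V_vc, V_pa) {
    .nn_eval_cpp(theta, mu, sd,
                 matrix(c(V_lv, V_rv, V_ao, V_vc, V_pa), 1L, 5L))[1L, ]
  })
}

#' Write / read network weights
#'
#' Text-based exact-decimal container: `#key=value` lines carry the shape
#' manifest, creation seed and scaling descriptor, followed by one parameter
#' value per line (17 significant digits) in the canonical flat layout.
#'
#' @param net a `network_params` object.
#' @param path file path.
#' @param scaling input scaling descriptor stored with the weights.
#' @return `read_network()` returns `list(net, scaling)`.
#' @export
write_network <- function(net, path, scaling = identity_scaling()) {
  net <- validate_network(net)
  theta <- flatten_network(net)
  hdr <- c(sprintf("#widths=%s", paste(.net_widths, collapse = ",")),
           sprintf("#seed=%d", net$seed),
           sprintf("#scaling_mu=%s", paste(sprintf("%.17g", scaling$mu), collapse = ",")),
           sprintf("#scaling_sd=%s", paste(sprintf("%.17g", scaling$sd), collapse = ",")))
  writeLines(c(hdr, sprintf("%.17g", theta)), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines)]
  getm <- function(key) {
    ln <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (!length(ln)) stop("network file missing #", key, call. = FALSE)
    sub(paste0("^#", key, "="), "", ln[1])
  }
  widths <- as.integer(strsplit(getm("widths"), ",")[[1]])
  if (!identical(widths, .net_widths)) {
    stop("network file shape manifest does not match 5-10-10-10-2",
         call. = FALSE)
  }
  seed <- suppressWarnings(as.integer(getm("seed")))
  mu <- as.numeric(strsplit(getm("scaling_mu"), ",")[[1]])
  sd <- as.numeric(strsplit(getm("scaling_sd"), ",")[[1]])
  theta <- as.numeric(body[nzchar(body)])
  net <- unflatten_network(theta, seed = seed)
  list(net = net, scaling = list(mu = mu, sd = sd))
}
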