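#' Network hyperparameters
#'
#' Parameters of the random rate network prior to training. The base
#' connectivity `J` has i.i.d. Gaussian entries with variance `g^2 / N`,
#' so `g` sets the spectral radius of `J` (circular law); `sigma_f2` is
#' the variance of the output- and latent-feedback weights; `sparsity`
#' is the fraction of `J` entries forced to zero (Bernoulli mask applied
#' after drawing, with no variance rescaling, so the realized radius
#' shrinks to about `g * sqrt(1 - sparsity)`).
#'
#' Defaults are the indirect fixed-point (IFP) exemplar initialization
#' `g = 0.9`, `sigma_f2 = 0.05`, `sparsity = 0.1` at `N = 1000`.
#'
#' @param N Neuron count (>= 2).
#' @param g Connection-strength scale (>= 0, dimensionless).
#' @param sigma_f2 Feedback-weight variance (> 0).
#' @param sparsity Fraction of `J` entries zeroed, in `[0, 1)`.
#' @param input_var Variance of the input weights.
#' @param tau Network time constant (the dynamics are defined with
#'   `tau = 1`).
#' @param dt Euler integration step.
#' @param seed Optional integer seed consumed by [init_network()].
#' @return An object of class `network_params`.
#' @export
network_params <- function(N = 1000L, g = 0.9, sigma_f2 = 0.05,
                           sparsity = 0.1, input_var = 0.02, tau = 1,
                           dt = 0.1, seed = NULL) {
  N <- as.integer(N)
  stopifnot(N >= 2L, g >= 0, sigma_f2 > 0, sparsity >= 0, sparsity < 1,
            input_var > 0, tau > 0, dt > 0)
  structure(list(N = N, g = g, sigma_f2 = sigma_f2, sparsity = sparsity,
                 input_var = input_var, tau = tau, dt = dt, seed = seed),
            class = "network_params")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Initialize a network bundle
#'
#' Draws the fixed weight matrices: base connectivity `J` with entries
#' `N(0, g^2/N)` then zeroed i.i.d. with probability `sparsity`; input
#' weights `W_i` (`N x 2`, variance `input_var`); feedback weights `W_f`
#' (`N x 1`) and `W_fd` (`N x 2`) with variance `sigma_f2`. The trained
#' readouts `W_o` (`N x 1`) and `W_d` (`N x 2`) start at exactly zero.
#' If `params$seed` is set the draw is made under that seed (the ambient
#' RNG state is restored afterwards).
#'
#' @param params A [network_params()] object.
#' @return An object of class `network_bundle` with the weight matrices,
#'   `params`, and bookkeeping fields `trained` and `provenance`.
#' @export
#' @examples
#' net <- init_network(network_params(N = 50, seed = 1))
#' all(net$W_o == 0)
init_network <- function(params) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N
  with_seed(params$seed, {
    J <- matrix(rnorm(N * N, 0, params$g / sqrt(N)), N, N)
    if (params$sparsity > 0)
      J[runif(N * N) < params$sparsity] <- 0
    W_i <- matrix(rnorm(2L * N, 0, sqrt(params$input_var)), N, 2L)
    W_f <- matrix(rnorm(N, 0, sqrt(params$sigma_f2)), N, 1L)
    W_fd <- matrix(rnorm(2L * N, 0, sqrt(params$sigma_f2)), N, 2L)
    structure(list(params = params, J = J, W_i = W_i, W_f = W_f,
                   W_fd = W_fd, W_o = matrix(0, N, 1L),
                   W_d = matrix(0, N, 2L), trained = FALSE,
                   provenance = list(seed = params$seed)),
              class = "network_bundle")
  })
}

#' Effective (task) connectivity
#'
#' The trained network's connectivity is the base matrix plus the rank-3
#' feedback-times-readout structure:
#' `J_T = J + W_f W_o^T + W_fd W_d^T`. Before training (zero readouts)
#' this equals `J` exactly, and `J_T - J` always has rank at most 3.
#'
#' @param net A [init_network()] bundle.
#' @return The `N x N` effective connectivity matrix.
#' @export
effective_connectivity <- function(net) {
  net$J + net$W_f %*% t(net$W_o) + net$W_fd %*% t(net$W_d)
}

#' Simulate the network by forward Euler integration
#'
#' Integrates `tau * dx/dt = -x + J_T r + W_i u` with `r = tanh(x)` and
#' both readouts fed back through `W_f`, `W_fd`. Weights are frozen: this
#' is the forward simulation used for evaluation and analysis.
#'
#' @param net A `network_bundle`.
#' @param u Input series, `2 x T` numeric matrix.
#' @param x0 Initial state (length-`N`, default zero).
#' @return An object of class `trajectory`: `x` and `r` are `T x N`
#'   matrices (state after each Euler step and its rate `tanh(x)`),
#'   `z_o` the length-`T` output, `z_d` the `T x 2` latent readout,
#'   plus `dt`.
#' @export
simulate_network <- function(net, u, x0 = rep(0, net$params$N)) {
  stopifnot(inherits(net, "network_bundle"), is.matrix(u), nrow(u) == 2L,
            length(x0) == net$params$N, all(is.finite(u)),
            all(is.finite(x0)))
  out <- sim_core(net$J, net$W_i, net$W_f[, 1L], net$W_fd, net$W_o[, 1L],
                  net$W_d, u, as.numeric(x0), net$params$dt,
                  net$params$tau)
  structure(list(x = out$x, r = out$r, z_o = as.numeric(out$z_o),
                 z_d = out$z_d, dt = net$params$dt),
            class = "trajectory")
}

#' Save or load a network bundle
#'
#' The bundle is stored as a single RDS file with a human-readable JSON
#' sidecar (`<path>.json`) carrying the scalar parameters and training
#' provenance (seed, epochs, final RMSE).
#'
#' @param net A `network_bundle`.
#' @param path Destination path for the RDS file.
#' @return `write_network_bundle()` returns `path` invisibly;
#'   `read_network_bundle()` returns the bundle.
#' @export
write_network_bundle <- function(net, path) {
  saveRDS(net, path)
  meta <- list(params = unclass(net$params), trained = net$trained,
               provenance = net$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_network_bundle
#' @export
read_network_bundle <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "network_bundle"))
  net
}

#' @export
print.network_bundle <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<network_bundle> N = %d, g = %g, sigma_f2 = %g, sparsity = %g\n",
    p$N, p$g, p$sigma_f2, p$sparsity))
  cat(sprintf("  trained: %s\n", x$trained))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d steps x %d neurons (dt = %g)\n",
              nrow(x$x), ncol(x$x), x$dt))
  invisible(x)
}
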