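#' Trainer state for the temporally restricted FORCE rule
#'
#' Holds the two inverse-correlation estimates of recursive least squares:
#' `P_o` accumulated over response epochs for the output readout `W_o`,
#' and `P_d` over delay epochs, shared by the two columns of the latent
#' readout `W_d`. Both start at `I / alpha` (a ridge prior with
#' regularization `alpha`, default 1, i.e. the identity).
#'
#' @param N Neuron count.
#' @param alpha Regularization parameter (> 0).
#' @param update_every Update cadence: one RLS update per `update_every`
#'   kernel steps (default 2).
#' @param rmse_threshold Convergence bound on the frozen-weight RMSE of
#'   every trial type (default 0.01).
#' @param max_epochs Cap on training epochs.
#' @return An object of class `trainer_state`.
#' @export
trainer_state <- function(N, alpha = 1, update_every = 2L,
                          rmse_threshold = 0.01, max_epochs = 500L) {
  stopifnot(N >= 1L, alpha > 0, update_every >= 1L, rmse_threshold > 0,
            max_epochs >= 1L)
  structure(list(P_o = diag(N) / alpha, P_d = diag(N) / alpha,
                 alpha = alpha, update_every = as.integer(update_every),
                 rmse_threshold = rmse_threshold,
                 max_epochs = as.integer(max_epochs)),
            class = "trainer_state")
}

#' One recursive least-squares update
#'
#' Rank-one update of the inverse-correlation estimate and the readout
#' column: `P' = P - (P r)(P r)^T / (1 + r^T P r)` and
#' `W' = W - e * P' r`, where the weight update uses the post-update
#' `P'` (note `P' r = P r / (1 + r^T P r)`). `P'` equals the exact
#' inverse of `P^{-1} + r r^T` (Sherman–Morrison), so a full pass over a
#' batch starting from `P = I / alpha`, `W = 0` lands exactly on the
#' ridge-regression solution with penalty `alpha`.
#'
#' This reference implementation mirrors the compiled update used inside
#' [train_trial()].
#'
#' @param W Readout column (length-`N` numeric).
#' @param P `N x N` symmetric positive-definite matrix.
#' @param r Rate vector (length `N`).
#' @param e Scalar error `z - f` at this step.
#' @return `list(W, P)` with the updated column and matrix.
#' @export
rls_update <- function(W, P, r, e) {
  stopifnot(all(is.finite(W)), all(is.finite(P)), all(is.finite(r)),
            is.finite(e))
  Pr <- P %*% r
  denom <- 1 + sum(r * Pr)
  P2 <- P - tcrossprod(Pr) / denom
  W2 <- W - e * (Pr / denom)
  list(W = W2, P = P2)
}

trial_epoch_codes <- function(trial) {
  Ttot <- ncol(trial$u)
  ep <- integer(Ttot)
  ep[trial$masks$delay1] <- 1L
  ep[trial$masks$delay2] <- 1L
  ep[trial$masks$response] <- 2L
  fd <- matrix(0, 2L, Ttot)
  fd[, trial$masks$delay1] <- trial$f_d1
  fd[, trial$masks$delay2] <- trial$f_d2
  list(ep = ep, fd = fd)
}

#' Train the readouts on a single trial
#'
#' Simulates the trial step by step and, on every `update_every`-th step
#' inside the error kernel (delay and response epochs), applies the RLS
#' update: during delays each column of `W_d` is regressed against the
#' active latent target using the shared `P_d`; during the response
#' `W_o` is regressed against the scalar output target using `P_o`. No
#' weight changes occur outside the kernel.
#'
#' @param net A `network_bundle`.
#' @param trial A [build_trial()] object.
#' @param tstate A [trainer_state()].
#' @param x0 Initial state for this trial (state carries over between
#'   consecutive trials during training).
#' @return A list with the updated `net` and `tstate`, the final state
#'   `x`, the readout traces `z_o`, `z_d`, and `errors` (per-trial RMSE
#'   plus the instantaneous pre/post-update output errors at each
#'   response-epoch update event).
#' @export
train_trial <- function(net, trial, tstate, x0 = rep(0, net$params$N)) {
  stopifnot(inherits(net, "network_bundle"),
            inherits(trial, "trial"), inherits(tstate, "trainer_state"))
  codes <- trial_epoch_codes(trial)
  out <- train_core(net$J, net$W_i, net$W_f[, 1L], net$W_fd,
                    net$W_o[, 1L], net$W_d, tstate$P_o, tstate$P_d,
                    trial$u, codes$ep, codes$fd, trial$f_o,
                    as.numeric(x0), net$params$dt, net$params$tau,
                    tstate$update_every)
  net$W_o <- matrix(out$W_o, ncol = 1L)
  net$W_d <- out$W_d
  tstate$P_o <- out$P_o
  tstate$P_d <- out$P_d
  err <- trial_rmse(out$z_o, out$z_d, trial)
  list(net = net, tstate = tstate, x = as.numeric(out$x_final),
       z_o = as.numeric(out$z_o), z_d = out$z_d,
       errors = c(err, list(n_updates = out$n_updates,
                            update_step = out$update_step,
                            e_pre = out$e_pre, e_post = out$e_post)))
}

# RMSE over the error kernel: latent readout over both delays (pooled
# over steps and the two components), output over the response window,
# then the mean of the two.
trial_rmse <- function(z_o, z_d, trial) {
  ed1 <- sweep(z_d[trial$masks$delay1, , drop = FALSE], 2L, trial$f_d1)
  ed2 <- sweep(z_d[trial$masks$delay2, , drop = FALSE], 2L, trial$f_d2)
  rmse_d <- sqrt(mean(c(ed1, ed2)^2))
  rmse_o <- sqrt(mean((z_o[trial$masks$response] - trial$f_o)^2))
  list(rmse_d = rmse_d, rmse_o = rmse_o, rmse = (rmse_d + rmse_o) / 2)
}

all_digit_pairs <- function(n_classes = 2L) {
  expand.grid(d1 = seq_len(n_classes) - 1L, d2 = seq_len(n_classes) - 1L,
              KEEP.OUT.ATTRS = FALSE)[, c("d1", "d2")]
}

#' Evaluate a network with frozen weights
#'
#' Runs one validation trial per ordered digit pair (fresh stimulus
#' noise, no weight updates) and reports the kernel RMSE of each.
#' Network state carries over from trial to trial.
#'
#' @param net A `network_bundle`.
#' @param timing,model Task definition.
#' @param x0 State entering the first validation trial.
#' @return `list(rmse, x)`: per-pair RMSE vector and the final state.
#' @export
evaluate_network <- function(net, timing = trial_timing(),
                             model = stimulus_model(),
                             x0 = rep(0, net$params$N)) {
  pairs <- all_digit_pairs(model$n_classes)
  x <- x0
  rmse <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    tr <- build_trial(pairs$d1[k], pairs$d2[k], timing, model)
    traj <- simulate_network(net, tr$u, x)
    rmse[k] <- trial_rmse(traj$z_o, traj$z_d, tr)$rmse
    x <- traj$x[nrow(traj$x), ]
  }
  list(rmse = rmse, x = x)
}

#' Train a network on the sequential pattern-matching task
#'
#' Epoch structure: at the start of each epoch the network is evaluated
#' with frozen weights on one fresh validation trial per ordered digit
#' pair; if every trial's kernel RMSE is below `rmse_threshold` training
#' stops (converged). Otherwise one training trial per pair is run with
#' RLS updates inside the error kernel. Network state carries over
#' across all trials (validation and training), emulating a continuous
#' session of concatenated trials. Non-convergence within `max_epochs`
#' is reported via the log, not an error.
#'
#' Stimulus noise is drawn from the ambient RNG: seed with [set.seed()]
#' (together with `params$seed` for the weights) for bit-reproducible
#' training.
#'
#' @param net An untrained (or partially trained) `network_bundle`.
#' @param timing,model Task definition.
#' @param tstate A [trainer_state()]; defaults to a fresh state.
#' @param verbose Print per-epoch RMSE.
#' @return `list(net, log)`: the trained bundle (with `trained` and
#'   provenance set) and a `training_log` containing the per-epoch,
#'   per-pair validation RMSE matrix, `epochs` (training epochs run),
#'   `converged`, and `final_rmse`.
#' @export
train_network <- function(net, timing = trial_timing(),
                          model = stimulus_model(),
                          tstate = trainer_state(net$params$N),
                          verbose = FALSE) {
  pairs <- all_digit_pairs(model$n_classes)
  x <- rep(0, net$params$N)
  rmse_hist <- NULL
  converged <- FALSE
  epochs_run <- 0L
  for (epoch in seq_len(tstate$max_epochs + 1L)) {
    ev <- evaluate_network(net, timing, model, x)
    x <- ev$x
    rmse_hist <- rbind(rmse_hist, ev$rmse)
    if (verbose)
      message(sprintf("epoch %3d: rmse %s", epoch - 1L,
                      paste(signif(ev$rmse, 3), collapse = " ")))
    if (all(ev$rmse < tstate$rmse_threshold)) {
      converged <- TRUE
      break
    }
    if (epoch > tstate$max_epochs) break
    for (k in seq_len(nrow(pairs))) {
      tr <- build_trial(pairs$d1[k], pairs$d2[k], timing, model)
      res <- train_trial(net, tr, tstate, x)
      net <- res$net
      tstate <- res$tstate
      x <- res$x
    }
    epochs_run <- epochs_run + 1L
  }
  final <- rmse_hist[nrow(rmse_hist), ]
  net$trained <- converged
  net$provenance <- c(net$provenance[setdiff(names(net$provenance),
                                             c("epochs", "final_rmse",
                                               "converged"))],
                      list(epochs = epochs_run, final_rmse = mean(final),
                           converged = converged))
  log <- structure(list(rmse = unname(rmse_hist), epochs = epochs_run,
                        converged = converged, final_rmse = mean(final),
                        rmse_threshold = tstate$rmse_threshold),
                   class = "training_log")
  list(net = net, log = log, tstate = tstate)
}

#' @export
print.training_log <- function(x, ...) {
  cat(sprintf("<training_log> %d epochs, converged: %s, final RMSE %.4g\n",
              x$epochs, x$converged, x$final_rmse))
  invisible(x)
}
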