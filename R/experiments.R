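# Fixed stimulus realizations for a battery of trials (n_real
# realizations of each ordered digit pair), plus per-trial entry states
# obtained by running the battery as one concatenated session (after a
# warm-up pass over the four pairs, as during training). Perturbed
# variants of trial i then start from the same entry state as the
# unperturbed trial i, isolating the effect of the perturbation.
build_battery <- function(net, timing, model, n_real, warmup = 1L) {
  pairs <- all_digit_pairs(model$n_classes)
  x <- rep(0, net$params$N)
  for (w in seq_len(warmup)) {
    for (k in seq_len(nrow(pairs))) {
      tr <- build_trial(pairs$d1[k], pairs$d2[k], timing, model)
      traj <- simulate_network(net, tr$u, x)
      x <- traj$x[nrow(traj$x), ]
    }
  }
  out <- list()
  for (real in seq_len(n_real)) {
    for (k in seq_len(nrow(pairs))) {
      b <- list(d1 = pairs$d1[k], d2 = pairs$d2[k], realization = real,
                s1 = sample_stimulus(pairs$d1[k], timing$stim_len, model),
                s2 = sample_stimulus(pairs$d2[k], timing$stim_len, model),
                x0 = x)
      tr <- build_trial(b$d1, b$d2, timing, model,
                        stimuli = list(s1 = b$s1, s2 = b$s2))
      traj <- simulate_network(net, tr$u, x)
      b$z_o_ref <- traj$z_o[tr$masks$response]
      b$outcome <- tr$outcome
      x <- traj$x[nrow(traj$x), ]
      out[[length(out) + 1L]] <- b
    }
  }
  out
}

run_battery_trial <- function(net, timing, model, b,
                              delay1_len = timing$delay_len,
                              delay2_len = timing$delay_len,
                              noise_var = 0) {
  s1 <- b$s1
  if (noise_var > 0)
    s1 <- s1 + matrix(rnorm(length(s1), 0, sqrt(noise_var)), 2L)
  tr <- build_trial(b$d1, b$d2, timing, model, delay1_len = delay1_len,
                    delay2_len = delay2_len,
                    stimuli = list(s1 = s1, s2 = b$s2))
  traj <- simulate_network(net, tr$u, b$x0)
  list(z_o = traj$z_o[tr$masks$response], outcome = tr$outcome)
}

robustness_rows <- function(grid, grid_name, battery, runner) {
  rows <- lapply(grid, function(gval) {
    pert <- runner(gval)
    dev <- mean(vapply(seq_along(battery), function(i)
      mean((pert[[i]]$z_o - battery[[i]]$z_o_ref)^2), numeric(1)))
    correct <- mean(vapply(seq_along(battery), function(i)
      decode_outcome(pert[[i]]$z_o) == pert[[i]]$outcome, logical(1)))
    data.frame(grid = gval, deviation = dev, decode_correct = correct)
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- grid_name
  out
}

#' Extended-delay robustness experiment
#'
#' Lengthens the first delay by `factor * delay_len` steps (weights
#' frozen, identical stimulus realizations) and compares the
#' response-window output against the unperturbed run: the mean squared
#' output deviation and the fraction of trials still decoding to the
#' correct outcome. Direct fixed-point networks hold their memory
#' through arbitrary extensions; slow-manifold networks gradually
#' forget.
#'
#' @param net A trained `network_bundle` (never mutated).
#' @param factors Extension factors as fractions of the nominal delay
#'   (e.g. `1` doubles the first delay). `0` reproduces the unperturbed
#'   trial exactly.
#' @param timing,model Task definition.
#' @param n_real Stimulus realizations per ordered digit pair.
#' @param extend_second Extend the second delay instead of the first.
#' @param warmup Warm-up passes initializing the session (see
#'   [classify_mechanism()]).
#' @return A `robustness_curve` data frame with columns `factor`,
#'   `deviation`, `decode_correct`.
#' @export
extended_delay_experiment <- function(net, factors = c(0, 0.25, 0.5, 0.75,
                                                       1, 1.5, 2),
                                      timing = trial_timing(),
                                      model = stimulus_model(),
                                      n_real = 5L, extend_second = FALSE,
                                      warmup = 1L) {
  stopifnot(isTRUE(all(diff(factors) > 0)) || length(factors) == 1L)
  battery <- build_battery(net, timing, model, n_real, warmup)
  runner <- function(f) {
    extra <- as.integer(round(f * timing$delay_len))
    d1 <- timing$delay_len + if (extend_second) 0L else extra
    d2 <- timing$delay_len + if (extend_second) extra else 0L
    lapply(battery, function(b)
      run_battery_trial(net, timing, model, b, delay1_len = d1,
                        delay2_len = d2))
  }
  out <- robustness_rows(factors, "factor", battery, runner)
  attr(out, "mode") <- if (extend_second) "delay2" else "delay1"
  class(out) <- c("robustness_curve", class(out))
  out
}

#' Distractor-noise robustness experiment
#'
#' Adds i.i.d. zero-mean Gaussian noise of each variance to the input
#' during the first stimulus only (fresh noise per trial and variance,
#' weights frozen) and measures the deviation of the response-window
#' output from the noise-free run plus the decoding accuracy. The
#' task's own stimulus variance is attached as the reference line.
#'
#' @param net A trained `network_bundle`.
#' @param variances Noise-variance grid (strictly increasing).
#' @param timing,model Task definition.
#' @param n_real Stimulus realizations per ordered digit pair.
#' @param warmup Warm-up passes initializing the session.
#' @return A `robustness_curve` data frame with columns `variance`,
#'   `deviation`, `decode_correct`; attribute `stimulus_variance`.
#' @export
noise_robustness_experiment <- function(net,
                                        variances = c(0, 0.01, 0.05, 0.1,
                                                      0.2, 0.5, 1),
                                        timing = trial_timing(),
                                        model = stimulus_model(),
                                        n_real = 5L, warmup = 1L) {
  stopifnot(isTRUE(all(diff(variances) > 0)) || length(variances) == 1L)
  battery <- build_battery(net, timing, model, n_real, warmup)
  runner <- function(v)
    lapply(battery, function(b)
      run_battery_trial(net, timing, model, b, noise_var = v))
  out <- robustness_rows(variances, "variance", battery, runner)
  attr(out, "stimulus_variance") <- mean(model$class_stds^2)
  attr(out, "mode") <- "noise"
  class(out) <- c("robustness_curve", class(out))
  out
}

#' Sweep initialization parameters and census the emergent mechanisms
#'
#' For every combination of `g`, `sigma_f2`, `sparsity` and seed:
#' initialize, train, and (when converged) classify the mechanism.
#' Individual failures are recorded, never abort the sweep. All
#' randomness derives from the per-run seed, so a manifest (grid plus
#' seeds) regenerates identical records.
#'
#' @param g_values,sigma_f2_values,sparsity_values Parameter grids.
#' @param seeds Integer seeds (one training run per grid cell and seed).
#' @param N Network size for every run.
#' @param timing,model Task definition.
#' @param max_epochs Training-epoch cap per run.
#' @param n_real Realizations per pair for mechanism classification.
#' @param classify_args Extra arguments passed to
#'   [classify_mechanism()].
#' @param verbose Print one line per run.
#' @return A list with `records` (one row per run: parameters, seed,
#'   `converged`, `epochs`, `final_rmse`, `label`) and `census` (see
#'   [sweep_census()]).
#' @export
parameter_sweep <- function(g_values, sigma_f2_values, sparsity_values,
                            seeds, N = 300L, timing = trial_timing(),
                            model = stimulus_model(), max_epochs = 100L,
                            n_real = 3L, classify_args = list(),
                            verbose = FALSE) {
  grid <- expand.grid(g = g_values, sigma_f2 = sigma_f2_values,
                      sparsity = sparsity_values, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  stopifnot(nrow(grid) > 0L)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gi <- grid[i, ]
    rec <- data.frame(gi, converged = FALSE, epochs = NA_integer_,
                      final_rmse = NA_real_, label = "UNTRAINABLE",
                      stringsAsFactors = FALSE)
    ok <- try({
      set.seed(gi$seed)
      params <- network_params(N = N, g = gi$g, sigma_f2 = gi$sigma_f2,
                               sparsity = gi$sparsity, seed = gi$seed)
      net <- init_network(params)
      fit <- train_network(net, timing, model,
                           trainer_state(N, max_epochs = max_epochs))
      rec$converged <- fit$log$converged
      rec$epochs <- fit$log$epochs
      rec$final_rmse <- fit$log$final_rmse
      if (fit$log$converged) {
        lab <- do.call(classify_mechanism,
                       c(list(net = fit$net, timing = timing,
                              model = model, n_real = n_real),
                         classify_args))
        rec$label <- lab$label
      }
    }, silent = TRUE)
    if (inherits(ok, "try-error"))
      rec$label <- "UNTRAINABLE"
    if (verbose)
      message(sprintf(
        "g=%.2g sigma_f2=%.3g sparsity=%.2g seed=%d -> %s (%s epochs)",
        gi$g, gi$sigma_f2, gi$sparsity, gi$seed, rec$label,
        ifelse(is.na(rec$epochs), "?", rec$epochs)))
    rec
  })
  records <- do.call(rbind, rows)
  list(records = records, census = sweep_census(records))
}

#' Aggregate a sweep into per-parameter censuses
#'
#' For each of the three initialization parameters, the fraction of
#' trainable networks per value (`relative_count`) and the mechanism
#' counts among them. Mechanism counts sum to the number of trainable
#' records.
#'
#' @param records The `records` data frame from [parameter_sweep()].
#' @return A list with one data frame per parameter plus `labels`, the
#'   overall mechanism table.
#' @export
sweep_census <- function(records) {
  mechs <- c("DFP", "IFP", "LC", "Mix")
  per_param <- function(param) {
    vals <- sort(unique(records[[param]]))
    do.call(rbind, lapply(vals, function(v) {
      sub <- records[records[[param]] == v, ]
      counts <- vapply(mechs, function(m) sum(sub$label == m), integer(1))
      data.frame(value = v, n = nrow(sub),
                 relative_count = mean(sub$converged),
                 t(counts))
    }))
  }
  list(g = per_param("g"), sigma_f2 = per_param("sigma_f2"),
       sparsity = per_param("sparsity"),
       labels = table(factor(records$label,
                             levels = c(mechs, "UNTRAINABLE"))))
}
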