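#' Autonomous forward simulation from an arrest state
#'
#' Simulates the network with zero input from `x0` for
#' `duration_multiplier` times the nominal trial length, the horizon
#' after which the state is assumed to have reached its stationary
#' regime (a fixed point or limit cycle neighbourhood).
#'
#' @param net A `network_bundle` (weights frozen).
#' @param x0 Starting state.
#' @param duration_multiplier Horizon in units of the nominal trial
#'   length (default 10).
#' @param timing A [trial_timing()] defining the nominal trial length.
#' @return A `trajectory`.
#' @export
forward_simulate <- function(net, x0, duration_multiplier = 10,
                             timing = trial_timing()) {
  Tfs <- as.integer(round(duration_multiplier * trial_length(timing)))
  stopifnot(Tfs >= 2L)
  simulate_network(net, matrix(0, 2L, Tfs), x0)
}

#' Classify the asymptotic set of a trajectory tail
#'
#' Examines the final `tail_frac` of the trajectory. The tail is a
#' fixed point when both the maximum step-to-step displacement
#' (max-norm) is below `eps_fp` and the largest per-neuron half-range is
#' below `eps_amp`; it is a limit cycle when the half-range exceeds
#' `eps_amp` and the autocorrelation of the first principal component
#' has a non-zero-lag local peak of at least `acf_peak`; any other tail
#' (e.g. a slow linear drift) is `none`. Periodicity is assessed on a
#' window three times the tail (periods up to ~15% of the trajectory are
#' detectable); the stationarity test stays on the tail proper.
#'
#' @param traj A `trajectory` (or a `T x N` state matrix).
#' @param eps_fp Fixed-point bound on the max-norm step displacement.
#' @param eps_amp Amplitude threshold separating stationary tails from
#'   oscillations.
#' @param tail_frac Fraction of the trajectory treated as the tail.
#' @param acf_peak Minimum autocorrelation at the candidate period.
#' @return An object of class `attractor_result`: `kind` in
#'   `c("fixed_point", "limit_cycle", "none")`, `x_star` (tail mean, for
#'   fixed points), `amplitude` (largest per-neuron half-range), and
#'   `period_steps` (for limit cycles).
#' @export
classify_asymptotic <- function(traj, eps_fp = 1e-4, eps_amp = 1e-2,
                                tail_frac = 0.1, acf_peak = 0.9) {
  X <- if (inherits(traj, "trajectory")) traj$x else as.matrix(traj)
  Tn <- nrow(X)
  i0 <- max(1L, Tn - max(4L, floor(Tn * tail_frac)) + 1L)
  tail_x <- X[i0:Tn, , drop = FALSE]
  stopifnot(nrow(tail_x) >= 4L)
  disp <- max(abs(diff(tail_x)))
  rng <- apply(tail_x, 2L, function(col) diff(range(col)))
  amplitude <- max(rng) / 2
  kind <- "none"
  x_star <- NULL
  period <- NA_real_
  if (disp < eps_fp && amplitude < eps_amp) {
    kind <- "fixed_point"
    x_star <- colMeans(tail_x)
  } else if (amplitude > eps_amp) {
    # longer window for periodicity: slow cycles can exceed the tail
    i1 <- max(1L, Tn - 3L * (Tn - i0 + 1L) + 1L)
    osc_x <- X[i1:Tn, , drop = FALSE]
    pc1 <- as.numeric(osc_x %*% prcomp(osc_x, center = TRUE)$rotation[, 1L])
    n <- length(pc1)
    max_lag <- n %/% 2L
    # unbiased lagged correlation (stats::acf's 1/n normalization caps
    # the value at (n - lag)/n, hiding genuine periodicity)
    ac <- vapply(seq_len(max_lag), function(k) {
      a <- pc1[seq_len(n - k)]
      b <- pc1[(k + 1L):n]
      if (sd(a) == 0 || sd(b) == 0) return(-Inf)
      stats::cor(a, b)
    }, numeric(1))
    # first interior local maximum reaching the peak bound; the
    # correlation must dip on the way there (a monotone drift keeps
    # lagged correlation near 1 at every lag and is not a cycle)
    if (max_lag >= 3L) {
      lags <- 2L:(max_lag - 1L)
      is_peak <- ac[lags] > ac[lags - 1L] & ac[lags] >= ac[lags + 1L] &
        ac[lags] >= acf_peak &
        vapply(lags, function(k) min(ac[1:k]) < acf_peak / 2, logical(1))
      if (any(is_peak)) {
        kind <- "limit_cycle"
        period <- lags[which(is_peak)[1L]]
      }
    }
  }
  structure(list(kind = kind, x_star = x_star, amplitude = amplitude,
                 period_steps = period, max_step_disp = disp),
            class = "attractor_result")
}

#' Fixed-point residual of the autonomous dynamics
#'
#' Max-norm of `-x + J_T tanh(x)`, zero exactly at a fixed point.
#'
#' @param net A `network_bundle`.
#' @param x State vector.
#' @return Scalar residual.
#' @export
fixed_point_residual <- function(net, x) {
  JT <- effective_connectivity(net)
  max(abs(-x + JT %*% tanh(x)))
}

# Trials run as one concatenated session (network state carries over
# from trial to trial, as during training); each trial is arrested at
# the requested moments and forward-simulated autonomously from there.
# The session itself continues from the unarrested trial end.
run_arrest_battery <- function(net, timing, model, n_real, arrests,
                               duration_multiplier, eps_fp, eps_amp,
                               warmup = 1L) {
  pairs <- all_digit_pairs(model$n_classes)
  x <- rep(0, net$params$N)
  for (w in seq_len(warmup)) {
    for (k in seq_len(nrow(pairs))) {
      tr <- build_trial(pairs$d1[k], pairs$d2[k], timing, model)
      traj <- simulate_network(net, tr$u, x)
      x <- traj$x[nrow(traj$x), ]
    }
  }
  rows <- list()
  for (real in seq_len(n_real)) {
    for (k in seq_len(nrow(pairs))) {
      tr <- build_trial(pairs$d1[k], pairs$d2[k], timing, model)
      traj <- simulate_network(net, tr$u, x)
      x <- traj$x[nrow(traj$x), ]
      arrest_steps <- c(delay1_end = max(tr$masks$delay1),
                        delay2_end = max(tr$masks$delay2),
                        trial_end = ncol(tr$u))[arrests]
      for (a in seq_along(arrest_steps)) {
        xa <- traj$x[arrest_steps[a], ]
        fs <- forward_simulate(net, xa, duration_multiplier, timing)
        res <- classify_asymptotic(fs, eps_fp, eps_amp)
        drift <- if (res$kind == "fixed_point")
          sqrt(sum((res$x_star - xa)^2)) else
          max(sqrt(rowSums(sweep(fs$x, 2L, xa)^2)))
        rows[[length(rows) + 1L]] <- list(
          d1 = pairs$d1[k], d2 = pairs$d2[k], realization = real,
          arrest = names(arrest_steps)[a], kind = res$kind,
          drift = drift, arrest_norm = sqrt(sum(xa^2)), result = res)
      }
    }
  }
  rows
}

#' Classify the working-memory mechanism of a trained network
#'
#' For every ordered digit pair and `n_real` stimulus realizations, the
#' trial is simulated (trials run as one concatenated session after a
#' warm-up pass, so each trial starts from the state the previous one
#' left, as during training), arrested at the end of the first delay,
#' and forward-simulated autonomously. The label follows the asymptotic
#' attractor kind and whether the delay-arrest state is itself the
#' fixed point reached, judged by the *relative* drift
#' `|x* - x(arrest)| / |x(arrest)|` (Euclidean norms):
#' all fixed points reached and every arrest state at one (relative
#' drift below `delta_mem`) gives `DFP`; all fixed points but arrest
#' from them gives `IFP`; all limit cycles gives `LC`; both kinds across
#' trials gives `Mix`. A network that failed to converge in training is
#' `UNTRAINABLE`. Trials whose tail is neither kind are excluded from
#' aggregation and flagged.
#'
#' @param net A trained `network_bundle`.
#' @param timing,model Task definition.
#' @param n_real Stimulus realizations per digit pair (>= 3 recommended).
#' @param duration_multiplier,eps_fp,eps_amp Passed to
#'   [forward_simulate()] / [classify_asymptotic()].
#' @param delta_mem Memory-coincidence bound on the relative drift
#'   between the arrest state and the asymptotic fixed point (default
#'   0.2: tonic states move by less than 20% of their own magnitude).
#' @param warmup Warm-up passes over the four digit pairs before the
#'   assayed trials (session initialization).
#' @return An object of class `mechanism_label`: `label` in
#'   `c("DFP", "IFP", "LC", "Mix", "UNTRAINABLE")`, per-trial `evidence`
#'   data frame (arrest drift and asymptotic kind), and a `warning_flag`
#'   when unclassified tails were dropped.
#' @export
classify_mechanism <- function(net, timing = trial_timing(),
                               model = stimulus_model(), n_real = 3L,
                               duration_multiplier = 10, eps_fp = 1e-4,
                               eps_amp = 1e-2, delta_mem = 0.2,
                               warmup = 1L) {
  if (!isTRUE(net$trained)) {
    return(structure(list(label = "UNTRAINABLE", evidence = NULL,
                          warning_flag = FALSE, delta_mem = delta_mem),
                     class = "mechanism_label"))
  }
  rows <- run_arrest_battery(net, timing, model, n_real, "delay1_end",
                             duration_multiplier, eps_fp, eps_amp, warmup)
  ev <- do.call(rbind, lapply(rows, function(z)
    data.frame(d1 = z$d1, d2 = z$d2, realization = z$realization,
               kind = z$kind, drift = z$drift,
               drift_rel = z$drift / max(z$arrest_norm, 1e-12))))
  warning_flag <- any(ev$kind == "none")
  if (warning_flag)
    warning("unclassified asymptotic tail on ", sum(ev$kind == "none"),
            " trial(s); excluded from aggregation")
  ok <- ev[ev$kind != "none", ]
  label <- if (nrow(ok) == 0L) {
    "UNTRAINABLE"
  } else if (all(ok$kind == "fixed_point")) {
    if (all(ok$drift_rel < delta_mem)) "DFP" else "IFP"
  } else if (all(ok$kind == "limit_cycle")) {
    "LC"
  } else {
    "Mix"
  }
  structure(list(label = label, evidence = ev, warning_flag = warning_flag,
                 delta_mem = delta_mem),
            class = "mechanism_label")
}

#' @export
print.mechanism_label <- function(x, ...) {
  cat(sprintf("<mechanism_label> %s\n", x$label))
  if (!is.null(x$evidence))
    print(table(kind = x$evidence$kind))
  invisible(x)
}

canonical_sign <- function(x_star) {
  if (sum(tanh(x_star)) < 0) -x_star else x_star
}

#' Discover the distinct task fixed points of a trained network
#'
#' Arrests every digit-pair trial at the end of each delay and at trial
#' end, forward-simulates autonomously, collects the fixed-point tails,
#' maps each to the positive-quadrant member of its mirror pair (the
#' odd activation makes `-x*` a fixed point whenever `x*` is), and
#' merges points closer than `cluster_radius` in max-norm.
#'
#' @inheritParams classify_mechanism
#' @param cluster_radius Max-norm merge radius for distinct points.
#' @param n_real Stimulus realizations per pair (default 1).
#' @return A list with `x_star` (`N x k` matrix of representatives),
#'   `count` (k), `sources` (evidence data frame), and `residuals`
#'   (max-norm autonomous-dynamics residual at each representative).
#' @export
find_task_fixed_points <- function(net, timing = trial_timing(),
                                   model = stimulus_model(),
                                   cluster_radius = 0.1, n_real = 1L,
                                   duration_multiplier = 10,
                                   eps_fp = 1e-4, eps_amp = 1e-2,
                                   warmup = 1L) {
  rows <- run_arrest_battery(net, timing, model, n_real,
                             c("delay1_end", "delay2_end", "trial_end"),
                             duration_multiplier, eps_fp, eps_amp, warmup)
  fps <- lapply(Filter(function(z) z$kind == "fixed_point", rows),
                function(z) canonical_sign(z$result$x_star))
  sources <- do.call(rbind, lapply(rows, function(z)
    data.frame(d1 = z$d1, d2 = z$d2, realization = z$realization,
               arrest = z$arrest, kind = z$kind)))
  if (length(fps) == 0L) {
    return(list(x_star = matrix(0, net$params$N, 0L), count = 0L,
                sources = sources, residuals = numeric(0)))
  }
  reps <- list(fps[[1L]])
  members <- c(1L)
  if (length(fps) > 1L) {
    for (i in 2L:length(fps)) {
      d <- vapply(reps, function(rp) max(abs(rp - fps[[i]])), numeric(1))
      if (min(d) < cluster_radius) {
        j <- which.min(d)
        # running mean keeps the representative centred in its cluster
        reps[[j]] <- (reps[[j]] * members[j] + fps[[i]]) / (members[j] + 1)
        members[j] <- members[j] + 1L
      } else {
        reps[[length(reps) + 1L]] <- fps[[i]]
        members <- c(members, 1L)
      }
    }
  }
  x_star <- do.call(cbind, reps)
  res <- vapply(seq_len(ncol(x_star)),
                function(j) fixed_point_residual(net, x_star[, j]),
                numeric(1))
  list(x_star = x_star, count = ncol(x_star), sources = sources,
       residuals = res)
}

#' Linearization at a state
#'
#' Returns `Q = J_T R'` with `R' = diag(1 - tanh(x)^2)` (the Jacobian of
#' the recurrent drive) and the full Jacobian of the autonomous dynamics
#' `-I + Q`. At the origin `R' = I` so `Q = J_T`; at strongly saturated
#' states `R'` is small and the spectrum of `Q` contracts.
#'
#' @param net A `network_bundle`.
#' @param x_star State at which to linearize.
#' @return `list(Q, jacobian, r_prime)`.
#' @export
jacobian_at <- function(net, x_star) {
  stopifnot(all(is.finite(x_star)), length(x_star) == net$params$N)
  JT <- effective_connectivity(net)
  rp <- 1 - tanh(x_star)^2
  Q <- JT * rep(rp, each = nrow(JT))  # column scaling: JT %*% diag(rp)
  list(Q = Q, jacobian = -diag(nrow(JT)) + Q, r_prime = rp)
}

#' Spectrum summary of a connectivity or Jacobian matrix
#'
#' Eigendecomposition with the observables used to compare mechanisms:
#' the largest real part, the number of outliers beyond the theoretical
#' disk (radius inflated by the finite-size band `1 + 3/sqrt(N)`), and
#' the number of slow eigenvalues, i.e. real parts inside `slow_band`
#' (meaningful when `m` is the full Jacobian `-I + Q`, whose slow modes
#' sit just left of the imaginary axis).
#'
#' @param m Square matrix.
#' @param radius Theoretical disk radius (use `g` for `J` or `J_T` at
#'   the origin).
#' @param slow_band Two numbers `(lo, hi)`; slow modes have
#'   `lo < Re(lambda) < hi`. Default `c(-0.1, 0)`.
#' @return An object of class `spectrum_summary` with `eigenvalues`,
#'   `lambda_max_re`, `n_outliers`, `n_slow`, `radius`.
#' @export
spectrum_summary <- function(m, radius, slow_band = c(-0.1, 0)) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  N <- nrow(m)
  ev <- eigen(m, only.values = TRUE)$values
  structure(list(
    eigenvalues = ev,
    lambda_max_re = max(Re(ev)),
    n_outliers = sum(Mod(ev) > radius * (1 + 3 / sqrt(N))),
    n_slow = sum(Re(ev) > slow_band[1L] & Re(ev) < slow_band[2L]),
    radius = radius, slow_band = slow_band, N = N),
    class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf(
    "<spectrum_summary> N = %d, lambda_max_re = %.4g, outliers = %d (radius %g), slow = %d\n",
    x$N, x$lambda_max_re, x$n_outliers, x$radius, x$n_slow))
  invisible(x)
}

#' Project trajectories and fixed points into a common PCA basis
#'
#' Fits principal components on the pooled, mean-centered rate vectors
#' of the supplied trajectories and projects each trajectory — and any
#' supplied fixed points (state vectors, mapped through `tanh` into rate
#' space) — into that basis.
#'
#' @param trajectories A list of `trajectory` objects (or `T x N` rate
#'   matrices).
#' @param n_components Number of components (default 3).
#' @param points Optional `N x k` matrix of state vectors (e.g. fixed
#'   points) to project.
#' @return A list with `coords` (list of `T x n_components` scores per
#'   trajectory), `points` (projected points, if given),
#'   `explained_variance` (ratios, non-increasing), and the fitted
#'   `center`/`rotation`.
#' @export
pca_project <- function(trajectories, n_components = 3L, points = NULL) {
  rates <- lapply(trajectories, function(tr)
    if (inherits(tr, "trajectory")) tr$r else as.matrix(tr))
  pooled <- do.call(rbind, rates)
  stopifnot(nrow(pooled) >= n_components)
  if (all(apply(pooled, 2L, function(col) diff(range(col))) == 0))
    stop("degenerate (constant) activity: PCA undefined")
  fit <- prcomp(pooled, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(fit$rotation))
  rot <- fit$rotation[, seq_len(n_components), drop = FALSE]
  coords <- lapply(rates, function(rr)
    sweep(rr, 2L, fit$center) %*% rot)
  pts <- NULL
  if (!is.null(points))
    pts <- t(sweep(tanh(as.matrix(points)), 1L, fit$center) ) %*% rot
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  list(coords = coords, points = pts,
       explained_variance = evr[seq_len(n_components)],
       center = fit$center, rotation = rot)
}
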