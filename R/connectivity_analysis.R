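#' Order neurons by the time of their peak activity
#'
#' Stable sort of neurons by the step at which `|r_i(t)|` attains its
#' maximum over the trial; ties keep the original neuron order.
#'
#' @param r A `T x N` rate matrix (or a `trajectory`).
#' @return An integer permutation of `1:N` (neuron indices in peak-time
#'   order).
#' @export
sort_by_peak <- function(r) {
  if (inherits(r, "trajectory")) r <- r$r
  stopifnot(is.matrix(r), nrow(r) >= 1L)
  peak <- apply(abs(r), 2L, which.max)
  order(peak, seq_along(peak))
}

#' Average presynaptic (incoming) weight per neuron
#'
#' Row means of the (optionally peak-sorted) effective connectivity:
#' `Jbar_i = sum_j J_T[i, j] / N`.
#'
#' @param J_T Effective connectivity matrix.
#' @param perm Optional neuron permutation from [sort_by_peak()]; rows
#'   and columns are permuted symmetrically before averaging.
#' @return Numeric vector of length `N`.
#' @export
presynaptic_average <- function(J_T, perm = NULL) {
  stopifnot(is.matrix(J_T), nrow(J_T) == ncol(J_T))
  if (!is.null(perm)) {
    stopifnot(length(perm) == nrow(J_T),
              all(sort(perm) == seq_len(nrow(J_T))))
    J_T <- J_T[perm, perm]
  }
  rowMeans(J_T)
}

#' Coupling strength versus temporal distance
#'
#' On a peak-sorted connectivity matrix, the mean and variance of all
#' entries at index distance `|i - j| = c` (both triangles pooled), for
#' `c = 0, ..., N-1`. A near-diagonal peak indicates that temporally
#' adjacent neurons are more tightly coupled (a sequential, daisy-chain
#' structure).
#'
#' @param J_T_sorted Square matrix, rows/columns already in peak order
#'   (see [sort_by_peak()], [presynaptic_average()]).
#' @return A data frame with columns `distance`, `mean`, `var` (`var` is
#'   `NA` where only one entry exists).
#' @export
temporal_distance_coupling <- function(J_T_sorted) {
  stopifnot(is.matrix(J_T_sorted), nrow(J_T_sorted) == ncol(J_T_sorted))
  N <- nrow(J_T_sorted)
  out <- lapply(0:(N - 1L), function(cc) {
    if (cc == 0L) {
      vals <- diag(J_T_sorted)
    } else {
      i <- seq_len(N - cc)
      vals <- c(J_T_sorted[cbind(i, i + cc)],  # superdiagonal j - i = c
                J_T_sorted[cbind(i + cc, i)])  # subdiagonal   i - j = c
    }
    c(mean = mean(vals),
      var = if (length(vals) > 1L) var(vals) else NA_real_)
  })
  out <- do.call(rbind, out)
  data.frame(distance = 0:(N - 1L), mean = out[, "mean"],
             var = out[, "var"])
}

#' Fraction of saturated delay-period activity
#'
#' The proportion of (neuron, step) samples inside the delay epochs
#' whose rate magnitude exceeds `sat_threshold` (i.e. sits in the flat
#' range of `tanh`), averaged over trials. High values indicate tonic,
#' saturated memory activity (DFP); low values indicate lightly
#' saturated, phasic activity (IFP).
#'
#' @param trajectories A `trajectory` or list of them (one per trial).
#' @param masks Delay step indices: an integer vector or a list of
#'   vectors (e.g. `trial$masks[c("delay1", "delay2")]`).
#' @param sat_threshold Saturation bound on `|r|` (default 0.9,
#'   equivalently `|x| > atanh(0.9) ~ 1.47`).
#' @return Fraction in `[0, 1]`.
#' @export
saturation_ratio <- function(trajectories, masks, sat_threshold = 0.9) {
  if (inherits(trajectories, "trajectory"))
    trajectories <- list(trajectories)
  steps <- sort(unique(unlist(masks)))
  stopifnot(length(steps) > 0L)
  per_trial <- vapply(trajectories, function(tr) {
    r <- if (is.list(tr)) tr$r else as.matrix(tr)
    mean(abs(r[steps, , drop = FALSE]) > sat_threshold)
  }, numeric(1))
  mean(per_trial)
}

#' Weight histograms before and after training
#'
#' Histograms of the entries of `J` and `J_T` on a shared set of break
#' points; each histogram's counts sum to `N^2`.
#'
#' @param net A `network_bundle`.
#' @param bins Number of bins.
#' @return A list with `breaks`, `before` and `after` counts, and
#'   `mids`.
#' @export
weight_histograms <- function(net, bins = 100L) {
  JT <- effective_connectivity(net)
  rng <- range(net$J, JT)
  breaks <- seq(rng[1L] - 1e-12, rng[2L] + 1e-12, length.out = bins + 1L)
  h0 <- hist(net$J, breaks = breaks, plot = FALSE)
  h1 <- hist(JT, breaks = breaks, plot = FALSE)
  list(breaks = breaks, mids = h0$mids, before = h0$counts,
       after = h1$counts)
}

#' Connectivity statistics of a trained network over one trial
#'
#' Convenience wrapper producing the full structural characterization:
#' weight histograms, peak-activation ordering, presynaptic averages in
#' peak order, temporal-distance band statistics, and the delay-period
#' saturation ratio for the supplied trial.
#'
#' @param net A trained `network_bundle`.
#' @param trial A [build_trial()] object.
#' @param sat_threshold Passed to [saturation_ratio()].
#' @param bins Passed to [weight_histograms()].
#' @return An object of class `connectivity_stats`.
#' @export
connectivity_stats <- function(net, trial, sat_threshold = 0.9,
                               bins = 100L) {
  traj <- simulate_network(net, trial$u)
  perm <- sort_by_peak(traj)
  JT <- effective_connectivity(net)
  JTs <- JT[perm, perm]
  structure(list(
    hist = weight_histograms(net, bins),
    perm = perm,
    presyn_avg = rowMeans(JTs),
    bands = temporal_distance_coupling(JTs),
    saturation = saturation_ratio(traj, trial$masks[c("delay1", "delay2")],
                                  sat_threshold),
    sat_threshold = sat_threshold),
    class = "connectivity_stats")
}

#' @export
print.connectivity_stats <- function(x, ...) {
  cat(sprintf(
    "<connectivity_stats> N = %d, saturation ratio %.3f (|r| > %g)\n",
    length(x$presyn_avg), x$saturation, x$sat_threshold))
  invisible(x)
}
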