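---
title: "Working-memory mechanisms in FORCE-trained rate networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working-memory mechanisms in FORCE-trained rate networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Working memory requires a neural circuit to hold a latent representation of
a past stimulus across a delay and use it later. Two qualitatively
different delay-activity profiles are seen in cortex and in models: tonic
(persistent elevated firing) and phasic (transient, ramping on and off).
`wmforce` implements a top-down route to studying which circuit dynamics
produce each profile: train recurrent rate networks on a working-memory
task, then dissect the trained network's attractor landscape with
dynamical-systems tools.

The package covers the full pipeline:

1. a **sequential pattern-matching (SPM) task** generator,
2. a **rank-3-perturbed random rate network** simulator,
3. a **temporally restricted FORCE trainer** (recursive least squares
   confined to delay/response epochs, with readout feedback),
4. **attractor analysis** (fixed points, limit cycles, mechanism labels,
   Jacobian spectra, PCA projections),
5. **connectivity analysis** of the trained weights, and
6. **functional experiments**: extended delays, distractor noise, and
   initialization-parameter sweeps.

# Task

A trial is `stimulus 1 (100 steps) - delay 1 (50) - stimulus 2 (100) -
delay 2 (50) - response (50)` at Euler step `dt = 0.1` (350 steps, 35 time
units with `tau = 1`). Each stimulus is a two-dimensional Gaussian process:
independent bivariate Gaussian draws per step around a class mean. The two
classes stand in for latent codes of two digit categories; the network must
report the *sum* of the two class labels (outcomes 0, 1, 2 encoded as
output targets 0.5, 1.0, 1.5) during the response window, and must hold a
latent two-vector equal to the class mean of the preceding stimulus during
each delay.

## Stimulus statistics (synthetic-data choices)

The latent class statistics of the original digit encoder are not public;
the generator's defaults are an explicit configuration:
`mu0 = (0.5, 1.0)`, `mu1 = (1.0, 0.5)`, per-step standard deviation 0.3 in
each dimension. The means are positive and well separated so that trained
activity lives in the positive quadrant (which the sign convention of the
fixed-point analysis exploits), and a noise-to-separation ratio of about
0.3/0.7 makes single-step class identity ambiguous — the network must
integrate the stimulus over time, which is the point of the task. The
process is white in time; temporal correlations of real encoder latents
are deliberately not modeled. Consequences for interpreting results: tests
passing under this generator demonstrate the mechanism-level claims
(trainability, attractor structure, robustness orderings), not performance
on any real digit data.

# Network model and trainer

The network is `tau dx/dt = -x + J_T r + W_i u`, `r = tanh(x)`, with
`J_T = J + W_f W_o^T + W_fd W_d^T`. `J` is i.i.d. Gaussian with variance
`g^2/N` (spectral radius `g` by the circular law), optionally sparsified by
an i.i.d. Bernoulli mask with no variance rescaling (so the realized radius
is about `g sqrt(1 - s)`; sparsity has no qualitative effect, and the naive
masking is the minimal reading of "sparsity of the initial connectivity").
Readouts `z_o = W_o^T r` (task output) and `z_d = W_d^T r` (latent memory)
are fed back through fixed Gaussian weights `W_f`, `W_fd` of variance
`sigma_f2`, making the trained connectivity a rank-3 perturbation of `J`.

Training is FORCE with a **temporally restricted error kernel**: recursive
least squares (regularization `alpha = 1`, `P` initialized to the
identity) updates `W_d` only during delays and `W_o` only during the
response, every 2nd kernel step; all other epochs are unconstrained. Both
columns of `W_d` share one inverse-correlation matrix `P_d` accumulated
over delay steps; `W_o` has its own `P_o` over response steps. The weight
step uses the post-update `P` (standard RLS), which makes one full pass
over a batch land exactly on the ridge-regression solution — a property
the test suite checks against a closed-form oracle.

## Epoch structure and termination

The update rule, its cadence, and the termination bound (average RMSE
< 0.01 for all trials, frozen weights) are fixed parts of the method; the
trial ordering is not, and is a package choice: an epoch cycles the four
ordered digit pairs with fresh stimulus noise; network state carries over
from trial to trial (a continuous session of concatenated trials);
validation runs first in each epoch (one frozen trial per pair), so an
already-converged network stops after a single evaluation with its weights
untouched. RMSE is computed where targets exist: over both delays for
`z_d` (pooled across steps and components) and over the response for
`z_o`, then averaged.

Because validation trials are stochastic, the termination rule is a
first-passage event once the frozen-weight error plateaus near the bound.
At `N = 1000` (the nominal scale) the plateau sits below 0.01; at the
scaled-down sizes used in this package's tests the plateau is close to the
bound and more epochs are needed before every trial of an epoch clears it
simultaneously, which is why `max_epochs` defaults to 500.

# Attractor analysis

**Forward simulation.** Analyses freeze the weights, arrest a trial at a
moment of interest (end of delay 1, end of delay 2, trial end) and
integrate autonomously (`u = 0`) for 10 nominal trial lengths, after which
the state is taken to be within its stationary regime.

**Tail classification.** On the final 10% of the horizon: a *fixed point*
requires the max-norm step-to-step displacement below `eps_fp = 1e-4` and
the largest per-neuron half-range below `eps_amp = 1e-2`; a *limit cycle*
requires half-range above `eps_amp` plus a non-zero-lag peak of at least
0.9 in the lagged autocorrelation of the tail's first principal component.
The autocorrelation is the unbiased lagged Pearson correlation (the
conventional 1/n-normalized estimator is bounded by `(n - lag)/n` and
cannot reach 0.9 at long lags even for a perfect cycle), and a candidate
peak counts only if the correlation dips below half the peak bound at some
shorter lag — a monotone slow drift correlates near 1 at every lag and
must not be read as a cycle. Anything else is `none` and is excluded (with
a warning flag) from mechanism aggregation. These numeric tolerances are
package choices (the stationarity criterion itself only requires *some*
epsilon) and all are exposed as arguments.

**Mechanism labels.** Per trial, the state at the end of delay 1 is the
memory representation. If every forward simulation lands on a fixed point
and every arrest state already sits at one (Euclidean drift below
`delta_mem`), memories coincide with attractors: direct fixed-point
encoding (DFP, tonic activity). If all asymptotic sets are fixed points
but arrest states are away from them, memories are held in passing, along
slow stable manifolds: indirect encoding (IFP, phasic activity). All limit
cycles: LC; both kinds across trials: Mix; a network that failed training:
UNTRAINABLE. The coincidence bound `delta_mem` is *relative*: the drift
`|x* - x(arrest)|` is compared with `delta_mem * |x(arrest)|` (default
0.2), so "the state stays where it was" means it moves by less than 20%
of its own magnitude. An absolute bound was evaluated and rejected: the
drift scale of tonic (saturated) states grows with `N` and with activity
level, and trained tonic networks sit one order of magnitude below 0.2
while phasic ones sit well above it, making the relative criterion the
stable discriminator across network sizes.

**Fixed-point census.** Because the activation is odd and input is zero,
`-x*` is a fixed point whenever `x*` is; discovered points are mapped to
the mirror member with positive summed rate (the task operates in the
positive quadrant) and merged within a max-norm radius of 0.1. The number
of distinct survivors is the "attractors deployed in the service of the
task": 4 for a typical DFP network (two memory points, output points),
1 for IFP.

**Spectra.** `jacobian_at` returns `Q = J_T diag(1 - tanh^2 x*)` and the
full Jacobian `-I + Q`. Outliers are eigenvalues with modulus beyond the
theoretical radius inflated by `1 + 3/sqrt(N)` (a finite-size band);
"slow" modes are full-Jacobian eigenvalues with real part in `(-0.1, 0)`,
operationalizing "near the imaginary axis". Both matrices are exposed so either convention
for plotting spectra (with or without the `-I` shift) is available.

# Experiments

Perturbation assays run a battery (ordered pairs x realizations) as a
concatenated session, recording each trial's entry state; the perturbed
variant of trial *i* starts from the same entry state with the same
stimulus realizations, so the measured deviation is attributable to the
perturbation alone. The extended-delay assay lengthens delay 1 by a factor
of the nominal delay (the memory-demand probe); the noise assay adds
i.i.d. Gaussian distractor noise to stimulus 1 only. Both report the mean
squared deviation of the response-window output from the unperturbed run
and the fraction of trials decoding to the correct outcome
(nearest-target decoding of the mean output). The parameter sweep trains
one network per `(g, sigma_f2, sparsity, seed)` cell and aggregates
trainable fractions and mechanism counts.

# Numerical and scale choices

- Forward Euler with `dt = 0.1`, `tau = 1`; no adaptive stepping (the test
  suite bounds the Euler error against an adaptive integrator on small
  networks).
- All randomness flows through R's RNG; compiled code is deterministic.
  `set.seed` plus the `seed` field of `network_params` reproduce training
  bit-for-bit.
- Problem sizes: the package's tests and the acceptance script use
  networks of `N = 300`–`500` and reduced sweeps (dozens of runs), chosen
  to keep a full run on a single CPU in the tens of minutes while
  preserving every qualitative contrast; the nominal scale of the original
  study (`N = 1000`, thousands of runs) is available through the same API.
- Exemplar initializations keep their nominal parameter values at
  scaled-down `N` (e.g. the DFP exemplar's `sigma_f2 = 1`). Rescaling
  `sigma_f2` upward along its `1/(c N)` ladder to compensate for smaller
  `N` was evaluated and rejected: stronger feedback variance degrades
  trainability at small `N` without changing the emergent mechanism.

# Known limitations

- The VAE/digit encoder is out of scope; stimulus statistics are
  configuration, not estimates.
- Mechanism classification is operational, not topological: it inherits
  the finite horizon, the tail tolerances and `delta_mem`. Nets whose
  slowest modes decay on timescales beyond 10 trial lengths can be
  misread; lengthen `duration_multiplier` in that case.
- No training of `J`, `W_i`, `W_f`, `W_fd`; no gradient-based
  alternatives; no time-varying synapses; match/non-match task variants
  are not implemented.

# A worked example

```{r, eval = FALSE}
library(wmforce)

set.seed(1)
params <- network_params(N = 500, g = 0.9, sigma_f2 = 0.05,
                         sparsity = 0.1, seed = 1)
fit <- train_network(init_network(params))
fit$log

set.seed(2)
label <- classify_mechanism(fit$net)
label

set.seed(3)
fps <- find_task_fixed_points(fit$net)
fps$count

set.seed(4)
curve <- extended_delay_experiment(fit$net,
                                   factors = c(0.25, 0.5, 1, 2))
curve
```
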