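#' Trial timing for the sequential pattern-matching task
#'
#' A trial is stimulus 1, delay 1, stimulus 2, delay 2, response, in that
#' order. Durations are in integration steps; physical time is
#' `step * dt`. Defaults follow the nominal task: 100-step stimuli,
#' 50-step delays, 50-step response, Euler step `dt = 0.1`.
#'
#' @param stim_len Stimulus interval length in steps.
#' @param delay_len Delay interval length in steps.
#' @param response_len Response interval length in steps.
#' @param dt Euler integration step (dimensionless time).
#' @return An object of class `trial_timing`.
#' @export
#' @examples
#' tm <- trial_timing()
#' trial_length(tm) # 350
trial_timing <- function(stim_len = 100L, delay_len = 50L,
                         response_len = 50L, dt = 0.1) {
  stim_len <- as.integer(stim_len)
  delay_len <- as.integer(delay_len)
  response_len <- as.integer(response_len)
  stopifnot(stim_len >= 1L, delay_len >= 1L, response_len >= 1L, dt > 0)
  structure(list(stim_len = stim_len, delay_len = delay_len,
                 response_len = response_len, dt = dt),
            class = "trial_timing")
}

#' Total trial length in steps
#'
#' @param timing A [trial_timing()] object.
#' @param delay1_len,delay2_len Optional per-delay overrides (used by the
#'   extended-delay experiments); default the nominal delay length.
#' @return Integer step count `2 * stim_len + delay1 + delay2 + response_len`.
#' @export
trial_length <- function(timing, delay1_len = timing$delay_len,
                         delay2_len = timing$delay_len) {
  2L * timing$stim_len + as.integer(delay1_len) + as.integer(delay2_len) +
    timing$response_len
}

#' Epoch step-index masks for one trial
#'
#' Epoch boundaries are half-open step ranges laid head to tail; the
#' returned components are 1-based step indices into the trial.
#'
#' @inheritParams trial_length
#' @return A list with integer vectors `stim1`, `delay1`, `stim2`,
#'   `delay2`, `response`.
#' @export
epoch_masks <- function(timing, delay1_len = timing$delay_len,
                        delay2_len = timing$delay_len) {
  d1 <- as.integer(delay1_len)
  d2 <- as.integer(delay2_len)
  stopifnot(d1 >= 1L, d2 >= 1L)
  s <- timing$stim_len
  bounds <- cumsum(c(0L, s, d1, s, d2, timing$response_len))
  masks <- lapply(seq_len(5L), function(k) (bounds[k] + 1L):bounds[k + 1L])
  names(masks) <- c("stim1", "delay1", "stim2", "delay2", "response")
  masks
}

#' Class-conditioned stimulus model
#'
#' Each stimulus is a two-dimensional Gaussian process around a per-class
#' mean vector: independent bivariate Gaussian draws at every step (white
#' in time). The class means and per-step standard deviations emulate the
#' latent-space statistics of a digit encoder; defaults place the two
#' classes at distinct points of the positive quadrant.
#'
#' @param class_means Numeric matrix, one row per class, two columns
#'   (latent units, dimensionless).
#' @param class_stds Numeric matrix of matching shape with per-step,
#'   per-dimension standard deviations.
#' @return An object of class `stimulus_model`.
#' @export
#' @examples
#' sm <- stimulus_model()
#' sm$class_means
stimulus_model <- function(class_means = rbind(c(0.5, 1.0), c(1.0, 0.5)),
                           class_stds = matrix(0.3, nrow(class_means), 2L)) {
  class_means <- as.matrix(class_means)
  class_stds <- as.matrix(class_stds)
  stopifnot(ncol(class_means) == 2L, nrow(class_means) >= 2L,
            all(dim(class_stds) == dim(class_means)),
            all(class_stds >= 0))
  d <- as.matrix(stats::dist(class_means))
  if (any(d[upper.tri(d)] == 0))
    stop("class means must be pairwise distinct")
  structure(list(class_means = class_means, class_stds = class_stds,
                 n_classes = nrow(class_means)),
            class = "stimulus_model")
}

#' Sample one class-conditioned stimulus segment
#'
#' Draws a 2 x `length` series whose steps are independent bivariate
#' Gaussians with the class mean and standard deviation of `digit`.
#' Uses the ambient R random stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param digit Class index in `0:(n_classes - 1)`.
#' @param length Number of steps (>= 1).
#' @param model A [stimulus_model()].
#' @return A `2 x length` numeric matrix.
#' @export
sample_stimulus <- function(digit, length, model = stimulus_model()) {
  if (length(digit) != 1L || is.na(digit) ||
      !(digit %in% (seq_len(model$n_classes) - 1L)))
    stop("unknown class index: ", digit)
  stopifnot(length >= 1L)
  mu <- model$class_means[digit + 1L, ]
  sdv <- model$class_stds[digit + 1L, ]
  rbind(rnorm(length, mu[1L], sdv[1L]),
        rnorm(length, mu[2L], sdv[2L]))
}

#' Map a summation outcome to its scalar output target
#'
#' Outcomes 0, 1, 2 are encoded as output targets 0.5, 1.0, 1.5.
#'
#' @param outcome Integer outcome(s) in `{0, 1, 2}`.
#' @return Numeric target value(s).
#' @export
outcome_target <- function(outcome) {
  stopifnot(all(outcome %in% 0:2))
  c(0.5, 1.0, 1.5)[outcome + 1L]
}

#' Build one sequential pattern-matching trial
#'
#' Assembles the input series (stimulus epochs carry class-conditioned
#' noise, all other epochs are zero), the delay/response masks of the
#' temporally restricted error kernel, the latent targets (the class mean
#' of the digit presented just before each delay), and the scalar output
#' target encoding the digit sum.
#'
#' @param d1,d2 Class indices of the first and second stimulus.
#' @param timing A [trial_timing()].
#' @param model A [stimulus_model()].
#' @param delay1_len,delay2_len Optional delay-length overrides in steps
#'   (extended-delay experiments).
#' @param stimuli Optional list with precomputed `s1`, `s2` stimulus
#'   matrices (2 x stim_len); when supplied no stimulus noise is drawn,
#'   which lets perturbation experiments reuse identical realizations.
#' @return An object of class `trial` with elements `u` (2 x T input),
#'   `labels`, `masks` (`delay1`, `delay2`, `response`), `epochs` (all
#'   five epochs), `f_d1`, `f_d2`, `f_o`, `outcome`, `timing`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- build_trial(0, 1)
#' tr$outcome # 1
#' tr$f_o     # 1.0
build_trial <- function(d1, d2, timing = trial_timing(),
                        model = stimulus_model(),
                        delay1_len = timing$delay_len,
                        delay2_len = timing$delay_len,
                        stimuli = NULL) {
  ep <- epoch_masks(timing, delay1_len, delay2_len)
  Ttot <- trial_length(timing, delay1_len, delay2_len)
  if (is.null(stimuli)) {
    s1 <- sample_stimulus(d1, timing$stim_len, model)
    s2 <- sample_stimulus(d2, timing$stim_len, model)
  } else {
    s1 <- stimuli$s1
    s2 <- stimuli$s2
    stopifnot(ncol(s1) == timing$stim_len, ncol(s2) == timing$stim_len)
  }
  u <- matrix(0, 2L, Ttot)
  u[, ep$stim1] <- s1
  u[, ep$stim2] <- s2
  outcome <- d1 + d2
  structure(list(
    u = u,
    labels = c(d1 = d1, d2 = d2),
    masks = list(delay1 = ep$delay1, delay2 = ep$delay2,
                 response = ep$response),
    epochs = ep,
    f_d1 = model$class_means[d1 + 1L, ],
    f_d2 = model$class_means[d2 + 1L, ],
    f_o = outcome_target(outcome),
    outcome = outcome,
    timing = timing
  ), class = "trial")
}

#' Decode the task outcome from the response-window output
#'
#' Averages the scalar output over the response window and returns the
#' outcome whose target is nearest (ties resolve to the smaller outcome).
#'
#' @param z_o Numeric vector: network output over the response window.
#' @param targets Output encoding of outcomes `0:(length(targets)-1)`.
#' @return Integer predicted outcome.
#' @export
#' @examples
#' decode_outcome(rep(1.5, 10)) # 2
#' decode_outcome(rep(0.74, 10)) # 0
decode_outcome <- function(z_o, targets = c(0.5, 1.0, 1.5)) {
  if (length(z_o) == 0L) stop("empty response window")
  which.min(abs(mean(z_o) - targets)) - 1L
}

#' Tabulate a trial as a columnar data frame
#'
#' One row per step with the input, the epoch label, and the targets
#' active at that step (`NA` outside the error kernel), suitable for
#' writing to CSV.
#'
#' @param x A [build_trial()] object.
#' @param row.names,optional,... Passed over for S3 compatibility; unused.
#' @return A `data.frame` with columns `step`, `u1`, `u2`, `epoch`,
#'   `fd1`, `fd2`, `fo`.
#' @export
as.data.frame.trial <- function(x, row.names = NULL, optional = FALSE, ...) {
  Ttot <- ncol(x$u)
  epoch <- character(Ttot)
  for (nm in names(x$epochs)) epoch[x$epochs[[nm]]] <- nm
  fd1 <- fd2 <- fo <- rep(NA_real_, Ttot)
  fd1[x$masks$delay1] <- x$f_d1[1L]
  fd2[x$masks$delay1] <- x$f_d1[2L]
  fd1[x$masks$delay2] <- x$f_d2[1L]
  fd2[x$masks$delay2] <- x$f_d2[2L]
  fo[x$masks$response] <- x$f_o
  data.frame(step = seq_len(Ttot), u1 = x$u[1L, ], u2 = x$u[2L, ],
             epoch = epoch, fd1 = fd1, fd2 = fd2, fo = fo)
}

#' Read or write a task configuration file
#'
#' The configuration is a YAML file with `timing` (stim_len, delay_len,
#' response_len, dt) and `stimulus` (class_means, class_stds) blocks.
#'
#' @param path File path.
#' @return `read_task_config()` returns `list(timing, model)`;
#'   `write_task_config()` returns `path` invisibly.
#' @export
#' @examples
#' cfg <- read_task_config(system.file("extdata", "default_task.yaml",
#'                                     package = "wmforce"))
#' cfg$timing$stim_len
read_task_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  timing <- do.call(trial_timing, cfg$timing)
  model <- stimulus_model(
    class_means = do.call(rbind, cfg$stimulus$class_means),
    class_stds = do.call(rbind, cfg$stimulus$class_stds))
  list(timing = timing, model = model)
}

#' @rdname read_task_config
#' @param timing A [trial_timing()].
#' @param model A [stimulus_model()].
#' @export
write_task_config <- function(path, timing = trial_timing(),
                              model = stimulus_model()) {
  cfg <- list(
    timing = list(stim_len = timing$stim_len, delay_len = timing$delay_len,
                  response_len = timing$response_len, dt = timing$dt),
    stimulus = list(
      class_means = lapply(seq_len(model$n_classes),
                           function(i) as.numeric(model$class_means[i, ])),
      class_stds = lapply(seq_len(model$n_classes),
                          function(i) as.numeric(model$class_stds[i, ]))))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
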