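test_that("subcritical untrained networks relax to the origin", {
  net <- tiny_net(N = 50, g = 0.8, seed = 1)
  traj <- forward_simulate(net, rnorm(50, 0, 0.1))
  expect_equal(nrow(traj$x), 3500L)  # 10 x nominal trial length
  expect_lt(max(abs(traj$x[nrow(traj$x), ])), 1e-3)
  res <- classify_asymptotic(traj)
  expect_equal(res$kind, "fixed_point")
  expect_lt(max(abs(res$x_star)), 1e-3)
})

test_that("tail classification separates constant, periodic, drifting", {
  Tn <- 2000L
  # constant tail
  cst <- matrix(rep(c(0.4, -0.7), each = Tn), Tn, 2)
  res <- classify_asymptotic(cst)
  expect_equal(res$kind, "fixed_point")
  expect_equal(res$x_star, c(0.4, -0.7))

  # synthetic oscillation with phase spread across units
  omega <- 2 * pi / 40
  phases <- seq(0, pi, length.out = 5)
  osc <- sapply(phases, function(ph) sin(omega * seq_len(Tn) + ph))
  res <- classify_asymptotic(osc)
  expect_equal(res$kind, "limit_cycle")
  expect_equal(res$period_steps, 40, tolerance = 0.05)
  expect_gt(res$amplitude, 0.9)

  # slow linear drift: neither
  drift <- matrix(seq_len(Tn) * 1e-3, Tn, 1)
  expect_equal(classify_asymptotic(drift)$kind, "none")
})

test_that("a planar supercritical rotation settles on a limit cycle", {
  net <- tiny_net(N = 2, g = 0.5, seed = 2)
  net$J <- rbind(c(1.2, -2), c(2, 1.2))
  net$W_f[] <- 0
  net$W_fd[] <- 0
  traj <- forward_simulate(net, c(0.1, 0))
  res <- classify_asymptotic(traj)
  expect_equal(res$kind, "limit_cycle")
  expect_gt(res$amplitude, 0.1)
  expect_false(is.na(res$period_steps))
})

test_that("the linearization matches a finite-difference Jacobian", {
  net <- tiny_net(N = 10, g = 0.9, seed = 3)
  net$W_o <- matrix(rnorm(10, 0, 0.3), 10, 1)
  net$W_d <- matrix(rnorm(20, 0, 0.3), 10, 2)
  x_star <- rnorm(10, 0, 0.8)
  jac <- jacobian_at(net, x_star)
  JT <- effective_connectivity(net)
  f <- function(x) -x + JT %*% tanh(x)
  h <- 1e-6
  fd <- sapply(seq_len(10), function(j) {
    e <- numeric(10)
    e[j] <- h
    (f(x_star + e) - f(x_star - e)) / (2 * h)
  })
  expect_lt(max(abs(jac$jacobian - fd)), 1e-5)
  # at the origin Q reduces to J_T
  expect_equal(jacobian_at(net, rep(0, 10))$Q, JT)
})

test_that("saturation contracts the spectrum of Q", {
  net <- tiny_net(N = 40, g = 1.1, seed = 4)
  rad <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))
  r0 <- rad(jacobian_at(net, rep(0, 40))$Q)
  rsat <- rad(jacobian_at(net, rnorm(40, 0, 10))$Q)
  expect_lt(rsat, r0)
  # deeply saturated states give a nearly vanishing Q
  expect_lt(rad(jacobian_at(net, rep(50, 40))$Q), 1e-10)
})

test_that("spectrum summary counts outliers and slow modes", {
  expect_equal(spectrum_summary(diag(20), radius = 0.5)$n_outliers, 20L)
  net <- init_network(network_params(N = 500, g = 0.9, sigma_f2 = 0.05,
                                     sparsity = 0, seed = 5))
  ss <- spectrum_summary(net$J, radius = 0.9)
  expect_equal(ss$n_outliers, 0L)
  expect_lt(ss$lambda_max_re, 1)
  # slow band counts real parts in (lo, 0) of the supplied matrix
  m <- diag(c(-0.05, -0.5, -0.01, 0.2))
  expect_equal(spectrum_summary(m, radius = 1)$n_slow, 2L)
})

test_that("PCA projection reports ordered variance and recovers rank", {
  set.seed(6)
  basis <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
  scores <- matrix(rnorm(400), 200, 2) %*% t(basis)
  p <- pca_project(list(scores), n_components = 3)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-8)
  expect_gte(sum(p$explained_variance[1:2]), 0.999)
  expect_error(pca_project(list(matrix(1, 50, 4))), "degenerate")
})

test_that("untrained networks classify as UNTRAINABLE", {
  net <- tiny_net(N = 20, seed = 7)
  lab <- classify_mechanism(net)
  expect_equal(lab$label, "UNTRAINABLE")
})

test_that("a saturating multistable surrogate classifies as DFP", {
  # strong self-excitation pins every arrest state at a nearby stable
  # corner fixed point, the signature of direct encoding
  net <- tiny_net(N = 30, g = 0.5, seed = 8)
  net$J <- diag(30) * 2
  net$W_f[] <- 0
  net$W_fd[] <- 0
  net$trained <- TRUE
  set.seed(8)
  lab <- classify_mechanism(net, n_real = 2)
  expect_equal(lab$label, "DFP")
  expect_true(all(lab$evidence$kind == "fixed_point"))
})

test_that("a leaky surrogate with one global fixed point classifies IFP", {
  # slow subcritical recurrence with strong input drive: arrest states
  # are far from the origin but decay to it, so memories cannot
  # coincide with the attractor
  net <- tiny_net(N = 30, g = 0.97, seed = 9)
  net$W_i <- net$W_i * 8
  net$trained <- TRUE
  set.seed(9)
  lab <- classify_mechanism(net, n_real = 2)
  expect_equal(lab$label, "IFP")
  expect_true(all(lab$evidence$drift > lab$delta_mem))
})

test_that("mechanism classification is deterministic given the seed", {
  net <- tiny_net(N = 25, g = 0.7, seed = 10)
  net$trained <- TRUE
  set.seed(42)
  a <- classify_mechanism(net, n_real = 2)
  set.seed(42)
  b <- classify_mechanism(net, n_real = 2)
  expect_identical(a$label, b$label)
  expect_identical(a$evidence, b$evidence)
})

test_that("fixed-point discovery merges mirrors and clusters", {
  # the multistable surrogate has corner fixed points; discovery should
  # return a small positive-quadrant set with tiny residuals
  net <- tiny_net(N = 20, g = 0.5, seed = 11)
  net$J <- diag(20) * 2
  net$W_f[] <- 0
  net$W_fd[] <- 0
  net$trained <- TRUE
  set.seed(11)
  fps <- find_task_fixed_points(net)
  expect_gt(fps$count, 0)
  for (j in seq_len(fps$count)) {
    expect_lt(fps$residuals[j], 1e-3)
    # mirror symmetry: -x* is a fixed point too
    expect_lt(fixed_point_residual(net, -fps$x_star[, j]), 1e-3)
    # canonical representative lies in the positive activity quadrant
    expect_gt(sum(tanh(fps$x_star[, j])), 0)
  }
})
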