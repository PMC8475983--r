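test_that("RLS with zero error updates P but leaves W unchanged", {
  set.seed(1)
  P <- crossprod(matrix(rnorm(16), 4))
  W <- rnorm(4)
  r <- rnorm(4)
  out <- rls_update(W, P, r, 0)
  expect_equal(out$W, matrix(W, 4, 1), ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(out$P, P)))
})

test_that("the P update is the Sherman-Morrison rank-one inverse", {
  set.seed(2)
  P <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  r <- rnorm(4)
  out <- rls_update(rep(0, 4), P, r, 0.3)
  expect_equal(out$P, solve(solve(P) + tcrossprod(r)), tolerance = 1e-10)
  # symmetry is preserved exactly up to round-off
  expect_lt(max(abs(out$P - t(out$P))), 1e-12)
})

test_that("a full RLS pass lands on the ridge-regression solution", {
  set.seed(3)
  n_feat <- 4L
  n_obs <- 50L
  R <- matrix(rnorm(n_feat * n_obs), n_feat, n_obs)
  y <- rnorm(n_obs)
  alpha <- 1
  rls_passes <- function(passes) {
    W <- rep(0, n_feat)
    P <- diag(n_feat) / alpha
    for (p in seq_len(passes)) {
      for (k in seq_len(n_obs)) {
        e <- sum(W * R[, k]) - y[k]
        out <- rls_update(W, P, R[, k], e)
        W <- out$W[, 1]
        P <- out$P
      }
    }
    W
  }
  ridge <- function(copies) {
    solve(copies * tcrossprod(R) + alpha * diag(n_feat),
          copies * (R %*% y))[, 1]
  }
  expect_equal(rls_passes(1), ridge(1), tolerance = 1e-6)
  # further passes equal ridge over the duplicated sample
  expect_equal(rls_passes(3), ridge(3), tolerance = 1e-6)
})

test_that("no weight changes outside the error kernel (bit-exact)", {
  set.seed(4)
  net <- tiny_net(N = 40, seed = 4)
  ts <- trainer_state(40)
  tr <- build_trial(0, 1)
  tr$masks$delay1 <- integer(0)
  tr$masks$delay2 <- integer(0)
  tr$masks$response <- integer(0)
  res <- train_trial(net, tr, ts)
  expect_identical(res$net$W_o, net$W_o)
  expect_identical(res$net$W_d, net$W_d)
  expect_identical(res$tstate$P_o, ts$P_o)
  expect_identical(res$tstate$P_d, ts$P_d)
  expect_equal(res$errors$n_updates, 0L)
})

test_that("update cadence yields floor(|kernel| / update_every) events", {
  set.seed(5)
  net <- tiny_net(N = 40, seed = 5)
  tr <- build_trial(1, 0)
  n_kernel <- length(unlist(tr$masks))
  res <- train_trial(net, tr, trainer_state(40, update_every = 2))
  expect_equal(res$errors$n_updates, n_kernel %/% 2L)
  res3 <- train_trial(net, tr, trainer_state(40, update_every = 3))
  expect_equal(res3$errors$n_updates, n_kernel %/% 3L)
})

test_that("each RLS event reduces the instantaneous output error", {
  set.seed(6)
  net <- tiny_net(N = 60, seed = 6)
  res <- train_trial(net, build_trial(1, 1), trainer_state(60))
  expect_gt(length(res$errors$e_pre), 0)
  expect_true(all(res$errors$e_post <= res$errors$e_pre + 1e-12))
})

test_that("P matrices stay symmetric positive definite during training", {
  set.seed(7)
  net <- tiny_net(N = 30, seed = 7)
  ts <- trainer_state(30)
  x <- rep(0, 30)
  for (k in 1:4) {
    tr <- build_trial(k %% 2, (k %/% 2) %% 2)
    res <- train_trial(net, tr, ts, x)
    net <- res$net
    ts <- res$tstate
    x <- res$x
  }
  for (P in list(ts$P_o, ts$P_d)) {
    expect_lt(max(abs(P - t(P))), 1e-10)
    expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("training is bit-deterministic under a fixed seed", {
  run <- function() {
    set.seed(8)
    net <- tiny_net(N = 30, seed = 8)
    train_network(net, tstate = trainer_state(30, max_epochs = 2))
  }
  a <- run()
  b <- run()
  expect_identical(a$net$W_o, b$net$W_o)
  expect_identical(a$net$W_d, b$net$W_d)
  expect_identical(a$log$rmse, b$log$rmse)
})

test_that("a network meeting the bound stops at the first evaluation", {
  set.seed(9)
  net <- tiny_net(N = 30, seed = 9)
  # a permissive bound is met immediately: zero training epochs, no
  # weight updates at all
  fit <- train_network(net, tstate = trainer_state(30, rmse_threshold = 10))
  expect_true(fit$log$converged)
  expect_equal(fit$log$epochs, 0L)
  expect_identical(fit$net$W_o, net$W_o)
  expect_identical(fit$net$W_d, net$W_d)
})

test_that("non-convergence is reported via the log, not an error", {
  set.seed(10)
  net <- tiny_net(N = 20, g = 0.1, sigma_f2 = 1e-4, seed = 10)
  fit <- train_network(net, tstate = trainer_state(20, max_epochs = 2))
  expect_false(fit$log$converged)
  expect_false(fit$net$trained)
  expect_equal(fit$log$epochs, 2L)
})

test_that("trainability improves with initial connectivity strength", {
  res <- lapply(c(0.2, 1.2), function(g) {
    vapply(1:3, function(seed) {
      set.seed(seed)
      net <- init_network(network_params(N = 200, g = g, sigma_f2 = 0.05,
                                         sparsity = 0.1, seed = seed))
      fit <- train_network(net, tstate = trainer_state(200, max_epochs = 25))
      c(conv = fit$log$converged, rmse = fit$log$final_rmse)
    }, numeric(2))
  })
  frac_low <- mean(res[[1]]["conv", ])
  frac_high <- mean(res[[2]]["conv", ])
  expect_gte(frac_high, frac_low)
  # strong initial connectivity also reaches lower validation error
  expect_lt(mean(res[[2]]["rmse", ]), mean(res[[1]]["rmse", ]))
})
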