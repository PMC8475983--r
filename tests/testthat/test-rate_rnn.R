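test_that("initialization matches the declared distributions", {
  net <- tiny_net(N = 200, g = 0, sigma_f2 = 0.05, seed = 2)
  expect_true(all(net$J == 0))  # zero-variance draw

  net <- tiny_net(N = 200, g = 0.9, sparsity = 0.3, seed = 2)
  expect_true(all(net$W_o == 0))
  expect_true(all(net$W_d == 0))
  expect_equal(dim(net$W_i), c(200L, 2L))
  expect_equal(dim(net$W_fd), c(200L, 2L))
  # empirical zero fraction close to the sparsity level
  expect_lt(abs(mean(net$J == 0) - 0.3), 0.02)
  # bit-reproducible under the stored seed
  net2 <- tiny_net(N = 200, g = 0.9, sparsity = 0.3, seed = 2)
  expect_identical(net$J, net2$J)
  expect_identical(net$W_fd, net2$W_fd)
})

test_that("spectral radius of J tracks g (circular law, one draw)", {
  net <- init_network(network_params(N = 1000, g = 0.9, sigma_f2 = 0.05,
                                     sparsity = 0, seed = 4))
  rad <- max(Mod(eigen(net$J, only.values = TRUE)$values))
  expect_gt(rad, 0.85)
  expect_lt(rad, 0.95)
})

test_that("effective connectivity is J plus the rank-3 structure", {
  net <- tiny_net(N = 30, seed = 5)
  expect_identical(effective_connectivity(net), net$J)  # untrained

  # hand outer-product example
  net3 <- tiny_net(N = 3, seed = 5)
  net3$J <- diag(3)
  net3$W_f <- matrix(c(1, 0, 0), 3, 1)
  net3$W_o <- matrix(c(0, 1, 0), 3, 1)
  net3$W_fd <- matrix(0, 3, 2)
  net3$W_d <- matrix(0, 3, 2)
  expected <- diag(3)
  expected[1, 2] <- 1
  expect_equal(effective_connectivity(net3), expected)

  # rank of the perturbation never exceeds 3
  net$W_o <- matrix(rnorm(30), 30, 1)
  net$W_d <- matrix(rnorm(60), 30, 2)
  expect_lte(qr(effective_connectivity(net) - net$J)$rank, 3L)
})

test_that("simulation follows the closed-form linear decay when idle", {
  net <- tiny_net(N = 10, g = 0, sigma_f2 = 1e-9, seed = 6)
  net$W_f[] <- 0
  net$W_fd[] <- 0
  net$W_i[] <- 0
  x0 <- rnorm(10)
  Tn <- 50L
  traj <- simulate_network(net, matrix(0, 2, Tn), x0)
  dt <- net$params$dt
  expected <- outer((1 - dt)^(seq_len(Tn)), x0)
  expect_equal(traj$x, expected, tolerance = 1e-12)
})

test_that("a fixed point of the driven dynamics stays fixed", {
  net <- tiny_net(N = 2, g = 0.5, seed = 7)
  net$W_i <- diag(2)
  x_star <- c(0.3, -0.2)
  u_star <- x_star - net$J %*% tanh(x_star)  # solves -x* + J r* + u = 0
  u <- matrix(u_star, 2, 100)
  traj <- simulate_network(net, u, x_star)
  expect_equal(traj$x, matrix(rep(x_star, each = 100), 100, 2),
               tolerance = 1e-10)
})

test_that("autonomous dynamics are odd: simulate(-x0) = -simulate(x0)", {
  net <- tiny_net(N = 25, g = 1.2, seed = 8)
  net$W_o <- matrix(rnorm(25, 0, 0.1), 25, 1)
  net$W_d <- matrix(rnorm(50, 0, 0.1), 25, 2)
  x0 <- rnorm(25)
  u <- matrix(0, 2, 120)
  a <- simulate_network(net, u, x0)
  b <- simulate_network(net, u, -x0)
  expect_equal(b$x, -a$x, tolerance = 1e-12)
  expect_equal(b$z_o, -a$z_o, tolerance = 1e-12)
})

test_that("rates are bounded and states stay finite under bounded drive", {
  net <- tiny_net(N = 30, g = 1.5, seed = 9)
  u <- matrix(rnorm(2 * 300, 0, 2), 2, 300)
  traj <- simulate_network(net, u)
  expect_true(all(abs(traj$r) <= 1))
  expect_true(all(is.finite(traj$x)))
  expect_error(simulate_network(net, u, rep(NaN, 30)))
})

test_that("Euler integration agrees with an adaptive integrator", {
  net <- tiny_net(N = 5, g = 0.9, seed = 10)
  net$W_o <- matrix(rnorm(5, 0, 0.2), 5, 1)
  x0 <- rnorm(5, 0, 0.5)
  Tn <- 200L
  traj <- simulate_network(net, matrix(0, 2, Tn), x0)
  JT <- effective_connectivity(net)
  ref <- deSolve::ode(
    y = x0, times = seq(0, Tn * net$params$dt, by = net$params$dt),
    func = function(t, x, p) list(-x + JT %*% tanh(x)),
    method = "lsoda", rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(traj$x - ref[-1, -1])), 10 * net$params$dt)
})

test_that("network bundles round-trip through serialization", {
  net <- tiny_net(N = 15, seed = 11)
  path <- tempfile(fileext = ".rds")
  write_network_bundle(net, path)
  back <- read_network_bundle(path)
  expect_identical(back$J, net$J)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$params$N, 15L)
  unlink(c(path, paste0(path, ".json")))
})
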