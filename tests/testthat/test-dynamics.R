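test_that("module gains follow the geometric series", {
  expect_equal(module_gain(1), 0.45)
  expect_equal(module_gain(3), 0.225)
  g <- module_gain(1:5)
  expect_equal(g[-5] / g[-1], rep(sqrt(2), 4))
  expect_error(module_gain(6), "out of range")
})

test_that("velocity input evaluates the cosine drive", {
  expect_equal(velocity_input(0, 37, 0, 0.45), 0.6)
  expect_equal(velocity_input(1, 90, 0, 0.45), 0.6)          # orthogonal
  expect_equal(velocity_input(1, 0, 0, 0.45), 1.05)
  expect_equal(velocity_input(0.5, 180, 0, 0.3), 0.6 - 0.15)
})

test_that("shifted radial inhibition has uniform out-degree and shift", {
  # brute-force lattice count inside radius 12
  off <- expand.grid(-12:12, -12:12)
  n_expect <- sum(off[, 1]^2 + off[, 2]^2 <= 144)
  expect_equal(inhibition_outdegree(12), n_expect)
  expect_length(inhibition_targets(32, unit = 3), n_expect)
  # east-preferring set is the west-preferring set translated by 4 columns
  dirs <- sheet_directions(32)
  uE <- which(dirs == "E")[1] - 1
  uW <- which(dirs == "W")[1] - 1
  # move W unit to the same lattice site as E unit, then compare sets
  sE <- inhibition_targets(32, uE)
  rE <- uE %/% 32; cE <- uE %% 32
  rW <- uW %/% 32; cW <- uW %% 32
  sW <- inhibition_targets(32, uW)
  # translate W's set by the site difference plus 4 columns eastward
  tr <- function(s, dr, dc) sort(((s %/% 32 + dr) %% 32) * 32 +
                                   ((s %% 32 + dc) %% 32))
  expect_equal(sE, tr(sW, rE - rW, cE - cW + 4))
})

test_that("spike_step implements the clipped Bernoulli probability", {
  expect_equal(spike_step(0.1, beta = 0.1, rate_based = TRUE), 0)
  expect_equal(spike_step(0.2, beta = 0.1, rate_based = TRUE), 0.15)
  expect_equal(spike_step(0.1 + 2 / 3, beta = 0.1, rate_based = TRUE), 1)
  set.seed(1)
  s <- spike_step(rep(0.2, 20000), beta = 0.1)
  expect_true(all(s %in% c(0, 1)))
  expect_equal(mean(s), 0.15, tolerance = 0.05)
})

test_that("integrate_activation is the leaky spike integrator", {
  expect_equal(integrate_activation(0, 1), 0.5)
  expect_equal(integrate_activation(1, 0), 0.9)
  expect_equal(integrate_activation(0, 0), 0)
  # asymptote under continuous spiking: alpha / (dt/c) = 5
  a <- 0
  for (i in 1:400) a <- integrate_activation(a, 1)
  expect_equal(a, 5, tolerance = 1e-3)
})

test_that("hebbian update: fixed points and total-weight convergence", {
  # a_j = 0: no change
  w <- c(0.01, 0.02)
  expect_equal(hebbian_update(w, pre = c(1, 1), post = 0, xi = 0.4), w)
  # single persistently coactive input converges to xi
  w <- 0.01
  for (i in 1:300000) w <- hebbian_update(w, pre = 1, post = 1, xi = 0.4,
                                          lambda = 1e-4)
  expect_equal(w, 0.4, tolerance = 1e-3)
  # equal activity across inputs: total converges to xi
  W <- matrix(runif(32 * 4, 0, 0.025), 32, 4)
  for (i in 1:30000) W <- hebbian_update_matrix(W, pre = rep(0.5, 32),
                                                post = rep(1, 4), xi = 0.4,
                                                lambda = 1e-4)
  expect_equal(colSums(W), rep(0.4, 4), tolerance = 0.01)
  # matrix and vector forms agree
  set.seed(3)
  W0 <- matrix(runif(10 * 3), 10, 3)
  pre <- runif(10); post <- runif(3)
  W1 <- hebbian_update_matrix(W0, pre, post, xi = 0.5, lambda = 0.01)
  W2 <- vapply(1:3, function(j)
    hebbian_update(W0[, j], pre, post[j], xi = 0.5, lambda = 0.01),
    numeric(10))
  expect_equal(W1, W2)
})

test_that("total_input composes the three population rules", {
  expect_equal(total_input("border", in_field = c(TRUE, FALSE)), c(0.1, 0))
  # stationary rat, zero activations -> grid input is gamma
  expect_equal(total_input("grid", activations = numeric(3),
                           weights = matrix(0, 3, 2),
                           velocity = rep(0.6, 2)), rep(0.6, 2))
  # one border afferent a = 0.4, w = 0.025
  expect_equal(total_input("grid", activations = 0.4,
                           weights = matrix(0.025, 1, 1), velocity = 0.6),
               0.61)
  # uniform place activity, no grid input: 64 * (-0.15)
  b <- total_input("place", activations = numeric(5),
                   weights = matrix(0, 5, 64), recurrent = -0.15,
                   place_activations = rep(1, 64))
  expect_equal(b, rep(-9.6, 64))
})

test_that("engine single steps match the R reference operations", {
  # one step, rate-based (deterministic): grid input = gamma everywhere
  cfg <- dynamics_constants()
  a0 <- rep(0.2, 16 * 16)
  mod <- list(nside = 16L, gain = 0.45, a = a0, w_bg = NULL)
  disp <- matrix(c(0.06, 0), 1, 2)
  res <- gridtether:::.sim_core_cpp(disp, 0L, 1L, list(mod),
                                    list(ptr = c(0L, 0L), idx = integer(0)),
                                    NULL, integer(0),
                                    gridtether:::.engine_cfg(cfg, FALSE,
                                                             TRUE, FALSE))
  # reference: velocity input per direction + uniform inhibition field
  dirs <- sheet_directions(16)
  phi <- c(E = 0, N = 90, W = 180, S = 270)[dirs]
  v <- velocity_input(0.06, 0, phi, 0.45)
  ndisc <- inhibition_outdegree(12)
  # all a equal: convolved field = ndisc * a everywhere
  b <- v + cfg$inhib_w * ndisc * 0.2
  p <- spike_step(b, cfg$beta_grid, rate_based = TRUE)
  a1 <- unname(integrate_activation(a0, p))
  expect_equal(res$modules[[1]]$a, a1, tolerance = 1e-12)
})

test_that("place layer wiring and input", {
  pl <- init_place_layer(n_grid = 2000, n_place = 8, seed = 4)
  expect_equal(dim(pl$aff), c(500, 8))
  expect_true(all(apply(pl$aff, 2, function(x) !any(duplicated(x)))))
  expect_true(all(pl$w_gp >= 0 & pl$w_gp <= 0.022))
  pl2 <- init_place_layer(n_grid = 2000, n_place = 8, seed = 4)
  expect_identical(pl$aff, pl2$aff)
  expect_error(init_place_layer(n_grid = 100), "smaller")
  # single afferent input
  ga <- numeric(2000); ga[pl$aff[1, 1]] <- 1
  W <- matrix(0, 500, 8); W[1, 1] <- 0.01
  b <- place_input(numeric(8), ga, W, pl$aff)
  expect_equal(b[1], 0.01)
})
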