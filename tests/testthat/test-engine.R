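test_that("network construction follows the published architecture", {
  cfg <- network_config("full")
  expect_equal(cfg$n_modules, 5L)
  expect_equal(cfg$nside, 128L)
  expect_equal(cfg$gains, 0.45 * 2^(-(0:4) / 2))
  expect_equal(cfg$familiarize_s, 3600)
  expect_equal(cfg$test_s, 1800)
  cfg_d <- network_config("desk", familiarize_s = 120)
  expect_equal(cfg_d$familiarize_s, 120)
  expect_error(network_config("desk", nonsense = 1), "unknown")
  net <- init_network(network_config("desk", nside = 32L), seed = 1)
  expect_length(net$modules, 2)
  expect_true(all(net$modules[[1]]$w_bg >= 0 & net$modules[[1]]$w_bg <= 0.025))
  expect_equal(dim(net$modules[[1]]$w_bg), c(32^2, 32))
  expect_equal(dim(net$place$aff), c(500, 64))
})

test_that("settling produces a stable periodic attractor state", {
  set.seed(2)
  st <- settle_module(64, 0.45, refine = FALSE)
  expect_gt(gridtether:::.sheet_gridness(st$a, 64), 0.5)
  expect_true(all(st$a >= 0))
  # zero-velocity drift: another 10 s of settling moves the pattern < 1 unit
  cfg <- dynamics_constants()
  n <- round(10 / cfg$dt)
  res <- gridtether:::.sim_core_cpp(
    matrix(0, n, 2), rep(-1L, n), 0L,
    list(list(nside = 64L, gain = 0.45, a = st$a, w_bg = NULL)),
    list(ptr = integer(n + 1), idx = integer(0)), NULL, integer(0),
    gridtether:::.engine_cfg(cfg, FALSE, TRUE, FALSE))
  expect_lte(phase_displacement(st$a, res$modules[[1]]$a, 64), 1)
})

test_that("path-integration closure: a closed loop restores the phase", {
  set.seed(3)
  st <- settle_module(64, 0.45, refine = FALSE)
  cfg <- dynamics_constants()
  d <- 20 * cfg$dt
  leg <- round(30 / d)
  disp <- rbind(matrix(rep(c(d, 0), each = leg), leg),
                matrix(rep(c(0, d), each = leg), leg),
                matrix(rep(c(-d, 0), each = leg), leg),
                matrix(rep(c(0, -d), each = leg), leg))
  n <- nrow(disp)
  res <- gridtether:::.sim_core_cpp(
    disp, rep(-1L, n), 0L,
    list(list(nside = 64L, gain = 0.45, a = st$a, w_bg = NULL)),
    list(ptr = integer(n + 1), idx = integer(0)), NULL, integer(0),
    gridtether:::.engine_cfg(cfg, FALSE, TRUE, FALSE))
  expect_lte(phase_displacement(st$a, res$modules[[1]]$a, 64), 2)
})

test_that("familiarization and test trials honour the protocol contracts", {
  cfg <- network_config("desk", nside = 32L, rec_per_module = 5L)
  env <- make_environment("rectangle", 60, 60)
  set.seed(10)
  net0 <- init_network(cfg, seed = 11)
  net <- familiarize(net0, env, duration_s = 20, seed = 12)
  # weights moved away from their initial values
  expect_gt(max(abs(net$modules[[1]]$w_bg - net0$modules[[1]]$w_bg)), 0)
  # weights stay non-negative (clamped rule)
  expect_true(all(net$modules[[1]]$w_bg >= 0))
  expect_true(all(net$place$w_gp >= 0))
  # cache has an entry for every visited pixel, including the start pixel
  ras <- rasterize_positions(env, net$familiar_traj$x, net$familiar_traj$y)
  expect_setequal(which(net$cache$seen), unique(ras$idx))
  # determinism: same seeds, identical weights
  set.seed(10)
  net0b <- init_network(cfg, seed = 11)
  netb <- familiarize(net0b, env, duration_s = 20, seed = 12)
  expect_identical(net$modules[[1]]$w_bg, netb$modules[[1]]$w_bg)
  expect_identical(net$place$w_gp, netb$place$w_gp)

  # test trial: weights fixed, record counts as configured
  tt <- test_trial(net, env, duration_s = 10, seed = 13)
  expect_length(tt$rec_grid, 2 * 5)
  expect_true(all(tt$spikes$grid$unit %in% tt$rec_grid))
  expect_identical(net$modules[[1]]$w_bg, netb$modules[[1]]$w_bg)
  # activations bounded by the geometric-series limit alpha/(dt/c) = 5
  expect_lte(max(net$modules[[1]]$a), 5 + 1e-9)
  expect_error(test_trial(init_network(cfg, seed = 1), env), "familiarized")
})

test_that("cache reinstatement picks the cached state at the start pixel", {
  cfg <- network_config("desk", nside = 32L, n_modules = 1L,
                        gains = 0.3182)
  env <- make_environment("rectangle", 40, 40)
  set.seed(20)
  net <- init_network(cfg, seed = 21)
  net <- familiarize(net, env, duration_s = 15, seed = 22)
  idx <- which(net$cache$seen)[1]
  ras <- net$cache$ras
  ix <- (idx - 1) %% ras$nx + 1; iy <- (idx - 1) %/% ras$nx + 1
  pt <- c((ix - 0.5) * 2.5, (iy - 0.5) * 2.5)
  net2 <- reinstate_from_cache(net, pt)
  expect_identical(net2$modules[[1]]$a,
                   unname(net$cache$snapshots[[1]][, idx]))
  # a miss falls back to the nearest cached pixel (never errors inside env)
  net3 <- reinstate_from_cache(net, c(0.1, 39.9))
  expect_true(is.numeric(net3$modules[[1]]$a))
})

test_that("checkpoints round-trip through disk", {
  cfg <- network_config("desk", nside = 32L)
  net <- init_network(cfg, seed = 5)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  expect_identical(back$modules[[1]]$w_bg, net$modules[[1]]$w_bg)
  unlink(f)
})
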