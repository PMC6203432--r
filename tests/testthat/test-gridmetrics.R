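test_that("rate maps conserve spike counts and mask unvisited pixels", {
  env <- make_environment("rectangle", 50, 50)
  traj <- random_walk(env, 60, seed = 31)
  # homogeneous Poisson-ish spiking at 5 Hz
  set.seed(1)
  spk <- traj$t[stats::runif(length(traj$t)) < 5 * traj$dt_s]
  m <- rate_map(traj, spk, env)
  # unsmoothed: rate * occupancy sums to the spike count exactly
  tot <- sum(m$rate_raw * m$occupancy_s, na.rm = TRUE)
  expect_equal(tot, length(spk))
  expect_equal(m$n_spikes, length(spk))
  # homogeneous rate recovered
  expect_equal(mean(m$rate[m$mask], na.rm = TRUE), 5, tolerance = 0.15)
  # unvisited pixels masked
  expect_true(all(is.na(m$rate[!m$mask])))
  # 1 spike in a pixel occupied 1 s
  traj2 <- toy_traj(rep(5, 10), rep(5, 10), dt = 0.1)
  m2 <- rate_map(traj2, spike_t = traj2$t[3], env, smooth = FALSE)
  expect_equal(m2$rate[3, 3], 1)
  expect_equal(sum(m2$rate > 0, na.rm = TRUE), 1)
  expect_error(rate_map(structure(list(t = numeric(0)),
                                  class = "gt_trajectory"), 1, env),
               "empty")
})

test_that("correlogram equals the brute-force per-lag Pearson oracle", {
  set.seed(7)
  A <- matrix(rnorm(100), 10, 10)
  B <- A + 0.5 * matrix(rnorm(100), 10, 10)
  maskA <- matrix(TRUE, 10, 10); maskA[1, 1:3] <- FALSE
  A[!maskA] <- NA
  oracle <- brute_correlogram(A, B, min_overlap = 20)
  got <- correlogram(as_map(A), as_map(B), min_overlap = 20)
  expect_equal(dim(got$r), dim(oracle))
  expect_equal(got$r, oracle, tolerance = 1e-8)
  # autocorrelogram properties
  ac <- correlogram(as_map(A), as_map(A))
  expect_equal(ac$r[ac$center[1], ac$center[2]], 1, tolerance = 1e-10)
  # symmetry under lag negation
  expect_equal(ac$r, ac$r[nrow(ac$r):1, ncol(ac$r):1], tolerance = 1e-10)
  # cross(A,B) at lag l = cross(B,A) at -l
  ba <- correlogram(as_map(B), as_map(A), min_overlap = 20)
  expect_equal(got$r, ba$r[nrow(ba$r):1, ncol(ba$r):1], tolerance = 1e-8)
  # constructed translation: B = A shifted by (2, 0) pixels
  C <- matrix(rnorm(400), 20, 20)
  D <- matrix(NA_real_, 20, 20); D[3:20, ] <- C[1:18, ]
  cc <- correlogram(as_map(D), as_map(C), min_overlap = 20)
  pk <- which(cc$r == max(cc$r, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk - cc$center), c(2, 0))
})

test_that("grid scale recovers constructed lattice spacing", {
  fx <- make_fixtures("hex_map", spacing_cm = 50, size_cm = 150)
  cg <- correlogram(fx$map, fx$map)
  sc <- grid_scale(cg)
  expect_equal(sc$scale_cm, 50, tolerance = 2.5)
  # dilation equivariance: a 2x coarser pixel pitch doubles the scale
  m2 <- fx$map; m2$pixel_cm <- 5
  cg2 <- correlogram(m2, m2)
  expect_equal(grid_scale(cg2)$scale_cm, 2 * sc$scale_cm, tolerance = 1e-9)
  # invariance to global rate scaling and to lattice phase
  fx3 <- make_fixtures("hex_map", spacing_cm = 50, size_cm = 150)
  fx3$map$rate <- fx3$map$rate * 7.3
  expect_equal(grid_scale(correlogram(fx3$map, fx3$map))$scale_cm,
               sc$scale_cm, tolerance = 1e-6)
  # the localmax method agrees to a pixel
  expect_equal(grid_scale(cg, method = "localmax")$scale_cm, sc$scale_cm,
               tolerance = 2.5)
})

test_that("gridness separates hexagonal, square and radial patterns", {
  fx <- make_fixtures("hex_map", spacing_cm = 50, size_cm = 150)
  cg <- correlogram(fx$map, fx$map)
  sc <- grid_scale(cg)
  expect_gt(gridness(cg, sc$scale_cm), 1)
  # square lattice: product of cosines on the two axes
  px <- (1:60 - 0.5) * 2.5
  sq <- outer(px, px, function(x, y)
    (cos(2 * pi * x / 50) + 1) * (cos(2 * pi * y / 50) + 1))
  cgs <- correlogram(as_map(sq), as_map(sq))
  expect_lt(gridness(cgs, 50), 0)
  # an exactly radially symmetric correlogram scores ~0 (all rotations
  # are identical up to interpolation error)
  lag <- (1:81 - 41) * 2.5
  rr <- outer(lag, lag, function(x, y) cos(sqrt(x^2 + y^2) * 2 * pi / 50))
  cgr <- structure(list(r = rr, valid = matrix(TRUE, 81, 81),
                        n = rr * 0 + 100, center = c(41, 41),
                        pixel_cm = 2.5), class = "gt_correlogram")
  expect_equal(gridness(cgr, 50), 0, tolerance = 0.05)
})

test_that("field length matches the 10% contour of a known Gaussian", {
  # autocorrelogram of a Gaussian field has a Gaussian central peak;
  # build the correlogram object directly from a closed form
  px <- 2.5
  n <- 41
  lag <- (seq_len(n) - 21) * px
  sigma <- 10
  r <- outer(lag, lag, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  corr <- structure(list(r = r, valid = matrix(TRUE, n, n), n = r * 0 + 100,
                         center = c(21, 21), pixel_cm = px),
                    class = "gt_correlogram")
  # 10% contour radius = sigma * sqrt(2 log 10)
  expected <- 2 * sigma * sqrt(2 * log(10))
  expect_equal(field_length(corr, "x"), expected, tolerance = 2 * px)
  expect_equal(field_length(corr, "y"), expected, tolerance = 2 * px)
  # anisotropic stretch: x length scales, y unchanged
  r2 <- outer(lag, lag, function(x, y)
    exp(-((x / 1.3)^2 + y^2) / (2 * sigma^2)))
  corr2 <- corr; corr2$r <- r2
  expect_equal(field_length(corr2, "x") / field_length(corr, "x"), 1.3,
               tolerance = 0.12)
  expect_equal(field_length(corr2, "y"), field_length(corr, "y"),
               tolerance = px)
})

test_that("firing rates and the inclusion criterion", {
  traj <- toy_traj(rep(5, 100), rep(5, 100), dt = 0.5)
  spk <- sort(stats::runif(100, 0, max(traj$t)))
  env <- make_environment("rectangle", 50, 50)
  m <- rate_map(traj, spk, env)
  fr <- firing_rates(m, duration_s = 50)
  expect_equal(fr$mean_hz, 2)
  expect_equal(firing_rates(m, duration_s = 25)$mean_hz, 4)
  expect_true(include_cell(c(0.9, 0.1)))
  expect_false(include_cell(c(0.3, 0.3)))
  expect_false(include_cell(c(0.4, 0.4)))       # strict inequality
  expect_true(include_cell(c(NA, 0.5)))         # missing trial dropped
})
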