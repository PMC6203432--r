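test_that("boundary rate maps split data by label and match occupancy", {
  env <- make_environment("rectangle", 60, 60)
  traj <- random_walk(env, 180, seed = 41)
  lab <- label_boundary_contacts(traj, env)
  set.seed(2)
  spk <- traj$t[stats::runif(length(traj$t)) < 8 * traj$dt_s]
  maps <- boundary_rate_maps(traj, spk, lab, env)
  got <- names(maps)[!vapply(maps, is.null, logical(1))]
  expect_true(all(c("N", "S", "E", "W") %in% got))
  # total samples across maps = labelled samples
  tot <- sum(vapply(maps[got], function(m) sum(m$sample_count), numeric(1)))
  expect_equal(tot, sum(lab != "none"))
  # matched pairs: identical per-pixel sample histograms, exactly
  pairs <- boundary_rate_maps(traj, spk, lab, env, matched = TRUE,
                              pair = c("E", "W"), iterations = 3, seed = 5)
  for (pp in pairs)
    expect_identical(pp[[1]]$sample_count, pp[[2]]$sample_count)
  # a path hugging one wall only defines one map
  trajN <- toy_traj(seq(15, 45, length.out = 30), rep(55, 30))
  labN <- label_boundary_contacts(trajN, env)
  mN <- boundary_rate_maps(trajN, trajN$t[5], labN, env)
  expect_null(mN$S)
  expect_false(is.null(mN$N))
})

test_that("shift recovery on constructed periodic maps", {
  # oracle: maps built as translated copies; measured shift must equal the
  # construction within one pixel
  for (delta in c(0, 5, 10)) {
    fx <- make_fixtures("shifted_pair", shift_cm = delta, spacing_cm = 50)
    s <- shift_between_maps(fx$map_a, fx$map_b, scale_cm = 50,
                            dimension = "x")
    expect_equal(s, delta, tolerance = 2.5)
  }
  # window-boundary case: translation of exactly scale/2
  fx <- make_fixtures("shifted_pair", shift_cm = 25, spacing_cm = 50)
  s <- shift_between_maps(fx$map_a, fx$map_b, scale_cm = 50, dimension = "x")
  expect_equal(s / 25, 1, tolerance = 0.1)
})

test_that("shift recovery across random phases (property)", {
  set.seed(11)
  errs <- replicate(25, {
    delta <- sample(0:9, 1)
    phase <- stats::runif(2, 0, 50)
    a <- gridtether:::.hex_rate_matrix(120, 120, 50, 0, phase)
    b <- gridtether:::.hex_rate_matrix(120, 120, 50, 0,
                                       phase + c(delta, 0))
    s <- shift_between_maps(a, b, scale_cm = 50, dimension = "x")
    abs(s - delta)
  })
  expect_lte(max(errs), 2.5)
})

test_that("alignment test identifies the anchoring boundary", {
  # familiar 100 cm map; deformed 70 cm boundary maps built by cropping
  fam <- gridtether:::.hex_rate_matrix(100, 100, 50, 0, c(12, 7))
  nx_d <- 28                       # 70 cm
  west_anchored <- as_map(fam$rate[1:nx_d, ])
  east_anchored <- as_map(fam$rate[(41 - nx_d):40, ])
  r1 <- alignment_test(west_anchored, fam, boundary = "W",
                       deformed_dim = "x")
  expect_equal(r1$alignment, "corresponding")
  r2 <- alignment_test(east_anchored, fam, boundary = "W",
                       deformed_dim = "x")
  expect_equal(r2$alignment, "opposite")
  # undeformed: tie goes to corresponding
  r3 <- alignment_test(fam, fam, boundary = "E", deformed_dim = "x")
  expect_equal(r3$alignment, "corresponding")
  expect_error(alignment_test(fam, fam, boundary = "N",
                              deformed_dim = "x"), "deformed dimension")
})

test_that("rescaling factor: exact recovery on the 5 cm search grid", {
  fx <- make_fixtures("compressed_pair", factor = 0.7, size_cm = 100)
  res <- rescaling_factor(fx$map_familiar, fx$map_deformed,
                          fam_len = 100, def_len = 70, dimension = "x")
  expect_equal(res$factor, 0.7)
  expect_equal(res$normalized_pct, 100)
  # candidate grid: 10 below smaller through 10 above larger in 5 cm steps
  expect_equal(range(res$candidates$len), c(60, 110))
  expect_equal(unique(diff(sort(unique(res$candidates$len)))), 5)
  # undeformed: factor 1, normalized undefined
  res2 <- rescaling_factor(fx$map_familiar, fx$map_familiar, 100, 100, "x")
  expect_equal(res2$factor, 1)
  expect_true(is.na(res2$normalized_pct))
})

test_that("two-phase mixture: boundary factor ~1, matched whole factor < 1", {
  fx <- make_fixtures("two_phase_mixture", seed = 8, duration_s = 300)
  res <- boundary_conditioned_rescaling(
    fx$traj, fx$spike_t, fx$labels, fx$env, fx$familiar_map,
    boundary = "W", fam_len = fx$meta$fam_len, def_len = fx$meta$def_len,
    dimension = "x", iterations = 15, seed = 9)
  expect_equal(res$boundary_factor, 1, tolerance = 0.11)
  expect_lt(res$matched_whole_factor, res$boundary_factor - 0.02)
})

test_that("boundary-tethered prediction reconstructs mixtures", {
  # undeformed environment: prediction = smoothed familiar map
  env <- make_environment("rectangle", 60, 60)
  traj <- random_walk(env, 120, seed = 51)
  lab <- label_boundary_contacts(traj, env)
  fam <- gridtether:::.hex_rate_matrix(60, 60, 40, 0, c(3, 9))
  pred <- predict_deformed_map(fam, traj, lab, env, env)
  ref <- smooth_map(fam$rate, matrix(TRUE, 24, 24), fill_all = TRUE)
  expect_equal(dim(pred$rate), c(24, 24))
  expect_gt(stats::cor(c(pred$rate), c(ref)), 0.999)
  # all-north labels: prediction equals the north-anchored crop
  env_d <- make_environment("rectangle", 60, 45)
  traj_d <- random_walk(env_d, 60, seed = 52)
  labN <- structure(rep("N", length(traj_d$x)), class = "gt_labels")
  predN <- predict_deformed_map(fam, traj_d, labN, env, env_d)
  # x is undeformed (full extent); y is anchored at the north wall
  crop <- fam$rate[, (24 - 18 + 1):24]
  expect_gt(stats::cor(c(predN$rate), c(crop)), 0.95)
  # 50/50 E/W mixture under compression: peak lower than either copy
  fxm <- make_fixtures("two_phase_mixture", seed = 12, duration_s = 240)
  env_f <- make_environment("rectangle", fxm$meta$fam_len, fxm$meta$fam_len)
  predM <- predict_deformed_map(fxm$familiar_map, fxm$traj, fxm$labels,
                                env_f, fxm$env)
  expect_equal(dim(predM$rate),
               c(round(fxm$meta$def_len / 2.5), fxm$meta$fam_len / 2.5))
  expect_lt(max(predM$rate), max(fxm$familiar_map$rate))
})

test_that("matched rescaling map and prediction similarity", {
  fx <- make_fixtures("compressed_pair", factor = 0.7, size_cm = 100)
  env_d <- make_environment("rectangle", 70, 100)
  m <- matched_rescaling_map(fx$map_familiar, env_d)
  expect_equal(dim(m$rate), c(28, 40))
  expect_equal(m$pixel_cm, 2.5)
  expect_equal(m$rate, fx$map_deformed$rate, tolerance = 1e-9)
  # undeformed: identity
  env_f <- make_environment("rectangle", 100, 100)
  m0 <- matched_rescaling_map(fx$map_familiar, env_f)
  expect_equal(m0$rate, fx$map_familiar$rate)
  # similarity: identical maps r = 1, z capped finite
  ps <- prediction_similarity(fx$map_deformed, m)
  expect_equal(ps$r, 1, tolerance = 1e-9)
  expect_true(is.finite(ps$z))
  # independent noise maps ~ 0
  set.seed(3)
  a <- as_map(matrix(rnorm(400), 20, 20))
  b <- as_map(matrix(rnorm(400), 20, 20))
  expect_lt(abs(prediction_similarity(a, b)$r), 0.2)
  expect_equal(prediction_similarity(a, b)$r, prediction_similarity(b, a)$r)
})

test_that("population vector correlation localises distortion", {
  set.seed(6)
  n_units <- 20
  fam_maps <- lapply(1:n_units, function(u)
    gridtether:::.hex_rate_matrix(100, 100, 50, 0, stats::runif(2, 0, 50)))
  # deformed stack: fields shifted only within 20 cm of the east wall
  def_maps <- lapply(fam_maps, function(m) {
    r <- m$rate
    east <- (nrow(r) - 7):nrow(r)            # last 20 cm
    r[east, ] <- r[pmax(east - 2, 1), ]      # 5 cm local shift
    as_map(r)
  })
  pv <- population_vector_correlation(fam_maps, def_maps)
  expect_equal(dim(pv$r), c(40, 40))
  cm <- pv$column_means
  expect_gt(mean(cm[1:30]), 0.99)
  expect_lt(mean(cm[34:40]), mean(cm[1:30]))
  # identical stacks: r = 1 everywhere
  pv1 <- population_vector_correlation(fam_maps, lapply(fam_maps, identity))
  expect_true(all(abs(pv1$r - 1) < 1e-9, na.rm = TRUE))
})
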