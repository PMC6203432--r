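test_that("environment construction and containment", {
  sq <- make_environment("rectangle", 150, 150)
  expect_equal(sq$width_cm, 150)
  expect_length(sq$walls, 4)
  expect_true(env_contains(sq, 75, 75))
  expect_false(env_contains(sq, -1, 75))

  tz <- make_environment("right_trapezoid", 180, 90,
                         trapezoid_short_wall_cm = 135)
  expect_true(env_contains(tz, 1, 89))
  expect_false(env_contains(tz, 179, 89))   # beyond the slanted wall
  expect_true(env_contains(tz, 179, 0.5))
  # slanted wall length
  expect_equal(gridtether:::.wall_length(tz, "E"), sqrt(45^2 + 90^2))

  expect_error(make_environment("rectangle", -5, 10), "positive")
  expect_error(make_environment("right_trapezoid", 180, 90,
                                trapezoid_short_wall_cm = 200), "shorter")
  # inserted wall must be strictly inside
  expect_error(make_environment("rectangle", 65, 65,
                                inserted_walls = rbind(c(0, 32.5, 40, 32.5))),
               "strictly inside")
  ins <- make_environment("rectangle", 65, 65,
                          inserted_walls = rbind(c(1, 32.5, 40, 32.5)))
  expect_equal(nrow(ins$inserted_walls), 1)
})

test_that("random walk obeys the path contracts", {
  env <- make_environment("rectangle", 100, 100)
  traj <- random_walk(env, duration_s = 60, seed = 11)
  expect_length(traj$t, 20001)               # 60 s / 0.003 s + start
  expect_equal(c(traj$x[1], traj$y[1]), c(50, 50))
  expect_equal(traj$speed_cms[1], 0)
  expect_true(all(env_contains(env, traj$x, traj$y)))
  expect_lte(max(traj$speed_cms), 40)
  expect_gte(min(traj$speed_cms), 0)
  # per-step displacement consistent with reported speed
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  expect_lte(max(d), 40 * 0.003 + 1e-9)
  # determinism
  traj2 <- random_walk(env, duration_s = 5, seed = 11)
  traj3 <- random_walk(env, duration_s = 5, seed = 11)
  expect_identical(traj2$x, traj3$x)
})

test_that("random walk respects inserted walls", {
  env <- make_environment("rectangle", 65, 65,
                          inserted_walls = rbind(c(32.5, 1, 32.5, 40)))
  traj <- random_walk(env, duration_s = 120, seed = 3)
  # no step may cross the wall segment
  crosses <- function(x0, y0, x1, y1) {
    # wall x = 32.5, y in [1, 40]
    straddles <- (x0 - 32.5) * (x1 - 32.5) < 0
    ty <- y0 + (y1 - y0) * (32.5 - x0) / (x1 - x0)
    straddles & ty >= 1 & ty <= 40
  }
  n <- length(traj$x)
  cr <- crosses(traj$x[-n], traj$y[-n], traj$x[-1], traj$y[-1])
  expect_false(any(cr, na.rm = TRUE))
})

test_that("track laps run at constant speed within [0, length]", {
  traj <- track_laps(161, duration_s = 30, speed_cm_per_s = 20)
  expect_true(all(traj$x >= 0 & traj$x <= 161))
  d <- abs(diff(traj$x))
  # all steps move at exactly speed * dt except the fold samples
  expect_equal(sort(unique(round(d, 9)))[length(unique(round(d, 9)))],
               20 * 0.003)
  folds <- sum(abs(d - 20 * 0.003) > 1e-9)
  expect_lte(folds, ceiling(30 / (161 / 20)) + 1)
  # lap time = length / speed
  expect_equal(161 / 20, 8.05)
})

test_that("boundary contact labels: recency, ties and none", {
  env <- make_environment("rectangle", 60, 60)
  # hand-built path: centre -> north band -> centre -> south band
  x <- c(30, 30, 30, 30, 30)
  y <- c(30, 50, 30, 8, 30)
  traj <- toy_traj(x, y)
  lab <- label_boundary_contacts(traj, env)
  expect_equal(as.character(lab), c("none", "N", "N", "S", "S"))

  # corner: nearer wall wins
  traj2 <- toy_traj(c(30, 5, 10), c(30, 8, 30))
  lab2 <- label_boundary_contacts(traj2, env)
  expect_equal(as.character(lab2), c("none", "W", "W"))
  traj3 <- toy_traj(c(30, 8, 30), c(30, 5, 30))
  expect_equal(as.character(label_boundary_contacts(traj3, env)),
               c("none", "S", "S"))
  # labels change only when a wall is within threshold
  env2 <- make_environment("rectangle", 100, 100)
  traj4 <- random_walk(env2, 30, seed = 5)
  lab4 <- label_boundary_contacts(traj4, env2)
  ch <- which(lab4[-1] != lab4[-length(lab4)]) + 1
  wd <- gridtether:::.wall_distances(env2, traj4$x, traj4$y)
  expect_true(all(apply(wd$dist[ch, , drop = FALSE], 1, min) <= 12))
})

test_that("recency bias map normalises and marginalises correctly", {
  env <- make_environment("rectangle", 60, 60)
  traj <- random_walk(env, 120, seed = 9)
  lab <- label_boundary_contacts(traj, env)
  rb <- recency_bias_map(lab, traj, env)
  tot <- rb$prob[, , 1] + rb$prob[, , 2] + rb$prob[, , 3] + rb$prob[, , 4]
  expect_true(all(abs(tot[!is.na(tot)] - 1) < 1e-9))
  expect_equal(sum(rb$joint), sum(lab != "none"))
  # path confined to the north band
  trajN <- toy_traj(seq(20, 40, length.out = 10), rep(55, 10))
  labN <- label_boundary_contacts(trajN, env)
  rbN <- recency_bias_map(labN, trajN, env)
  pN <- rbN$prob[, , "N"]
  expect_true(all(pN[!is.na(pN)] == 1))
})

test_that("trajectory round-trips through csv text", {
  env <- make_environment("rectangle", 50, 50)
  traj <- random_walk(env, 2, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(back$x, traj$x, tolerance = 1e-6)
  expect_equal(back$dt_s, traj$dt_s, tolerance = 1e-9)
  unlink(f)
})
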