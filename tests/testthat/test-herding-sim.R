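test_that("repulsion kernel: threshold, cap, inverse-distance law", {
  p <- sim_params()
  expect_equal(repulsion_force(c(11, 0), p), c(0, 0))
  expect_equal(repulsion_force(c(0.5, 0), p), c(450, 0))
  expect_equal(repulsion_force(c(10, 0), p), c(45, 0))
  # monotone non-increasing magnitude over a distance sweep
  d <- seq(0.05, 12, by = 0.05)
  mag <- vapply(d, function(di)
    sqrt(sum(repulsion_force(c(di, 0), p)^2)), numeric(1))
  expect_true(all(diff(mag) <= 1e-12))
  # direction along the offset
  f <- repulsion_force(c(3, 4), p)
  expect_equal(f / sqrt(sum(f^2)), c(3, 4) / 5, tolerance = 1e-12)
  expect_error(repulsion_force(c(Inf, 0), p), "finite")
})

test_that("ta_step: zero force leaves velocity unchanged, repulsion points away", {
  p <- sim_params()
  ta <- list(position = c(100, 50), velocity = c(2, -1))
  out <- ta_step(ta, matrix(numeric(0), 0, 2), p, brownian_force = c(0, 0))
  expect_equal(out$velocity, c(2, -1))
  expect_equal(out$position, c(100, 50) + c(2, -1) / p$tick_rate)
  expect_equal(out$status, "idle")
  # single player 1 m due west of the TA: velocity due east after one tick
  ta <- list(position = c(100, 0), velocity = c(0, 0))
  out <- ta_step(ta, matrix(c(99, 0), 1, 2), p)
  expect_gt(out$velocity[1], 0)
  expect_equal(out$velocity[2], 0)
  expect_equal(out$status, "fleeing")
})

test_that("sustained pursuit drives the TA to exactly the 10 m/s speed cap", {
  p <- sim_params()
  ta <- list(position = c(50, 0), velocity = c(0, 0))
  set.seed(1)
  vmax <- 0
  for (i in seq_len(1e4)) {
    # co-moving pursuer 0.5 m behind, along the TA's motion (or due west)
    v <- ta$velocity
    dir <- if (sqrt(sum(v^2)) > 1e-9) v / sqrt(sum(v^2)) else c(1, 0)
    player <- matrix(ta$position - 0.5 * dir, 1, 2)
    ta <- ta_step(ta, player, p)
    vmax <- max(vmax, sqrt(sum(ta$velocity^2)))
  }
  expect_equal(vmax, p$ta_speed_max, tolerance = 1e-12)
})

test_that("flee response: distance to a stationary threat never decreases", {
  p <- sim_params(brownian_force_max = 0)
  player <- matrix(c(195, 100), 1, 2)
  ta <- list(position = c(200, 100), velocity = c(0, 0))
  d_prev <- 5
  for (i in seq_len(300)) {
    ta <- ta_step(ta, player, p)
    d <- sqrt(sum((ta$position - player[1, ])^2))
    expect_gte(d, d_prev - 1e-12)
    d_prev <- d
  }
})

test_that("success requires 5 continuous seconds with every TA contained", {
  d <- condition_design(9, "clear", "none", seed = 3)
  inside <- matrix(rnorm(18, sd = 1), 9, 2) # all within the 5 m circle
  r <- run_trial(d, ta_init = inside, freeze_ta = TRUE, idle_players = TRUE)
  expect_true(r$success)
  expect_equal(r$duration, 5.0)
  expect_equal(r$contained_at_end, 9)
})

test_that("failed trials cap at the 300 s ceiling", {
  d <- condition_design(9, "clear", "none", seed = 3)
  far <- cbind(150 * cos(1:9), 150 * sin(1:9))
  r <- run_trial(d, ta_init = far, freeze_ta = TRUE, idle_players = TRUE)
  expect_false(r$success)
  expect_equal(r$duration, 300)
  expect_equal(r$contained_at_end, 0)
})

test_that("identical (design, params, seed) gives an identical record", {
  d <- condition_design(9, "fog", "late_spawn", seed = 11)
  p <- sim_params(trial_max = 30)
  r1 <- run_trial(d, params = p)
  r2 <- run_trial(d, params = p)
  expect_identical(r1$player_x, r2$player_x)
  expect_identical(r1$ta_x, r2$ta_x)
  expect_identical(r1$ta_status, r2$ta_status)
  expect_identical(r1$duration, r2$duration)
})

test_that("perturbation trials carry exactly one extra TA identity", {
  p <- sim_params(trial_max = 20)
  r0 <- run_trial(condition_design(9, "clear", "none", seed = 2), params = p)
  r1 <- run_trial(condition_design(9, "clear", "late_spawn", seed = 2),
                  params = p)
  expect_equal(ncol(r0$ta_x), 9)
  expect_equal(ncol(r1$ta_x), 10)
})

test_that("containment status agrees with the geometric predicate every tick", {
  p <- sim_params(trial_max = 15)
  r <- run_trial(condition_design(9, "clear", "none", seed = 8), params = p)
  d <- sqrt(r$ta_x^2 + r$ta_y^2)
  geom <- d <= p$containment_radius
  flagged <- r$ta_status >= 2
  expect_identical(flagged, geom)
})

test_that("speed clamps hold for every agent at every tick", {
  p <- sim_params(trial_max = 20)
  r <- run_trial(condition_design(18, "clear", "none", seed = 4), params = p)
  dt <- 1 / p$tick_rate
  ta_speed <- sqrt(diff(r$ta_x)^2 + diff(r$ta_y)^2) / dt
  expect_lte(max(ta_speed), p$ta_speed_max + 1e-9)
  pl_speed <- sqrt(diff(r$player_x)^2 + diff(r$player_y)^2) / dt
  expect_lte(max(pl_speed), p$player_speed + 1e-9)
  # away from the boundary clamp, player speeds are exactly 0, 5 or 10
  ok <- abs(pl_speed) < 1e-9 | abs(pl_speed - 5) < 1e-6 |
    abs(pl_speed - 10) < 1e-6
  expect_true(all(ok))
})

test_that("positions stay within the field bounds", {
  p <- sim_params(trial_max = 20)
  r <- run_trial(condition_design(18, "fog", "none", seed = 5), params = p)
  half <- p$field_size / 2
  expect_true(all(abs(r$ta_x) <= half + 1e-9, na.rm = TRUE))
  expect_true(all(abs(r$ta_y) <= half + 1e-9, na.rm = TRUE))
  expect_true(all(abs(r$player_x) <= half + 1e-9))
})

test_that("invalid target number is rejected naming the field", {
  expect_error(condition_design(12, "clear", "none"), "target_number")
})

test_that("parameter invariants are enforced", {
  expect_error(sim_params(containment_radius = 120), "containment_radius")
  expect_error(sim_params(success_dwell = 400), "success_dwell")
  expect_error(sim_params(tick_rate = -1), "tick_rate")
})

test_that("scripted policy: waypoint fallback, flanking, nested observation", {
  p <- sim_params()
  q <- policy_params()
  # no visible TA: heading points at the waypoint
  st <- policy_step(c(0, 0), c(30, 40), matrix(numeric(0), 0, 2),
                    params = p, policy = q)
  expect_equal(st$heading, c(3, 4) / 5, tolerance = 1e-12)
  expect_false(st$chasing)
  # TA directly on the line between player and containment centre, player on
  # the centre side: the control leaves the centre line to flank
  st <- policy_step(c(5, 0), c(0, 0), matrix(c(10, 0), 1, 2),
                    params = p, policy = q)
  expect_true(st$chasing)
  expect_gt(abs(st$heading[2]), 0.3)
  expect_lte(st$heading[1], 0) # never shoves the TA outward
  # player behind the TA (outward side): drives straight for the drive point
  st <- policy_step(c(20, 0), c(0, 0), matrix(c(10, 0), 1, 2),
                    params = p, policy = q)
  expect_lt(st$heading[1], 0)
  expect_equal(st$heading[2], 0, tolerance = 1e-9)
  # fog observation set is nested in the clear one
  set.seed(9)
  pts <- matrix(runif(40, -100, 100), 20, 2)
  fog <- visible_points(c(0, 0), pts, q$sense_fog)
  clear <- visible_points(c(0, 0), pts, q$sense_clear)
  expect_true(all(apply(fog, 1, function(row)
    any(clear[, 1] == row[1] & clear[, 2] == row[2]))))
})

test_that("trajectory and summary exports round-trip", {
  p <- sim_params(trial_max = 6)
  r <- run_trial(condition_design(9, "clear", "none", seed = 2), params = p)
  tab <- trajectory_table(r)
  expect_equal(nrow(tab), (r$n_ticks + 1) * (3 + 9))
  expect_setequal(unique(tab$role), c("ground", "target"))
  tmp <- tempfile(fileext = ".json")
  write_trial_summary_json(r, tmp)
  s <- jsonlite::read_json(tmp)
  expect_equal(s$duration, r$duration)
  expect_equal(s$seed, 2)
})
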