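unit_square <- function(dx = 0, dy = 0)
  list(x = c(0, 1, 1, 0) + dx, y = c(0, 0, 1, 1) + dy)

test_that("trajectory preprocessing: 5 Hz decimation and transient removal", {
  # 300 s at 90 Hz (initial state + 27000 ticks) -> 299 s x 5 Hz = 1495 pts
  traj <- cbind(seq_len(27001), 0)
  pts <- preprocess_trajectory(traj, tick_rate = 90)
  expect_equal(nrow(pts), 1495)
  expect_equal(pts[1, 1], 91) # first kept sample sits at t = 1 s
  expect_equal(diff(pts[1:3, 1]), c(18, 18)) # 0.2 s spacing
  # exactly 1 s of data leaves an empty set, shorter is rejected
  expect_equal(nrow(preprocess_trajectory(cbind(1:91, 0), 90)), 0)
  expect_error(preprocess_trajectory(cbind(1:80, 0), 90), "shorter")
  # a stationary avatar yields identical points
  pts <- preprocess_trajectory(matrix(5, 1000, 2), 90)
  expect_true(all(pts == 5))
})

test_that("search polygon of points in convex position is their hull", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  sp <- search_polygon(sq)
  expect_equal(sp$area, 1, tolerance = 1e-9)
  expect_equal(nrow(sp$vertices), 4)
})

test_that("alpha shape hugs concave clouds tighter than the convex hull", {
  set.seed(3)
  th <- runif(600, 0.25 * pi, 1.75 * pi) # C-shaped annulus sector
  r <- runif(600, 8, 10)
  pts <- cbind(r * cos(th), r * sin(th))
  sp <- search_polygon(pts)
  hull <- pts[grDevices::chull(pts), ]
  hull_area <- abs(herdcomm:::signed_area(hull[, 1], hull[, 2]))
  expect_equal(sp$method, "alpha_shape")
  expect_lt(sp$area, hull_area)
  # and every input point lies inside or on the polygon
  inside <- sp::point.in.polygon(pts[, 1], pts[, 2], sp$vertices[, 1],
                                 sp$vertices[, 2])
  expect_true(all(inside > 0))
})

test_that("degenerate geometry is rejected", {
  expect_error(search_polygon(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(search_polygon(cbind(1:10, 2 * (1:10))), "degenerate")
})

test_that("proportion overlap: identical, disjoint and exact rectangle cases", {
  a <- unit_square()
  expect_equal(proportion_overlap(list(a, a, a))$proportion, 1)
  far <- list(unit_square(), unit_square(5), unit_square(10))
  expect_equal(proportion_overlap(far)$proportion, 0)
  # squares at x-offsets 0 and 0.5 plus a far square: 0.5 / 2.5 = 0.2
  ov <- proportion_overlap(list(unit_square(), unit_square(0.5),
                                unit_square(8)))
  expect_equal(ov$overlap_area, 0.5, tolerance = 1e-6)
  expect_equal(ov$total_area, 2.5, tolerance = 1e-6)
  expect_equal(ov$proportion, 0.2, tolerance = 1e-6)
  # two coincident squares plus a disjoint 2 m^2 rectangle: 1 / 3
  rect <- list(x = c(2, 4, 4, 2), y = c(0, 0, 1, 1))
  ov <- proportion_overlap(list(unit_square(), unit_square(), rect))
  expect_equal(ov$proportion, 1 / 3, tolerance = 1e-6)
  # triple-covered regions are counted once
  ov <- proportion_overlap(list(unit_square(), unit_square(), unit_square(0.5)))
  expect_equal(ov$overlap_area, 1, tolerance = 1e-6)
  expect_equal(ov$proportion, 1 / 1.5, tolerance = 1e-6)
})

test_that("overlap proportion is invariant to rigid motions and lies in [0,1]", {
  set.seed(11)
  for (rep in 1:10) {
    polys <- lapply(1:3, function(i)
      random_convex_polygon(runif(2, 0, 2), runif(1, 0.5, 1.5)))
    ov <- proportion_overlap(polys)
    expect_gte(ov$proportion, 0)
    expect_lte(ov$proportion, 1)
    th <- runif(1, 0, 2 * pi)
    sh <- runif(2, -5, 5)
    moved <- lapply(polys, function(p)
      list(x = cos(th) * p$x - sin(th) * p$y + sh[1],
           y = sin(th) * p$x + cos(th) * p$y + sh[2]))
    expect_equal(proportion_overlap(moved)$proportion, ov$proportion,
                 tolerance = 1e-6)
  }
})

test_that("zero total area is rejected", {
  degenerate <- list(x = c(0, 0, 0), y = c(0, 1, 2))
  expect_error(proportion_overlap(list(degenerate, degenerate, degenerate)),
               "zero total")
})

test_that("trial overlap runs end-to-end on simulated trajectories", {
  r <- run_trial(condition_design(9, "clear", "none", seed = 21),
                 params = sim_params(trial_max = 30))
  res <- trial_overlap(r)
  expect_gte(res$overlap$proportion, 0)
  expect_lte(res$overlap$proportion, 1)
  expect_true(all(res$methods %in% c("alpha_shape", "convex_hull_fallback")))
  # alpha-shape areas never exceed the convex hull of the same points
  for (i in 1:3) {
    pts <- preprocess_trajectory(cbind(r$player_x[, i], r$player_y[, i]),
                                 tick_rate = 90)
    hull <- pts[grDevices::chull(pts), ]
    hull_area <- abs(herdcomm:::signed_area(hull[, 1], hull[, 2]))
    expect_lte(res$polygons[[i]]$area, hull_area + 1e-6)
  }
})
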