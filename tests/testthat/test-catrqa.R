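series_of <- function(codes, level = "team") {
  herdcomm:::new_cat_series(codes, level, 1:5, recoded = TRUE)
}

test_that("recurrence plot points match hand-checked examples", {
  rp <- recurrence_plot(series_of(c(1, 1)))
  expect_equal(nrow(rp$points), 2) # {(1,2),(2,1)}
  rp <- recurrence_plot(series_of(c(1, 2, 3, 4)))
  expect_equal(nrow(rp$points), 0)
  rp <- recurrence_plot(series_of(c(1, 2, 1, 2, 1, 2)))
  expect_equal(nrow(rp$points), 12)
  # symmetry: (i,j) recurrent iff (j,i) recurrent
  key <- paste(rp$points[, 1], rp$points[, 2])
  rev_key <- paste(rp$points[, 2], rp$points[, 1])
  expect_setequal(key, rev_key)
  expect_error(recurrence_plot(series_of(1L)), "length >= 2")
  raw <- herdcomm:::new_cat_series(c(0, 1, 0), "operator", 1L)
  expect_error(recurrence_plot(raw), "silence")
})

test_that("%REC: constant series 100, distinct 0, alternating 40", {
  expect_equal(percent_recurrence(recurrence_plot(series_of(rep(2, 7)))), 100)
  expect_equal(percent_recurrence(recurrence_plot(series_of(1:5))), 0)
  expect_equal(percent_recurrence(recurrence_plot(series_of(c(1, 2, 1, 2, 1, 2)))),
               100 * 12 / 30)
})

test_that("%DET: full lines, isolated points 0, alternating 100", {
  # constant series: every diagonal is one full line except the length-1
  # corner diagonals, which fall below min_line = 2
  n <- 7
  expect_equal(percent_determinism(recurrence_plot(series_of(rep(2, n)))),
               100 * (n * (n - 1) / 2 - 1) / (n * (n - 1) / 2))
  expect_equal(percent_determinism(recurrence_plot(series_of(c(1, 2, 3, 1)))), 0)
  expect_equal(percent_determinism(recurrence_plot(series_of(c(1, 2, 1, 2, 1, 2)))),
               100)
  expect_error(percent_determinism(recurrence_plot(series_of(c(1, 1))),
                                   min_line = 1), "min_line")
})

test_that("fast path, point-set path and brute-force oracle all agree", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(2:120, 1)
    codes <- sample.int(sample(1:6, 1), n, replace = TRUE)
    ora <- oracle_rqa(codes)
    fast <- rqa_stats(codes)
    expect_equal(fast$n_recurrent, ora$n_recurrent)
    expect_equal(fast$pct_rec, ora$pct_rec)
    expect_equal(fast$pct_det, ora$pct_det)
    rp <- recurrence_plot(series_of(codes))
    expect_equal(nrow(rp$points), ora$n_recurrent)
    expect_equal(percent_recurrence(rp), ora$pct_rec)
    expect_equal(percent_determinism(rp), ora$pct_det)
  }
})

test_that("line-length histogram matches the oracle", {
  set.seed(5)
  for (rep in 1:20) {
    codes <- sample.int(3, sample(10:80, 1), replace = TRUE)
    ora <- oracle_rqa(codes)
    fast <- rqa_stats(codes)
    expect_equal(sort(rep(fast$line_lengths, fast$line_counts)),
                 ora$line_lengths)
  }
})

test_that("appending a recurring code never decreases the recurrent count", {
  set.seed(41)
  for (rep in 1:20) {
    codes <- sample.int(4, 30, replace = TRUE)
    longer <- c(codes, sample(codes, 1))
    expect_gte(rqa_stats(longer)$n_recurrent, rqa_stats(codes)$n_recurrent)
  }
})

test_that("catrqa_trial composes coding, recoding and statistics", {
  # all silent: recoded codes never recur
  a <- make_activity(rep(0, 60), rep(0, 60), rep(0, 60), rep(0, 60))
  for (lv in c("operator", "ground", "team")) {
    r <- catrqa_trial(a, lv)
    expect_equal(r$pct_rec, 0)
    expect_equal(r$pct_det, 0)
  }
  # a single speaker talking continuously: every cell recurs
  b <- make_activity(rep(1, 60), rep(0, 60), rep(0, 60), rep(0, 60))
  expect_equal(catrqa_trial(b, "operator")$pct_rec, 100)
  expect_equal(catrqa_trial(b, "team")$pct_rec, 100)
})

test_that("independent-speaker %REC tracks the analytic match probability", {
  # with iid-ish frames, %REC converges to 100 * sum_c p_c^2 over the
  # speaking codes (silence never recurs after recoding)
  p <- speech_params(coupling = 0, response_hazard_boost = 0,
                     jitter_sd_scale = 0)
  set.seed(13)
  recs <- replicate(40, {
    a <- generate_activity(300, proportions = c(0.25, 0, 0, 0), params = p,
                           mean_on = rep(0.2, 4))
    catrqa_trial(a, "operator")$pct_rec
  })
  expect_equal(mean(recs), 100 * 0.25^2, tolerance = 0.1)
})
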