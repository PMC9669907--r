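test_that("all seven F statistics match the aov error-strata oracle", {
  set.seed(101)
  for (rep in 1:5) {
    tab <- random_design_table(n_teams = 8)
    res <- rm_anova_2x2x2(tab)
    ora <- oracle_rm_anova_aov(tab)
    for (i in seq_len(nrow(res))) {
      expect_equal(res$F[i], unname(ora[aov_effect_name(res$effect[i])]),
                   tolerance = 1e-10)
    }
  }
})

test_that("two-level within factor: F equals the squared paired t", {
  set.seed(55)
  tab <- random_design_table(n_teams = 10)
  res <- rm_anova_2x2x2(tab)
  agg <- aggregate(value ~ team_id + visibility, tab, mean)
  agg <- agg[order(agg$visibility, agg$team_id), ]
  fog <- agg$value[agg$visibility == "fog"]
  clr <- agg$value[agg$visibility == "clear"]
  tt <- t.test(fog, clr, paired = TRUE)
  expect_equal(res$F[res$effect == "visibility"], unname(tt$statistic)^2,
               tolerance = 1e-8)
  expect_equal(res$p[res$effect == "visibility"], tt$p.value,
               tolerance = 1e-8)
})

test_that("a factor with identical level values has F = 0 and epsilon is 1", {
  set.seed(77)
  tab <- random_design_table(n_teams = 6)
  # force perturbation levels identical within team x (A,B)
  for (t in unique(tab$team_id)) {
    for (a in c(9, 18)) for (b in c("clear", "fog")) {
      i <- tab$team_id == t & tab$target_number == a & tab$visibility == b
      tab$value[i] <- mean(tab$value[i])
    }
  }
  res <- rm_anova_2x2x2(tab)
  expect_equal(res$F[res$effect == "perturbation"], 0)
  expect_true(all(res$epsilon_GG == 1))
  expect_true(all(res$p_corrected == res$p))
})

test_that("partial eta squared identity holds for every effect", {
  set.seed(3)
  tab <- random_design_table(n_teams = 9)
  res <- rm_anova_2x2x2(tab)
  expect_equal(res$partial_eta_sq,
               res$F * res$df_num / (res$F * res$df_num + res$df_den))
})

test_that("incomplete designs are rejected naming the hole", {
  tab <- random_design_table(n_teams = 4)
  tab <- tab[-5, ]
  expect_error(rm_anova_2x2x2(tab), "missing cell for team")
  expect_error(rm_anova_2x2x2(random_design_table(1)), "2 teams")
})

test_that("visibility shift of one within-team SD is detected reliably", {
  set.seed(202)
  hits <- mean(replicate(200, {
    tab <- random_design_table(n_teams = 10, sd_team = 1, sd_noise = 1,
                               shift = 1)
    res <- rm_anova_2x2x2(tab)
    res$p[res$effect == "visibility"] < 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("mixed regression collapses to OLS when teams are homogeneous", {
  set.seed(9)
  n <- 120
  dat <- data.frame(team_id = rep(1:6, each = 20),
                    target_number = rep(c(9, 18), n / 2),
                    visibility = rep(c("clear", "fog"), each = 2,
                                     length.out = n),
                    perturbation = rep(c("none", "late_spawn"),
                                       length.out = n),
                    z = rnorm(n))
  dat$y <- 1 + 0.5 * dat$z + rnorm(n) # no team effect in truth
  fit <- mixed_regression(dat, "y", "z")
  ols <- lm(y ~ target_number * visibility * perturbation + z, data = dat)
  expect_equal(fit$beta_z, unname(coef(ols)["z"]), tolerance = 1e-6)
  expect_true(fit$ci95[1] <= fit$beta_z && fit$beta_z <= fit$ci95[2])
})

test_that("a perfectly predictive term has a huge f2 and tight CI", {
  set.seed(10)
  dat <- data.frame(team_id = rep(1:4, each = 16),
                    target_number = rep(c(9, 18), 32),
                    visibility = rep(c("clear", "fog"), each = 2,
                                     length.out = 64),
                    perturbation = "none",
                    z = rnorm(64))
  dat$y <- 2 * dat$z
  fit <- mixed_regression(dat, "y", "z",
                          covariates = c("target_number", "visibility"))
  expect_equal(fit$beta_z, 2, tolerance = 1e-6)
  expect_lt(fit$ci95[2] - fit$ci95[1], 1e-4)
  expect_gt(fit$cohens_f2, 100)
})

test_that("degenerate communication measures are rejected", {
  dat <- data.frame(team_id = rep(1:2, each = 4),
                    target_number = 9, visibility = "fog",
                    perturbation = "none", z = 1, y = rnorm(8))
  expect_error(mixed_regression(dat, "y", "z"), "zero variance")
})

test_that("bonferroni adjustment is min(1, m p)", {
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(0.2), 0.2)
  expect_equal(bonferroni(c(0.7, 1)), c(1, 1))
  expect_error(bonferroni(c(-0.1, 0.5)), "\\[0, 1\\]")
})
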