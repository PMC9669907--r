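#' 2x2x2 repeated-measures ANOVA
#'
#' Within-subjects factorial ANOVA over teams for the three two-level task
#' factors (target number, visibility, perturbation). Each of the seven
#' effects (three mains, three two-way, one three-way) is tested against its
#' own effect-by-team error stratum; for two-level factors this reduces to a
#' paired t-test on the per-team effect contrast, so F = t^2 with
#' df = (1, n - 1). Sphericity is vacuous with two levels, hence every
#' Greenhouse--Geisser epsilon is 1 and the corrected p equals the raw p.
#' Partial eta squared is `F df_num / (F df_num + df_den)`.
#'
#' If a team has several trials in a cell they are first averaged to one
#' value per team x cell; a missing cell is an error naming the team and
#' cell.
#'
#' @param table data.frame with columns `team_id`, `target_number`,
#'   `visibility`, `perturbation` and `value`.
#' @return An `effect_table` data.frame with one row per effect: `effect`,
#'   `F`, `df_num`, `df_den`, `epsilon_GG`, `p`, `p_corrected`,
#'   `partial_eta_sq`.
#' @export
rm_anova_2x2x2 <- function(table) {
  need <- c("team_id", "target_number", "visibility", "perturbation",
            "value")
  if (!all(need %in% names(table)))
    stop("rm_anova_2x2x2: table must have columns ",
         paste(need, collapse = ", "))
  agg <- aggregate(value ~ team_id + target_number + visibility +
                     perturbation, data = table, FUN = mean)
  teams <- sort(unique(agg$team_id))
  n <- length(teams)
  if (n < 2) stop("rm_anova_2x2x2: need at least 2 teams")
  cells <- expand.grid(target_number = sort(unique(agg$target_number)),
                       visibility = sort(unique(agg$visibility)),
                       perturbation = sort(unique(agg$perturbation)),
                       stringsAsFactors = FALSE)
  if (nrow(cells) != 8)
    stop("rm_anova_2x2x2: design must be a complete 2x2x2 factorial")
  # one value per team x cell, errors naming any hole
  y <- matrix(NA_real_, n, 8)
  for (ci in seq_len(8)) {
    for (ti in seq_len(n)) {
      v <- agg$value[agg$team_id == teams[ti] &
                       agg$target_number == cells$target_number[ci] &
                       agg$visibility == cells$visibility[ci] &
                       agg$perturbation == cells$perturbation[ci]]
      if (length(v) != 1)
        stop("rm_anova_2x2x2: missing cell for team ", teams[ti], ", (",
             cells$target_number[ci], ", ", cells$visibility[ci], ", ",
             cells$perturbation[ci], ")")
      y[ti, ci] <- v
    }
  }
  sA <- ifelse(cells$target_number == max(cells$target_number), 1, -1)
  sB <- ifelse(cells$visibility == max(cells$visibility), 1, -1)
  sC <- ifelse(cells$perturbation == max(cells$perturbation), 1, -1)
  effects <- list(target_number = sA, visibility = sB, perturbation = sC,
                  `target_number:visibility` = sA * sB,
                  `target_number:perturbation` = sA * sC,
                  `visibility:perturbation` = sB * sC,
                  `target_number:visibility:perturbation` = sA * sB * sC)
  # contrasts smaller than accumulated rounding error count as exactly null
  tol2 <- (1e-10 * max(abs(y), 1))^2
  rows <- lapply(names(effects), function(nm) {
    d <- drop(y %*% effects[[nm]]) / 4 # per-team effect contrast
    m <- mean(d)
    v <- var(d)
    f <- if (m^2 <= tol2 && v <= tol2) 0
         else if (v <= 0) Inf
         else n * m^2 / v
    p <- pf(f, 1, n - 1, lower.tail = FALSE)
    data.frame(effect = nm, F = f, df_num = 1, df_den = n - 1,
               epsilon_GG = 1, p = p, p_corrected = p,
               partial_eta_sq = f / (f + (n - 1)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_table", class(out))
  out
}

#' Random-intercept mixed regression of performance on communication
#'
#' Fits `y ~ target_number * visibility * perturbation + z + (1 | team)` by
#' maximum likelihood and reports the communication coefficient `beta_z`
#' with its Wald z statistic and 95% CI, the team and residual variances,
#' and Cohen's f^2 for the communication term: `(R2_full - R2_reduced) /
#' (1 - R2_full)` where R^2 is the squared correlation between fitted and
#' observed values and the reduced model omits `z`.
#'
#' @param data data.frame with per-trial rows.
#' @param outcome column name of the dependent variable.
#' @param z column name of the communication measure of interest.
#' @param covariates character vector of design covariate column names
#'   (crossed with `*`).
#' @param team column name of the team identifier.
#' @return An object of class `mixed_model_result`.
#' @export
mixed_regression <- function(data, outcome, z,
                             covariates = c("target_number", "visibility",
                                            "perturbation"),
                             team = "team_id") {
  stopifnot(all(c(outcome, z, covariates, team) %in% names(data)))
  if (length(unique(data[[team]])) < 2)
    stop("mixed_regression: need at least 2 teams")
  if (var(data[[z]]) == 0)
    stop("mixed_regression: communication measure '", z,
         "' has zero variance")
  fixed <- paste(covariates, collapse = " * ")
  f_full <- as.formula(paste0(outcome, " ~ ", fixed, " + ", z, " + (1 | ",
                              team, ")"))
  f_red <- as.formula(paste0(outcome, " ~ ", fixed, " + (1 | ", team, ")"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(f_full, data = data, REML = FALSE)))
  fit_red <- suppressWarnings(suppressMessages(
    lme4::lmer(f_red, data = data, REML = FALSE)))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  beta <- unname(fe[z])
  se_z <- unname(se[names(fe) == z])
  zstat <- beta / se_z
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se_z
  yv <- data[[outcome]]
  r2_full <- cor(fitted(fit), yv)^2
  r2_red <- cor(fitted(fit_red), yv)^2
  f2 <- (r2_full - r2_red) / (1 - r2_full)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(beta_z = beta, se = se_z, z = zstat,
                 p = 2 * pnorm(-abs(zstat)), ci95 = ci, cohens_f2 = f2,
                 intercept = unname(fe["(Intercept)"]), fixef = fe,
                 var_team = vc$vcov[vc$grp == team],
                 var_residual = vc$vcov[vc$grp == "Residual"],
                 r2_full = r2_full, r2_reduced = r2_red,
                 outcome = outcome, term = z, model = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "<mixed_model_result> %s ~ ... + %s: beta=%.4g (SE %.3g, z=%.2f, p=%.3g)\n",
    x$outcome, x$term, x$beta_z, x$se, x$z, x$p))
  cat(sprintf("  95%% CI [%.4g, %.4g]; Cohen's f2 = %.3g\n", x$ci95[1],
              x$ci95[2], x$cohens_f2))
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, m p)` for each of m p-values (via [stats::p.adjust()]).
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals) {
  if (any(pvals < 0 | pvals > 1)) stop("bonferroni: p-values must be in [0, 1]")
  p.adjust(pvals, method = "bonferroni")
}
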