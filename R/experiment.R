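#' Configuration of a full synthetic study
#'
#' A study is `n_teams` teams each completing `trials_per_cell` trials in
#' every cell of the 2x2x2 design (the defaults reproduce the session
#' structure of the modelled experiment: 10 teams x 8 conditions x 2 blocks
#' = 160 trials). Per-trial child seeds are derived arithmetically from
#' `master_seed`, team, cell and repetition, so any single trial can be
#' replayed without running the others.
#'
#' @param n_teams number of teams (>= 2; the repeated-measures ANOVA needs
#'   at least two).
#' @param trials_per_cell trials per team per design cell (>= 1).
#' @param sim [sim_params()]; @param speech [speech_params()];
#' @param policy [policy_params()].
#' @param master_seed integer master seed.
#' @param shared_trial_order if `TRUE` all teams play the same seeded-random
#'   trial order; otherwise each team gets its own shuffle.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_teams = 10, trials_per_cell = 2,
                              sim = sim_params(), speech = speech_params(),
                              policy = policy_params(), master_seed = 1,
                              shared_trial_order = TRUE) {
  if (!is.numeric(n_teams) || n_teams < 2)
    stop("experiment_config: 'n_teams' must be >= 2")
  if (!is.numeric(trials_per_cell) || trials_per_cell < 1)
    stop("experiment_config: 'trials_per_cell' must be >= 1")
  stopifnot(inherits(sim, "sim_params"), inherits(speech, "speech_params"),
            inherits(policy, "policy_params"))
  structure(list(n_teams = as.integer(n_teams),
                 trials_per_cell = as.integer(trials_per_cell), sim = sim,
                 speech = speech, policy = policy,
                 master_seed = as.integer(master_seed),
                 shared_trial_order = isTRUE(shared_trial_order)),
            class = "experiment_config")
}

#' Order-independent child seed for one trial
#'
#' Deterministic arithmetic hash of (master seed, team, cell, repetition)
#' into `[1, 2^31 - 2]`; trial k's seed never depends on execution order.
#'
#' @param master_seed,team,cell,rep integers.
#' @return Integer seed.
#' @export
derive_seed <- function(master_seed, team, cell, rep) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master_seed) %% m) * 69069 + team * 1664525 +
    cell * 22695477 + rep * 1013904223
  as.integer(x %% (m - 1)) + 1L
}

#' Read an experiment configuration from JSON
#'
#' The file may set any subset of the top-level fields (`n_teams`,
#' `trials_per_cell`, `master_seed`, `shared_trial_order`) and any subset of
#' the `sim`, `policy` and `speech` parameter blocks; omitted fields take
#' the package defaults.
#'
#' @param path JSON file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(block, ctor) {
    args <- cfg[[block]]
    if (is.null(args)) return(ctor())
    known <- names(formals(ctor))
    do.call(ctor, args[intersect(names(args), known)])
  }
  experiment_config(
    n_teams = if (is.null(cfg$n_teams)) 10 else cfg$n_teams,
    trials_per_cell = if (is.null(cfg$trials_per_cell)) 2 else
      cfg$trials_per_cell,
    sim = pick("sim", sim_params),
    speech = pick("speech", speech_params),
    policy = pick("policy", policy_params),
    master_seed = if (is.null(cfg$master_seed)) 1 else cfg$master_seed,
    shared_trial_order = if (is.null(cfg$shared_trial_order)) TRUE else
      cfg$shared_trial_order)
}

design_cells <- function() {
  expand.grid(target_number = c(9L, 18L), visibility = c("clear", "fog"),
              perturbation = c("none", "late_spawn"),
              stringsAsFactors = FALSE)
}

#' Simulate and measure a full synthetic study
#'
#' For every team and every repetition of every cell of the 2x2x2 design:
#' simulates the herding trial, generates the matching four-speaker speaking
#' series for the realised trial duration, and computes the per-trial
#' metrics (duration, containment rate, talk-time magnitudes, search-area
#' overlap, and %REC/%DET at the operator, ground and team levels). The
#' whole bundle is deterministic given `master_seed`.
#'
#' @param config an [experiment_config()].
#' @param progress print a line per team.
#' @return An object of class `herdcomm_experiment`: `trials` (one tidy row
#'   per trial, with seed and presentation order) and the `config`.
#' @export
run_experiment <- function(config = experiment_config(), progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cells <- design_cells()
  rows <- list()
  set.seed(derive_seed(config$master_seed, 0, 0, 0))
  shared_order <- sample(nrow(cells) * config$trials_per_cell)
  for (team in seq_len(config$n_teams)) {
    if (config$shared_trial_order) {
      order_idx <- shared_order
    } else {
      set.seed(derive_seed(config$master_seed, team, 99, 0))
      order_idx <- sample(nrow(cells) * config$trials_per_cell)
    }
    k <- 0
    for (rep in seq_len(config$trials_per_cell)) {
      for (ci in seq_len(nrow(cells))) {
        k <- k + 1
        seed <- derive_seed(config$master_seed, team, ci, rep)
        design <- condition_design(cells$target_number[ci],
                                   cells$visibility[ci],
                                   cells$perturbation[ci],
                                   trial_id = k, team_id = team, seed = seed)
        record <- run_trial(design, params = config$sim,
                            policy = config$policy)
        activity <- generate_activity(record$duration, design,
                                      params = config$speech, seed = seed)
        row <- trial_metrics(record, activity)
        row$order <- order_idx[k]
        rows[[length(rows) + 1]] <- row
      }
    }
    if (progress)
      message("team ", team, "/", config$n_teams, " done")
  }
  trials <- do.call(rbind, rows)
  trials <- trials[order(trials$team_id, trials$order), ]
  rownames(trials) <- NULL
  structure(list(trials = trials, config = config),
            class = "herdcomm_experiment")
}

#' @export
print.herdcomm_experiment <- function(x, ...) {
  cat(sprintf(
    "<herdcomm_experiment> %d teams x %d trials (%d rows); %.0f%% success\n",
    x$config$n_teams, nrow(x$trials) / x$config$n_teams, nrow(x$trials),
    100 * mean(x$trials$success)))
  invisible(x)
}

experiment_measures <- function() {
  c("duration", "containment_rate", "talk_operator", "talk_ground",
    "overlap_proportion", "rec_operator", "det_operator", "rec_ground",
    "det_ground", "rec_team", "det_team")
}

#' Condition-level summary tables
#'
#' Mean, SD and standard error of every per-trial measure within each cell
#' of the 2x2x2 design, in long format (one row per measure x cell). The SE
#' is over trials; with a single trial per cell it is reported as missing.
#'
#' @param experiment a [run_experiment()] result (or its `trials`
#'   data.frame).
#' @return Long-format data.frame (measure, target_number, visibility,
#'   perturbation, mean, sd, se, n).
#' @export
summarize_experiment <- function(experiment) {
  trials <- if (inherits(experiment, "herdcomm_experiment"))
    experiment$trials else experiment
  out <- list()
  for (m in experiment_measures()) {
    agg <- aggregate(trials[[m]],
                     by = list(target_number = trials$target_number,
                               visibility = trials$visibility,
                               perturbation = trials$perturbation),
                     FUN = function(v) c(mean = mean(v), sd = sd(v),
                                         n = length(v)))
    x <- as.data.frame(agg$x)
    out[[m]] <- data.frame(measure = m, agg[1:3], mean = x$mean, sd = x$sd,
                           se = ifelse(x$n > 1, x$sd / sqrt(x$n), NA_real_),
                           n = x$n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full inferential analysis of a synthetic study
#'
#' Runs the 2x2x2 repeated-measures ANOVA for every per-trial measure
#' (per-team cell means) and the random-intercept mixed regressions of each
#' performance outcome on each communication measure.
#'
#' @param experiment a [run_experiment()] result.
#' @param regression_outcomes performance outcomes for the mixed models.
#' @param regression_terms communication predictors for the mixed models.
#' @return list with `anova` (named list of `effect_table`s) and
#'   `regressions` (named list of `mixed_model_result`s, names
#'   `outcome~term`).
#' @export
analyze_experiment <- function(experiment,
                               regression_outcomes = c("duration",
                                                       "containment_rate"),
                               regression_terms = c("talk_operator",
                                                    "talk_ground",
                                                    "rec_ground",
                                                    "det_ground",
                                                    "rec_team")) {
  trials <- if (inherits(experiment, "herdcomm_experiment"))
    experiment$trials else as.data.frame(experiment)
  anovas <- lapply(setNames(nm = experiment_measures()), function(m) {
    tab <- trials[, c("team_id", "target_number", "visibility",
                      "perturbation")]
    tab$value <- trials[[m]]
    rm_anova_2x2x2(tab)
  })
  regs <- list()
  for (yv in regression_outcomes) {
    for (zv in regression_terms) {
      if (var(trials[[yv]]) == 0 || var(trials[[zv]]) == 0) {
        warning("analyze_experiment: skipping ", yv, " ~ ", zv,
                " (zero variance)")
        next
      }
      regs[[paste0(yv, "~", zv)]] <-
        mixed_regression(trials, outcome = yv, z = zv)
    }
  }
  list(anova = anovas, regressions = regs)
}

#' Write the study bundle to a directory
#'
#' Writes `trials.csv`, `summary.csv`, per-measure ANOVA tables
#' (`anova_<measure>.csv`), a regression table (`regressions.csv`) and the
#' configuration echo (`config.json`).
#'
#' @param experiment a [run_experiment()] result.
#' @param dir output directory (created if missing).
#' @param analysis optionally a precomputed [analyze_experiment()] result.
#' @return The directory, invisibly.
#' @export
write_experiment <- function(experiment, dir, analysis = NULL) {
  stopifnot(inherits(experiment, "herdcomm_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(experiment$trials, file.path(dir, "trials.csv"),
            row.names = FALSE)
  write.csv(summarize_experiment(experiment), file.path(dir, "summary.csv"),
            row.names = FALSE)
  if (is.null(analysis))
    analysis <- suppressWarnings(analyze_experiment(experiment))
  for (m in names(analysis$anova))
    write.csv(analysis$anova[[m]], file.path(dir, paste0("anova_", m,
                                                         ".csv")),
              row.names = FALSE)
  regs <- do.call(rbind, lapply(names(analysis$regressions), function(nm) {
    r <- analysis$regressions[[nm]]
    data.frame(model = nm, outcome = r$outcome, term = r$term,
               beta = r$beta_z, se = r$se, z = r$z, p = r$p,
               ci_lo = r$ci95[1], ci_hi = r$ci95[2],
               cohens_f2 = r$cohens_f2, var_team = r$var_team,
               var_residual = r$var_residual)
  }))
  if (is.null(regs))
    regs <- data.frame(model = character(), outcome = character(),
                       term = character(), beta = numeric())
  write.csv(regs, file.path(dir, "regressions.csv"), row.names = FALSE)
  cfg <- experiment$config
  jsonlite::write_json(
    list(schema_version = 1L, n_teams = cfg$n_teams,
         trials_per_cell = cfg$trials_per_cell,
         master_seed = cfg$master_seed,
         shared_trial_order = cfg$shared_trial_order,
         sim = unclass(cfg$sim), policy = unclass(cfg$policy),
         speech = unclass(cfg$speech)[setdiff(names(cfg$speech),
                                              "targets")]),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
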