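#' Containment rate of a trial
#'
#' TAs contained at the end of the trial divided by the trial duration
#' (TAs per second); higher is better. Failed trials use the 300 s ceiling
#' as the duration, and all completed trials -- successful or not -- enter
#' the analysis.
#'
#' @param record a [run_trial()] result (or any list with
#'   `contained_at_end` and `duration`).
#' @return Containment rate, TAs/s.
#' @export
containment_rate <- function(record) {
  if (is.null(record$duration) || record$duration <= 0)
    stop("containment_rate: positive 'duration' required")
  record$contained_at_end / record$duration
}

#' Talk-time proportion of a role within one trial
#'
#' Fraction of frames a participant spent speaking. For the `"ground"` role
#' the three per-player proportions are averaged into a single value.
#'
#' @param activity a `speaker_activity`.
#' @param role `"operator"`, `"ground"`, or a single channel `"gp1"`..`"gp3"`.
#' @return Proportion in `[0, 1]`.
#' @export
talk_proportion <- function(activity,
                            role = c("operator", "ground", "gp1", "gp2",
                                     "gp3")) {
  stopifnot(inherits(activity, "speaker_activity"))
  role <- match.arg(role)
  if (nrow(activity$frames) == 0)
    stop("talk_proportion: empty speaking series")
  if (role == "ground")
    return(mean(colMeans(activity$frames[, c("gp1", "gp2", "gp3"),
                                         drop = FALSE])))
  mean(activity$frames[, role])
}

#' Scalar per-trial metrics row
#'
#' Joins the simulator, speech, recurrence and overlap outputs of one trial
#' into a single tidy row.
#'
#' @param record a [run_trial()] result.
#' @param activity the trial's `speaker_activity`.
#' @param overlap optionally a precomputed [trial_overlap()] result.
#' @param min_line minimum diagonal line length for the recurrence measures.
#' @return One-row data.frame with design echo, duration, success,
#'   containment rate, talk proportions, overlap proportion, and %REC/%DET
#'   at the operator, ground and team levels.
#' @export
trial_metrics <- function(record, activity, overlap = NULL, min_line = 2) {
  stopifnot(inherits(record, "trial_record"),
            inherits(activity, "speaker_activity"))
  if (is.null(overlap)) overlap <- trial_overlap(record)
  rqa <- lapply(c(operator = "operator", ground = "ground", team = "team"),
                function(lv) catrqa_trial(activity, lv, min_line = min_line))
  data.frame(team_id = record$design$team_id,
             trial_id = record$design$trial_id,
             target_number = record$design$target_number,
             visibility = record$design$visibility,
             perturbation = record$design$perturbation,
             seed = record$seed,
             duration = record$duration,
             success = record$success,
             contained_at_end = record$contained_at_end,
             containment_rate = containment_rate(record),
             talk_operator = talk_proportion(activity, "operator"),
             talk_ground = talk_proportion(activity, "ground"),
             overlap_proportion = overlap$overlap$proportion,
             overlap_area_m2 = overlap$overlap$overlap_area,
             total_area_m2 = overlap$overlap$total_area,
             rec_operator = rqa$operator$pct_rec,
             det_operator = rqa$operator$pct_det,
             rec_ground = rqa$ground$pct_rec,
             det_ground = rqa$ground$pct_det,
             rec_team = rqa$team$pct_rec,
             det_team = rqa$team$pct_det)
}
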