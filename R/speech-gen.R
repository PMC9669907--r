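#' Default condition-dependent talk-time targets
#'
#' Per-role mean talk proportions (with between-trial SDs) for every cell of
#' the 2x2x2 design. The operator talks much more under fog (where ground
#' players depend on spoken guidance) while ground-player proportions sit
#' near 0.2 throughout, slightly lower under fog.
#'
#' @return data.frame with columns role ("operator"/"ground"), visibility,
#'   target_number, perturbation, talk (mean proportion) and sd.
#' @export
default_talk_targets <- function() {
  g <- expand.grid(role = c("operator", "ground"),
                   perturbation = c("late_spawn", "none"),
                   visibility = c("fog", "clear"),
                   target_number = c(9L, 18L),
                   stringsAsFactors = FALSE)
  key <- paste(g$role, g$perturbation, g$visibility, g$target_number)
  talk <- c(
    "operator late_spawn fog 9"    = 0.59, "operator late_spawn fog 18"   = 0.63,
    "operator late_spawn clear 9"  = 0.49, "operator late_spawn clear 18" = 0.22,
    "operator none fog 9"          = 0.63, "operator none fog 18"         = 0.64,
    "operator none clear 9"        = 0.51, "operator none clear 18"       = 0.47,
    "ground late_spawn fog 9"      = 0.20, "ground late_spawn fog 18"     = 0.19,
    "ground late_spawn clear 9"    = 0.22, "ground late_spawn clear 18"   = 0.24,
    "ground none fog 9"            = 0.19, "ground none fog 18"           = 0.20,
    "ground none clear 9"          = 0.21, "ground none clear 18"         = 0.24)
  sds <- c(
    "operator late_spawn fog 9"    = 0.11, "operator late_spawn fog 18"   = 0.11,
    "operator late_spawn clear 9"  = 0.14, "operator late_spawn clear 18" = 0.10,
    "operator none fog 9"          = 0.11, "operator none fog 18"         = 0.11,
    "operator none clear 9"        = 0.15, "operator none clear 18"       = 0.16,
    "ground late_spawn fog 9"      = 0.08, "ground late_spawn fog 18"     = 0.08,
    "ground late_spawn clear 9"    = 0.10, "ground late_spawn clear 18"   = 0.11,
    "ground none fog 9"            = 0.08, "ground none fog 18"           = 0.08,
    "ground none clear 9"          = 0.10, "ground none clear 18"         = 0.11)
  g$talk <- unname(talk[key])
  g$sd <- unname(sds[key])
  g
}

#' Speech generator parameters
#'
#' The generator is a coupled alternating-renewal (on/off) process per
#' speaker at `frame_rate` Hz with geometric dwell times, so a speaker with
#' mean on-duration `m_on` and target talk proportion `p` has mean
#' off-duration `m_on (1 - p) / p` and converges to `p` in the long run.
#' `coupling` multiplies a silent speaker's onset hazard by `(1 - coupling)`
#' while any other speaker is active (turn-taking inhibition);
#' `response_hazard_boost` multiplies ground-player onset hazards by
#' `(1 + boost)` for `boost_window` seconds after the operator stops
#' speaking, giving conversations an instruction-response structure.
#'
#' Mean utterance lengths are role- and visibility-dependent: under fog the
#' operator produces longer directive utterances (`mean_on_operator_fog`)
#' than under clear visibility, which lengthens speaking runs and with them
#' the diagonal-line structure recurrence analysis picks up.
#'
#' @param frame_rate frames per second of the binary series.
#' @param targets per-condition talk-time targets, see
#'   [default_talk_targets()].
#' @param mean_on_operator_clear,mean_on_operator_fog,mean_on_ground mean
#'   utterance (on) durations, s.
#' @param coupling turn-taking inhibition in `[0, 1]`.
#' @param response_hazard_boost ground-player onset boost after operator
#'   offsets (>= 0).
#' @param boost_window length of the response window, s.
#' @param jitter_sd_scale multiplier on the per-condition SDs used as
#'   between-trial jitter of the talk targets (0 disables jitter).
#' @return An object of class `speech_params`.
#' @export
speech_params <- function(frame_rate = 30, targets = default_talk_targets(),
                          mean_on_operator_clear = 1.2,
                          mean_on_operator_fog = 2.0, mean_on_ground = 0.8,
                          coupling = 0.3, response_hazard_boost = 1.0,
                          boost_window = 1.0, jitter_sd_scale = 1.0) {
  if (frame_rate <= 0) stop("speech_params: 'frame_rate' must be positive")
  if (coupling < 0 || coupling > 1)
    stop("speech_params: 'coupling' must be in [0, 1]")
  if (min(mean_on_operator_clear, mean_on_operator_fog, mean_on_ground) <= 0)
    stop("speech_params: mean on-durations must be positive")
  if (any(targets$talk < 0 | targets$talk > 1))
    stop("speech_params: talk targets must be proportions in [0, 1]")
  structure(list(frame_rate = frame_rate, targets = targets,
                 mean_on_operator_clear = mean_on_operator_clear,
                 mean_on_operator_fog = mean_on_operator_fog,
                 mean_on_ground = mean_on_ground, coupling = coupling,
                 response_hazard_boost = response_hazard_boost,
                 boost_window = boost_window,
                 jitter_sd_scale = jitter_sd_scale),
            class = "speech_params")
}

lookup_talk_target <- function(targets, role, condition) {
  i <- targets$role == role & targets$visibility == condition$visibility &
    targets$target_number == condition$target_number &
    targets$perturbation == condition$perturbation
  if (sum(i) != 1)
    stop("speech_params: no unique talk target for role '", role, "'")
  list(talk = targets$talk[i], sd = targets$sd[i])
}

#' Generate per-speaker binary speaking series for one trial
#'
#' Simulates frame-aligned 0/1 speaking series for the operator and the
#' three ground players. Per-speaker talk proportions are either looked up
#' from the condition (with optional truncated-normal between-trial jitter)
#' or supplied directly through `proportions`.
#'
#' @param duration trial duration, s (> 0).
#' @param condition [condition_design()]; may be `NULL` when `proportions`
#'   is given.
#' @param params [speech_params()].
#' @param seed optional integer seed.
#' @param proportions optional length-4 numeric (operator, gp1, gp2, gp3)
#'   overriding the condition lookup; values must lie in `[0, 1)` (a target
#'   of 1 is unreachable with a finite off-time and is rejected).
#' @param mean_on optional length-4 override of mean on-durations, s.
#' @return An object of class `speaker_activity`: integer matrix `frames`
#'   (`ceiling(duration * frame_rate)` rows; columns operator, gp1, gp2,
#'   gp3), `frame_rate`, and `duration`.
#' @export
generate_activity <- function(duration, condition = NULL,
                              params = speech_params(), seed = NULL,
                              proportions = NULL, mean_on = NULL) {
  stopifnot(inherits(params, "speech_params"))
  if (!is.numeric(duration) || duration <= 0)
    stop("generate_activity: 'duration' must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(proportions)) {
    if (is.null(condition))
      stop("generate_activity: supply 'condition' or 'proportions'")
    op <- lookup_talk_target(params$targets, "operator", condition)
    gp <- lookup_talk_target(params$targets, "ground", condition)
    jit <- function(tg) {
      if (params$jitter_sd_scale == 0) return(tg$talk)
      p <- rnorm(1, tg$talk, tg$sd * params$jitter_sd_scale)
      min(max(p, 0.01), 0.95)
    }
    proportions <- c(jit(op), jit(gp), jit(gp), jit(gp))
  }
  if (length(proportions) != 4 || any(proportions < 0))
    stop("generate_activity: 'proportions' must be 4 values in [0, 1)")
  if (any(proportions >= 1))
    stop("generate_activity: a talk proportion of 1 is unreachable with a ",
         "finite off-time")
  if (is.null(mean_on)) {
    m_op <- if (!is.null(condition) && condition$visibility == "fog")
      params$mean_on_operator_fog else params$mean_on_operator_clear
    mean_on <- c(m_op, rep(params$mean_on_ground, 3))
  }
  n <- as.integer(ceiling(duration * params$frame_rate))
  frames <- cpp_generate_activity(n, as.numeric(proportions),
                                  as.numeric(mean_on), params$coupling,
                                  params$response_hazard_boost,
                                  params$boost_window, params$frame_rate)
  colnames(frames) <- c("operator", "gp1", "gp2", "gp3")
  structure(list(frames = frames, frame_rate = params$frame_rate,
                 duration = duration),
            class = "speaker_activity")
}

#' Construct a speaker-activity object from binary frame data
#'
#' Wraps an existing frame-aligned 0/1 matrix (e.g. imported voice-activity
#' detection output) in the container the coding and recurrence functions
#' consume. Columns are taken in the order operator, gp1, gp2, gp3.
#'
#' @param frames matrix or data.frame with 4 binary columns.
#' @param frame_rate frames per second.
#' @return A `speaker_activity` object.
#' @export
speaker_activity <- function(frames, frame_rate = 30) {
  frames <- as.matrix(frames)
  if (ncol(frames) != 4 || !all(frames %in% c(0L, 1L)))
    stop("speaker_activity: 'frames' must be a 4-column binary matrix")
  storage.mode(frames) <- "integer"
  colnames(frames) <- c("operator", "gp1", "gp2", "gp3")
  structure(list(frames = frames, frame_rate = frame_rate,
                 duration = nrow(frames) / frame_rate),
            class = "speaker_activity")
}

#' @rdname write_activity_csv
#' @param frame_rate frames per second of the stored series.
#' @export
read_activity_csv <- function(path, frame_rate = 30) {
  df <- read.csv(path)
  speaker_activity(df[, c("operator", "gp1", "gp2", "gp3")], frame_rate)
}

#' @export
print.speaker_activity <- function(x, ...) {
  p <- colMeans(x$frames)
  cat(sprintf("<speaker_activity> %.0f s at %g Hz; talk proportions %s\n",
              x$duration, x$frame_rate,
              paste(sprintf("%s=%.2f", colnames(x$frames), p),
                    collapse = " ")))
  invisible(x)
}

#' Export speaking series
#'
#' `write_activity_csv()` writes the frame-level 0/1 table;
#' `activity_intervals()` converts it to diarization-style speaker-turn rows
#' and `write_intervals_csv()` writes them.
#'
#' @param activity a [generate_activity()] result.
#' @param path output path.
#' @return The path (writers, invisibly) or the interval data.frame.
#' @export
write_activity_csv <- function(activity, path) {
  n <- nrow(activity$frames)
  df <- data.frame(frame_idx = seq_len(n) - 1L,
                   t_seconds = (seq_len(n) - 1) / activity$frame_rate)
  df <- cbind(df, as.data.frame(activity$frames))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @export
activity_intervals <- function(activity) {
  out <- lapply(colnames(activity$frames), function(sp) {
    r <- rle(activity$frames[, sp])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- r$values == 1L
    if (!any(on)) return(NULL)
    data.frame(speaker = sp,
               onset_s = (starts[on] - 1) / activity$frame_rate,
               offset_s = ends[on] / activity$frame_rate)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(speaker = character(), onset_s = numeric(),
                      offset_s = numeric())
  out[order(out$onset_s), , drop = FALSE]
}

#' @rdname write_activity_csv
#' @export
write_intervals_csv <- function(activity, path) {
  write.csv(activity_intervals(activity), path, row.names = FALSE)
  invisible(path)
}
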