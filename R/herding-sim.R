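#' Repulsive force exerted on a TA by a player avatar
#'
#' Active only within the threat radius; magnitude is inversely proportional
#' to the player--TA distance, `min(repulsion_force_max, repulsion_k / d)` N,
#' directed from the player toward the TA. A coincident player (zero offset)
#' pushes at the capped force in a uniform-random direction drawn from the
#' current RNG stream.
#'
#' @param offset numeric length-2 vector from the player to the TA, m.
#' @param params [sim_params()].
#' @return Force vector (x, y) in newtons.
#' @export
repulsion_force <- function(offset, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.numeric(offset) || length(offset) != 2 || !all(is.finite(offset)))
    stop("repulsion_force: 'offset' must be a finite length-2 vector")
  cpp_repulsion_force(offset, params$threat_radius,
                      params$repulsion_force_max, params$repulsion_k)
}

#' Advance one TA by a single simulation tick
#'
#' Semi-implicit Euler update at `1/tick_rate` s: the held Brownian force and
#' the summed repulsion from all players within the threat radius accelerate
#' the TA, its speed is clamped to `ta_speed_max`, and the position advances.
#' The Brownian force is a zero-order hold owned by the caller (resample it
#' on `brownian_rate` boundaries). A TA inside the containment circle is
#' docile: Brownian forcing is suppressed and its velocity zeroed, though
#' repulsion from a player standing nearby still applies.
#'
#' @param ta list with `position` and `velocity` (length-2 numerics).
#' @param player_positions matrix with one (x, y) row per ground player; may
#'   have zero rows.
#' @param params [sim_params()].
#' @param brownian_force held force vector, N.
#' @return list with updated `position`, `velocity`, and `status` (one of
#'   `"idle"`, `"fleeing"`, `"contained"`).
#' @export
ta_step <- function(ta, player_positions, params = sim_params(),
                    brownian_force = c(0, 0)) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(dim(player_positions)))
    player_positions <- matrix(player_positions, ncol = 2)
  res <- cpp_ta_step(as.numeric(ta$position), as.numeric(ta$velocity),
                     player_positions, as.numeric(brownian_force), params)
  list(position = res$pos, velocity = res$vel,
       status = c("idle", "fleeing", "contained")[res$status + 1L])
}

#' One control decision of the scripted ground-player policy
#'
#' With no visible TA the player heads for its current search waypoint at
#' full speed. With visible TAs it picks the nearest one not already claimed
#' by a closer visible teammate and steers for the drive point a standoff
#' distance behind the TA (on the side opposite the containment centre); if
#' the player is on the centre side of the TA, it flanks tangentially off the
#' centre line rather than pushing the TA outward. Speed is the fine-control
#' 5 m/s within `fine_control_dist` of the chased TA, otherwise 10 m/s.
#'
#' @param player_pos,waypoint length-2 positions, m.
#' @param visible_tas matrix of visible uncontained TA positions (0 or more
#'   rows).
#' @param visible_mates matrix of visible teammate positions.
#' @param params [sim_params()]; @param policy [policy_params()].
#' @return list with unit `heading`, `speed` (0, 5 or 10 m/s), and `chasing`.
#' @export
policy_step <- function(player_pos, waypoint, visible_tas,
                        visible_mates = matrix(numeric(0), 0, 2),
                        params = sim_params(), policy = policy_params()) {
  if (is.null(dim(visible_tas))) visible_tas <- matrix(visible_tas, ncol = 2)
  if (is.null(dim(visible_mates)))
    visible_mates <- matrix(visible_mates, ncol = 2)
  cpp_policy_step(as.numeric(player_pos), as.numeric(waypoint), visible_tas,
                  visible_mates, params, policy)
}

#' Points visible from a position within a sensing radius
#'
#' The fog manipulation acts on the scripted policy purely through the
#' sensing radius, so the fog observation set is always a subset of the
#' clear-visibility one on the same world state.
#'
#' @param origin length-2 position.
#' @param points matrix of candidate (x, y) positions.
#' @param radius sensing radius, m.
#' @return The rows of `points` within `radius` of `origin`.
#' @export
visible_points <- function(origin, points, radius) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  d <- sqrt((points[, 1] - origin[1])^2 + (points[, 2] - origin[2])^2)
  points[d <= radius, , drop = FALSE]
}

#' Simulate one trial of the desert herding game
#'
#' Spawns TAs uniformly within `ta_spawn_radius` and the three ground avatars
#' within `player_spawn_radius` of the containment centre, then advances the
#' world at `tick_rate` until either all TAs have been contained continuously
#' for `success_dwell` seconds (success) or `trial_max` elapses (failure,
#' duration capped at the ceiling). On `late_spawn` perturbation trials one
#' extra TA appears at a uniform-random time inside the final
#' `perturb_window`, or as soon as all original TAs are contained, whichever
#' occurs first. All randomness is drawn from R's RNG after `set.seed(seed)`,
#' so the record is fully reproducible.
#'
#' @param design [condition_design()].
#' @param params [sim_params()]; @param policy [policy_params()].
#' @param seed integer; defaults to `design$seed`.
#' @param ta_init,player_init optional matrices of initial positions
#'   overriding the random spawns (for controlled experiments).
#' @param freeze_ta if `TRUE`, TA dynamics are frozen (they never move).
#' @param idle_players if `TRUE`, the scripted policy is disabled and the
#'   avatars stand still.
#' @return An object of class `trial_record`: the design, `duration` (s),
#'   `success`, `contained_at_end`, and per-tick trajectories (`player_x`,
#'   `player_y`, `ta_x`, `ta_y`, each one column per agent with a row per
#'   tick including the initial state) plus the per-tick `ta_status` matrix
#'   (0 idle, 1 fleeing, 2 contained, 3 all contained).
#' @export
run_trial <- function(design, params = sim_params(), policy = policy_params(),
                      seed = design$seed, ta_init = NULL, player_init = NULL,
                      freeze_ta = FALSE, idle_players = FALSE) {
  stopifnot(inherits(design, "condition_design"),
            inherits(params, "sim_params"),
            inherits(policy, "policy_params"))
  set.seed(seed)
  res <- cpp_run_trial(design$target_number, design$visibility == "fog",
                       design$perturbation == "late_spawn", params, policy,
                       ta_init, player_init, freeze_ta, idle_players)
  structure(c(list(design = design, params = params, seed = seed), res),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> %d TAs, %s, %s: %s in %.2f s (%d/%d contained)\n",
    x$design$target_number, x$design$visibility, x$design$perturbation,
    if (x$success) "success" else "failure", x$duration, x$contained_at_end,
    ncol(x$ta_x)))
  invisible(x)
}

#' Tidy per-tick trajectory table of a trial
#'
#' @param record a [run_trial()] result.
#' @return data.frame with columns team_id, trial_id, t_seconds, agent_id,
#'   role, x_m, y_m, status (players have status `NA`).
#' @export
trajectory_table <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  nt <- nrow(record$player_x)
  tt <- (seq_len(nt) - 1) / record$params$tick_rate
  n_ta <- ncol(record$ta_x)
  players <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(t_seconds = tt, agent_id = paste0("gp", i), role = "ground",
               x_m = record$player_x[, i], y_m = record$player_y[, i],
               status = NA_integer_)
  }))
  tas <- do.call(rbind, lapply(seq_len(n_ta), function(j) {
    data.frame(t_seconds = tt, agent_id = paste0("ta", j), role = "target",
               x_m = record$ta_x[, j], y_m = record$ta_y[, j],
               status = record$ta_status[, j])
  }))
  out <- rbind(players, tas)
  cbind(team_id = record$design$team_id, trial_id = record$design$trial_id,
        out)
}

#' Write trial outputs to disk
#'
#' `write_trajectory_csv()` writes the tidy per-tick table;
#' `write_trial_summary_json()` writes the design echo, duration, success,
#' contained-at-end count and seed.
#'
#' @param record a [run_trial()] result.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(record, path) {
  write.csv(trajectory_table(record), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_trial_summary_json <- function(record, path) {
  s <- list(team_id = record$design$team_id,
            trial_id = record$design$trial_id,
            target_number = record$design$target_number,
            visibility = record$design$visibility,
            perturbation = record$design$perturbation,
            duration = record$duration, success = record$success,
            contained_at_end = record$contained_at_end, seed = record$seed)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
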