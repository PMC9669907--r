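#' Simulation parameters for the desert herding game
#'
#' Physical and procedural constants of the herding task. Defaults follow the
#' game configuration used in the study this package models: a 500 m square
#' desert with a central containment circle 10 m in diameter, evasive target
#' agents (TAs) of 1 kg driven by Brownian forces of 0--60 N resampled at
#' 1 Hz, an inverse-distance repulsion from player avatars capped at 450 N
#' and active within the 10 m threat radius, 10 m/s speed caps for TAs and
#' avatars (5 m/s in fine-control mode), a 90 Hz server tick, a 300 s trial
#' ceiling, a 5 s continuous-containment success rule, and a 90 s terminal
#' window for the late-spawn perturbation.
#'
#' @param field_size square field side, m.
#' @param containment_radius radius of the central containment circle, m.
#' @param ta_spawn_radius TAs spawn uniformly within this radius of the
#'   containment centre, m.
#' @param player_spawn_radius players spawn uniformly within this radius, m.
#' @param threat_radius distance at which a player repels a TA, m.
#' @param brownian_force_max upper bound of the uniform Brownian force, N.
#' @param brownian_rate Brownian force resampling rate, Hz.
#' @param repulsion_force_max cap on the repulsive force, N.
#' @param repulsion_k constant of the inverse-distance repulsion kernel
#'   `min(repulsion_force_max, repulsion_k / d)`, N m.
#' @param ta_mass TA mass, kg.
#' @param ta_speed_max TA speed clamp, m/s.
#' @param player_speed avatar walking speed, m/s.
#' @param player_speed_slow avatar fine-control speed, m/s.
#' @param tick_rate simulation rate, Hz.
#' @param trial_max trial duration ceiling, s.
#' @param success_dwell continuous all-contained time required for success, s.
#' @param perturb_window length of the terminal window in which the extra TA
#'   of a perturbation trial may appear, s.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(field_size = 500, containment_radius = 5,
                       ta_spawn_radius = 180, player_spawn_radius = 100,
                       threat_radius = 10, brownian_force_max = 60,
                       brownian_rate = 1, repulsion_force_max = 450,
                       repulsion_k = 450, ta_mass = 1, ta_speed_max = 10,
                       player_speed = 10, player_speed_slow = 5,
                       tick_rate = 90, trial_max = 300, success_dwell = 5,
                       perturb_window = 90) {
  p <- list(field_size = field_size, containment_radius = containment_radius,
            ta_spawn_radius = ta_spawn_radius,
            player_spawn_radius = player_spawn_radius,
            threat_radius = threat_radius,
            brownian_force_max = brownian_force_max,
            brownian_rate = brownian_rate,
            repulsion_force_max = repulsion_force_max,
            repulsion_k = repulsion_k, ta_mass = ta_mass,
            ta_speed_max = ta_speed_max, player_speed = player_speed,
            player_speed_slow = player_speed_slow, tick_rate = tick_rate,
            trial_max = trial_max, success_dwell = success_dwell,
            perturb_window = perturb_window)
  positive <- setdiff(names(p), "brownian_force_max")
  for (nm in positive) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("sim_params: '", nm, "' must be a single positive number")
  }
  if (brownian_force_max < 0)
    stop("sim_params: 'brownian_force_max' must be non-negative")
  if (!(containment_radius < player_spawn_radius &&
        player_spawn_radius < ta_spawn_radius &&
        ta_spawn_radius <= field_size / 2))
    stop("sim_params: need containment_radius < player_spawn_radius < ",
         "ta_spawn_radius <= field_size/2")
  if (success_dwell >= trial_max)
    stop("sim_params: 'success_dwell' must be smaller than 'trial_max'")
  structure(p, class = "sim_params")
}

#' Scripted ground-player policy parameters
#'
#' The three ground avatars are driven by a scripted stand-in for human play:
#' each player sweeps search waypoints until a TA is visible, then approaches
#' the TA from the side opposite the containment centre to drive it inward.
#' Visibility is the fog manipulation's only effect on the policy: sensing is
#' restricted to `sense_fog` metres under fog versus `sense_clear` without,
#' and fogged players draw search waypoints over the whole spawn disc (they
#' lose the visual basis for keeping to a clean sector partition) while
#' clear-visibility players sweep their own 120-degree sector.
#'
#' @param sense_clear sensing radius without fog, m.
#' @param sense_fog sensing radius under fog, m.
#' @param standoff distance behind the TA (away from the containment centre)
#'   of the drive point the player steers for, m.
#' @param waypoint_tol distance at which a search waypoint counts as reached, m.
#' @param fine_control_dist distance to the chased TA below which the player
#'   drops to the slow walking speed, m.
#' @return An object of class `policy_params`.
#' @export
policy_params <- function(sense_clear = 150, sense_fog = 10, standoff = 3,
                          waypoint_tol = 5, fine_control_dist = 6) {
  p <- list(sense_clear = sense_clear, sense_fog = sense_fog,
            standoff = standoff, waypoint_tol = waypoint_tol,
            fine_control_dist = fine_control_dist)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("policy_params: '", nm, "' must be positive")
  structure(p, class = "policy_params")
}

#' Trial condition in the 2x2x2 task design
#'
#' @param target_number number of TAs to corral, 9 or 18.
#' @param visibility `"clear"` or `"fog"`.
#' @param perturbation `"none"` or `"late_spawn"` (an extra TA appears in the
#'   final window of the trial).
#' @param trial_id,team_id identifiers carried through all outputs.
#' @param seed integer seed making the trial reproducible.
#' @return An object of class `condition_design`.
#' @export
condition_design <- function(target_number, visibility = c("clear", "fog"),
                             perturbation = c("none", "late_spawn"),
                             trial_id = 1L, team_id = 1L, seed = 1L) {
  if (!is.numeric(target_number) || length(target_number) != 1 ||
      !target_number %in% c(9, 18))
    stop("condition_design: 'target_number' must be 9 or 18")
  visibility <- match.arg(visibility)
  perturbation <- match.arg(perturbation)
  structure(list(target_number = as.integer(target_number),
                 visibility = visibility, perturbation = perturbation,
                 trial_id = trial_id, team_id = team_id,
                 seed = as.integer(seed)),
            class = "condition_design")
}

#' @export
print.condition_design <- function(x, ...) {
  cat(sprintf("<condition_design> team %s trial %s: %d TAs, %s, %s (seed %d)\n",
              x$team_id, x$trial_id, x$target_number, x$visibility,
              x$perturbation, x$seed))
  invisible(x)
}
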