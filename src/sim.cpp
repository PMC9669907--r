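#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- small vector helpers -------------------------------------------------

static inline double norm2(double x, double y) { return std::sqrt(x * x + y * y); }

static inline void clamp_speed(double &vx, double &vy, double vmax) {
  double s = norm2(vx, vy);
  if (s > vmax) {
    vx *= vmax / s;
    vy *= vmax / s;
  }
}

struct SimP {
  double field_half, containment_radius, ta_spawn_radius, player_spawn_radius;
  double threat_radius, brownian_force_max, brownian_rate;
  double repulsion_force_max, repulsion_k, ta_mass, ta_speed_max;
  double player_speed, player_speed_slow, tick_rate, trial_max;
  double success_dwell, perturb_window;
};

static SimP unpack_params(const List &params) {
  SimP p;
  p.field_half = as<double>(params["field_size"]) / 2.0;
  p.containment_radius = as<double>(params["containment_radius"]);
  p.ta_spawn_radius = as<double>(params["ta_spawn_radius"]);
  p.player_spawn_radius = as<double>(params["player_spawn_radius"]);
  p.threat_radius = as<double>(params["threat_radius"]);
  p.brownian_force_max = as<double>(params["brownian_force_max"]);
  p.brownian_rate = as<double>(params["brownian_rate"]);
  p.repulsion_force_max = as<double>(params["repulsion_force_max"]);
  p.repulsion_k = as<double>(params["repulsion_k"]);
  p.ta_mass = as<double>(params["ta_mass"]);
  p.ta_speed_max = as<double>(params["ta_speed_max"]);
  p.player_speed = as<double>(params["player_speed"]);
  p.player_speed_slow = as<double>(params["player_speed_slow"]);
  p.tick_rate = as<double>(params["tick_rate"]);
  p.trial_max = as<double>(params["trial_max"]);
  p.success_dwell = as<double>(params["success_dwell"]);
  p.perturb_window = as<double>(params["perturb_window"]);
  return p;
}

// Repulsive force on a TA from one player. offset = TA position - player
// position. Inverse-distance kernel capped at fmax, active only within the
// threat radius; a coincident player (zero offset) pushes at full force in a
// uniform-random direction drawn from the R RNG stream.
static void repulsion(double ox, double oy, double threat, double fmax,
                      double k, double &fx, double &fy) {
  double d = norm2(ox, oy);
  if (d > threat) {
    fx = 0.0;
    fy = 0.0;
    return;
  }
  double mag;
  double ux, uy;
  if (d <= 0.0) {
    mag = fmax;
    double th = unif_rand() * 2.0 * M_PI;
    ux = std::cos(th);
    uy = std::sin(th);
  } else {
    mag = std::min(fmax, k / d);
    ux = ox / d;
    uy = oy / d;
  }
  fx = mag * ux;
  fy = mag * uy;
}

// [[Rcpp::export]]
NumericVector cpp_repulsion_force(NumericVector offset, double threat_radius,
                                  double force_max, double k) {
  double fx, fy;
  repulsion(offset[0], offset[1], threat_radius, force_max, k, fx, fy);
  return NumericVector::create(fx, fy);
}

// One semi-implicit Euler tick for a single TA. brownian_force is the
// zero-order-hold force currently applied (resampled at brownian_rate by the
// caller). Contained TAs (inside the containment radius) have Brownian
// forcing suppressed and velocity zeroed at tick start; repulsion still acts,
// so players standing inside can knock a TA back out.
// [[Rcpp::export]]
List cpp_ta_step(NumericVector pos, NumericVector vel, NumericMatrix players,
                 NumericVector brownian_force, List params) {
  SimP p = unpack_params(params);
  double dt = 1.0 / p.tick_rate;
  double x = pos[0], y = pos[1], vx = vel[0], vy = vel[1];

  bool contained = norm2(x, y) <= p.containment_radius;
  double fx = contained ? 0.0 : brownian_force[0];
  double fy = contained ? 0.0 : brownian_force[1];
  if (contained) {
    vx = 0.0;
    vy = 0.0;
  }

  bool fleeing = false;
  for (int i = 0; i < players.nrow(); ++i) {
    double rx, ry;
    repulsion(x - players(i, 0), y - players(i, 1), p.threat_radius,
              p.repulsion_force_max, p.repulsion_k, rx, ry);
    if (rx != 0.0 || ry != 0.0) fleeing = true;
    fx += rx;
    fy += ry;
  }

  vx += fx / p.ta_mass * dt;
  vy += fy / p.ta_mass * dt;
  clamp_speed(vx, vy, p.ta_speed_max);
  x += vx * dt;
  y += vy * dt;

  // reflective field boundary
  if (x > p.field_half)  { x = 2.0 * p.field_half - x;  vx = -vx; }
  if (x < -p.field_half) { x = -2.0 * p.field_half - x; vx = -vx; }
  if (y > p.field_half)  { y = 2.0 * p.field_half - y;  vy = -vy; }
  if (y < -p.field_half) { y = -2.0 * p.field_half - y; vy = -vy; }

  int status = 0; // idle
  if (norm2(x, y) <= p.containment_radius) status = 2; // contained
  else if (fleeing) status = 1;                        // fleeing

  return List::create(_["pos"] = NumericVector::create(x, y),
                      _["vel"] = NumericVector::create(vx, vy),
                      _["status"] = status);
}

// ---- scripted ground-player policy ---------------------------------------
//
// Sector-partitioned sweep search until a TA is visible, then approach the TA
// from the side opposite the containment centre (a "drive point" a standoff
// distance behind the TA) to push it inward. If the straight path to the
// drive point would shove the TA outward (player on the centre side of the
// TA), the player flanks tangentially around the threat radius instead.

struct PolicyP {
  double sense_clear, sense_fog, standoff, waypoint_tol, fine_control_dist;
};

static PolicyP unpack_policy(const List &policy) {
  PolicyP q;
  q.sense_clear = as<double>(policy["sense_clear"]);
  q.sense_fog = as<double>(policy["sense_fog"]);
  q.standoff = as<double>(policy["standoff"]);
  q.waypoint_tol = as<double>(policy["waypoint_tol"]);
  q.fine_control_dist = as<double>(policy["fine_control_dist"]);
  return q;
}

// heading/speed for one player; target_x/y is the chased TA (NAN if none),
// tvx/tvy its velocity (zero when unobserved) used to lead the pursuit
static void policy_control(double px, double py, double wx, double wy,
                           double tx, double ty, double tvx, double tvy,
                           const PolicyP &q, double speed_fast,
                           double speed_slow, double threat_radius,
                           double &hx, double &hy, double &speed) {
  if (ISNAN(tx)) { // no visible TA: head for the search waypoint
    double dx = wx - px, dy = wy - py, d = norm2(dx, dy);
    if (d < 1e-9) {
      hx = 1.0;
      hy = 0.0;
      speed = 0.0;
      return;
    }
    hx = dx / d;
    hy = dy / d;
    speed = speed_fast;
    return;
  }
  double dq0 = norm2(px - tx, py - ty);
  // lead a moving TA by ~half the time needed to reach it
  double lead = 0.5 * dq0 / std::max(speed_fast, 1.0);
  tx += tvx * lead;
  ty += tvy * lead;
  double rq = norm2(tx, ty);
  double ox = (rq < 1e-9) ? 1.0 : tx / rq; // outward radial at the TA
  double oy = (rq < 1e-9) ? 0.0 : ty / rq;
  double dxp = px - tx, dyp = py - ty; // TA -> player
  double behind = dxp * ox + dyp * oy; // >0: player outward of the TA
  double dq = norm2(dxp, dyp);

  if (behind > 0.25 * q.standoff || dq < 1e-9) {
    // safe to head straight for the drive point behind the TA
    double gx = tx + q.standoff * ox, gy = ty + q.standoff * oy;
    double dx = gx - px, dy = gy - py, d = norm2(dx, dy);
    if (d < 1e-9) { // sitting on the drive point: push inward
      hx = -ox;
      hy = -oy;
    } else {
      hx = dx / d;
      hy = dy / d;
    }
  } else {
    // flank: move tangentially (off the centre line) toward the outward side
    double txp = -dyp, typ = dxp; // perpendicular of TA->player
    double n = norm2(txp, typ);
    txp /= n;
    typ /= n;
    if (txp * ox + typ * oy < 0) { // pick the rotation toward outward
      txp = -txp;
      typ = -typ;
    }
    // keep clear of the threat radius while circling
    double away = (dq < threat_radius + 1.0) ? 0.6 : 0.0;
    hx = txp + away * (dxp / dq);
    hy = typ + away * (dyp / dq);
    double n2 = norm2(hx, hy);
    hx /= n2;
    hy /= n2;
  }
  speed = (dq < q.fine_control_dist) ? speed_slow : speed_fast;
}

// [[Rcpp::export]]
List cpp_policy_step(NumericVector player_pos, NumericVector waypoint,
                     NumericMatrix visible_tas, NumericMatrix visible_mates,
                     List params, List policy) {
  SimP p = unpack_params(params);
  PolicyP q = unpack_policy(policy);
  double tx = NA_REAL, ty = NA_REAL;
  // choose the nearest visible TA for which no visible teammate is closer
  double best = R_PosInf;
  for (int j = 0; j < visible_tas.nrow(); ++j) {
    double d = norm2(visible_tas(j, 0) - player_pos[0],
                     visible_tas(j, 1) - player_pos[1]);
    bool mate_closer = false;
    for (int m = 0; m < visible_mates.nrow(); ++m) {
      double dm = norm2(visible_tas(j, 0) - visible_mates(m, 0),
                        visible_tas(j, 1) - visible_mates(m, 1));
      if (dm < d) { mate_closer = true; break; }
    }
    if (!mate_closer && d < best) {
      best = d;
      tx = visible_tas(j, 0);
      ty = visible_tas(j, 1);
    }
  }
  if (ISNAN(tx) && visible_tas.nrow() > 0) { // all claimed: take the nearest
    for (int j = 0; j < visible_tas.nrow(); ++j) {
      double d = norm2(visible_tas(j, 0) - player_pos[0],
                       visible_tas(j, 1) - player_pos[1]);
      if (d < best) {
        best = d;
        tx = visible_tas(j, 0);
        ty = visible_tas(j, 1);
      }
    }
  }
  double hx, hy, speed;
  policy_control(player_pos[0], player_pos[1], waypoint[0], waypoint[1], tx,
                 ty, 0.0, 0.0, q, p.player_speed, p.player_speed_slow,
                 p.threat_radius, hx, hy, speed);
  return List::create(_["heading"] = NumericVector::create(hx, hy),
                      _["speed"] = speed,
                      _["chasing"] = !ISNAN(tx));
}

// uniform point in a disc of radius R (two RNG draws)
static void runif_disc(double R, double &x, double &y) {
  double r = R * std::sqrt(unif_rand());
  double th = unif_rand() * 2.0 * M_PI;
  x = r * std::cos(th);
  y = r * std::sin(th);
}

// ---- full trial loop ------------------------------------------------------
//
// Advances the world at tick_rate until success (all TAs contained for
// success_dwell continuous seconds) or trial_max. Consumes the R RNG stream
// only, so a set.seed() before the call makes the record reproducible.
// [[Rcpp::export]]
List cpp_run_trial(int n_targets, bool fog, bool perturb, List params,
                   List policy, Nullable<NumericMatrix> ta_init,
                   Nullable<NumericMatrix> player_init, bool freeze_ta,
                   bool idle_players) {
  SimP p = unpack_params(params);
  PolicyP q = unpack_policy(policy);
  double dt = 1.0 / p.tick_rate;
  int max_ticks = (int)std::lround(p.trial_max * p.tick_rate);
  int resample_ticks =
      std::max(1, (int)std::lround(p.tick_rate / p.brownian_rate));
  double sense = fog ? q.sense_fog : q.sense_clear;
  int n_total = n_targets + (perturb ? 1 : 0);

  std::vector<double> tax(n_total), tay(n_total), tavx(n_total, 0.0),
      tavy(n_total, 0.0), tabx(n_total, 0.0), taby(n_total, 0.0);
  std::vector<bool> alive(n_total, false);
  std::vector<double> px(3), py(3), wx(3), wy(3);

  // spawn initial TAs, then players (fixed draw order for reproducibility)
  for (int j = 0; j < n_targets; ++j) {
    runif_disc(p.ta_spawn_radius, tax[j], tay[j]);
    alive[j] = true;
  }
  for (int i = 0; i < 3; ++i) runif_disc(p.player_spawn_radius, px[i], py[i]);
  if (ta_init.isNotNull()) {
    NumericMatrix m(ta_init);
    for (int j = 0; j < std::min((int)m.nrow(), n_targets); ++j) {
      tax[j] = m(j, 0);
      tay[j] = m(j, 1);
    }
  }
  if (player_init.isNotNull()) {
    NumericMatrix m(player_init);
    for (int i = 0; i < std::min((int)m.nrow(), 3); ++i) {
      px[i] = m(i, 0);
      py[i] = m(i, 1);
    }
  }

  // initial search waypoints: own 120-degree sector when clear, anywhere in
  // the spawn disc under fog (fog removes the visual basis for partitioning)
  auto draw_waypoint = [&](int i) {
    double r = p.ta_spawn_radius * std::sqrt(unif_rand());
    double th;
    if (fog)
      th = unif_rand() * 2.0 * M_PI;
    else
      th = (i + unif_rand()) * (2.0 * M_PI / 3.0);
    wx[i] = r * std::cos(th);
    wy[i] = r * std::sin(th);
  };
  for (int i = 0; i < 3; ++i) draw_waypoint(i);

  // late-spawn perturbation schedule
  double spawn_time = R_PosInf;
  if (perturb)
    spawn_time = (p.trial_max - p.perturb_window) + unif_rand() * p.perturb_window;

  NumericMatrix rec_px(max_ticks + 1, 3), rec_py(max_ticks + 1, 3);
  NumericMatrix rec_tx(max_ticks + 1, n_total), rec_ty(max_ticks + 1, n_total);
  IntegerMatrix rec_st(max_ticks + 1, n_total);

  auto contained = [&](int j) {
    return norm2(tax[j], tay[j]) <= p.containment_radius;
  };
  auto record_state = [&](int row) {
    for (int i = 0; i < 3; ++i) {
      rec_px(row, i) = px[i];
      rec_py(row, i) = py[i];
    }
    bool allc = true;
    for (int j = 0; j < n_total; ++j)
      if (alive[j] && !contained(j)) allc = false;
    for (int j = 0; j < n_total; ++j) {
      if (!alive[j]) {
        rec_tx(row, j) = NA_REAL;
        rec_ty(row, j) = NA_REAL;
        rec_st(row, j) = NA_INTEGER;
        continue;
      }
      rec_tx(row, j) = tax[j];
      rec_ty(row, j) = tay[j];
      int st = 0;
      if (contained(j)) st = allc ? 3 : 2;
      else {
        for (int i = 0; i < 3; ++i)
          if (norm2(tax[j] - px[i], tay[j] - py[i]) <= p.threat_radius) {
            st = 1;
            break;
          }
      }
      rec_st(row, j) = st;
    }
  };

  record_state(0);
  bool success = false;
  double duration = p.trial_max;
  int n_ticks_done = max_ticks;
  double dwell_start = NA_REAL;
  int spawn_tick = NA_INTEGER;
  {
    bool allc0 = true;
    for (int j = 0; j < n_total; ++j)
      if (alive[j] && !contained(j)) allc0 = false;
    if (allc0) dwell_start = 0.0;
  }

  for (int tick = 1; tick <= max_ticks; ++tick) {
    double t_now = tick * dt;

    // resample Brownian zero-order-hold forces on brownian_rate boundaries
    if ((tick - 1) % resample_ticks == 0) {
      for (int j = 0; j < n_total; ++j) {
        double mag = unif_rand() * p.brownian_force_max;
        double th = unif_rand() * 2.0 * M_PI;
        tabx[j] = mag * std::cos(th);
        taby[j] = mag * std::sin(th);
      }
    }

    // perturbation: extra TA appears in the final window, or as soon as all
    // initial TAs are contained, whichever comes first
    if (perturb && !alive[n_total - 1]) {
      bool allc = true;
      for (int j = 0; j < n_targets; ++j)
        if (!contained(j)) allc = false;
      if (t_now >= spawn_time || allc) {
        runif_disc(p.ta_spawn_radius, tax[n_total - 1], tay[n_total - 1]);
        tavx[n_total - 1] = 0.0;
        tavy[n_total - 1] = 0.0;
        alive[n_total - 1] = true;
        spawn_tick = tick;
        dwell_start = NA_REAL;
      }
    }

    // players move first (control computed on the pre-tick world state)
    if (!idle_players) {
      for (int i = 0; i < 3; ++i) {
        // visible, uncontained TAs
        double bx = NA_REAL, by = NA_REAL, best = R_PosInf;
        int bj = -1;
        for (int j = 0; j < n_total; ++j) {
          if (!alive[j] || contained(j)) continue;
          double d = norm2(tax[j] - px[i], tay[j] - py[i]);
          if (d > sense) continue;
          bool mate_closer = false;
          for (int m = 0; m < 3; ++m) {
            if (m == i) continue;
            if (norm2(px[m] - px[i], py[m] - py[i]) > sense) continue;
            if (norm2(tax[j] - px[m], tay[j] - py[m]) < d) {
              mate_closer = true;
              break;
            }
          }
          double eff = mate_closer ? d + 1e6 : d; // deprioritise claimed TAs
          if (eff < best) {
            best = eff;
            bx = tax[j];
            by = tay[j];
            bj = j;
          }
        }
        if (ISNAN(bx) &&
            norm2(wx[i] - px[i], wy[i] - py[i]) < q.waypoint_tol)
          draw_waypoint(i);
        double hx, hy, speed;
        double bvx = (bj >= 0) ? tavx[bj] : 0.0;
        double bvy = (bj >= 0) ? tavy[bj] : 0.0;
        policy_control(px[i], py[i], wx[i], wy[i], bx, by, bvx, bvy, q,
                       p.player_speed, p.player_speed_slow, p.threat_radius,
                       hx, hy, speed);
        px[i] += speed * hx * dt;
        py[i] += speed * hy * dt;
        px[i] = std::max(-p.field_half, std::min(p.field_half, px[i]));
        py[i] = std::max(-p.field_half, std::min(p.field_half, py[i]));
      }
    }

    // TAs move
    if (!freeze_ta) {
      for (int j = 0; j < n_total; ++j) {
        if (!alive[j]) continue;
        bool cont = contained(j);
        double fx = cont ? 0.0 : tabx[j];
        double fy = cont ? 0.0 : taby[j];
        if (cont) {
          tavx[j] = 0.0;
          tavy[j] = 0.0;
        }
        for (int i = 0; i < 3; ++i) {
          double rx, ry;
          repulsion(tax[j] - px[i], tay[j] - py[i], p.threat_radius,
                    p.repulsion_force_max, p.repulsion_k, rx, ry);
          fx += rx;
          fy += ry;
        }
        tavx[j] += fx / p.ta_mass * dt;
        tavy[j] += fy / p.ta_mass * dt;
        clamp_speed(tavx[j], tavy[j], p.ta_speed_max);
        tax[j] += tavx[j] * dt;
        tay[j] += tavy[j] * dt;
        if (tax[j] > p.field_half)  { tax[j] = 2 * p.field_half - tax[j];  tavx[j] = -tavx[j]; }
        if (tax[j] < -p.field_half) { tax[j] = -2 * p.field_half - tax[j]; tavx[j] = -tavx[j]; }
        if (tay[j] > p.field_half)  { tay[j] = 2 * p.field_half - tay[j];  tavy[j] = -tavy[j]; }
        if (tay[j] < -p.field_half) { tay[j] = -2 * p.field_half - tay[j]; tavy[j] = -tavy[j]; }
      }
    }

    record_state(tick);

    // success dwell bookkeeping (a pending late TA blocks success)
    bool allc = (!perturb || alive[n_total - 1]);
    for (int j = 0; j < n_total && allc; ++j)
      if (alive[j] && !contained(j)) allc = false;
    if (allc) {
      if (ISNAN(dwell_start)) dwell_start = t_now;
      if (t_now - dwell_start >= p.success_dwell - 1e-9) {
        success = true;
        duration = t_now;
        n_ticks_done = tick;
        break;
      }
    } else {
      dwell_start = NA_REAL;
    }
  }

  int contained_at_end = 0;
  for (int j = 0; j < n_total; ++j)
    if (alive[j] && contained(j)) ++contained_at_end;

  int nr = n_ticks_done + 1;
  return List::create(
      _["duration"] = duration, _["success"] = success,
      _["contained_at_end"] = contained_at_end, _["n_ticks"] = n_ticks_done,
      _["player_x"] = rec_px(Range(0, nr - 1), _),
      _["player_y"] = rec_py(Range(0, nr - 1), _),
      _["ta_x"] = rec_tx(Range(0, nr - 1), _),
      _["ta_y"] = rec_ty(Range(0, nr - 1), _),
      _["ta_status"] = rec_st(Range(0, nr - 1), _),
      _["spawn_tick"] = spawn_tick);
}
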