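#include <Rcpp.h>
using namespace Rcpp;

// Coupled alternating-renewal (on/off) speaking process for 4 speakers
// (column 0 = operator, 1..3 = ground players) at frame_rate Hz.
//
// Per frame, an off speaker turns on with hazard dt/mean_off and an on
// speaker turns off with hazard dt/mean_on (geometric dwell times, so the
// long-run on-proportion is exactly mean_on/(mean_on+mean_off)). Two
// modulations act on onset hazards only:
//   * turn-taking inhibition: while any OTHER speaker was active on the
//     previous frame, the onset hazard is multiplied by (1 - coupling);
//   * response boost: for boost_window seconds after the operator stops
//     speaking, ground-player onset hazards are multiplied by (1 + boost).
// All randomness comes from the R RNG stream.
// [[Rcpp::export]]
IntegerMatrix cpp_generate_activity(int n_frames, NumericVector p_target,
                                    NumericVector mean_on, double coupling,
                                    double boost, double boost_window,
                                    double frame_rate) {
  IntegerMatrix out(n_frames, 4);
  double dt = 1.0 / frame_rate;
  double h_on[4], h_off[4];
  for (int s = 0; s < 4; ++s) {
    double p = p_target[s];
    if (p <= 0.0) {
      h_on[s] = 0.0;
      h_off[s] = 1.0;
    } else {
      double moff = mean_on[s] * (1.0 - p) / p;
      h_on[s] = std::min(1.0, dt / moff);
      h_off[s] = std::min(1.0, dt / mean_on[s]);
    }
  }
  int state[4] = {0, 0, 0, 0};
  double since_op_offset = R_PosInf;
  for (int t = 0; t < n_frames; ++t) {
    int prev[4] = {state[0], state[1], state[2], state[3]};
    int n_active = prev[0] + prev[1] + prev[2] + prev[3];
    for (int s = 0; s < 4; ++s) {
      if (prev[s] == 1) {
        if (unif_rand() < h_off[s]) state[s] = 0;
      } else {
        double h = h_on[s];
        if (n_active - prev[s] > 0) h *= (1.0 - coupling);
        if (s > 0 && since_op_offset < boost_window) h *= (1.0 + boost);
        if (unif_rand() < std::min(1.0, h)) state[s] = 1;
      }
      out(t, s) = state[s];
    }
    if (prev[0] == 1 && state[0] == 0) since_op_offset = 0.0;
    else since_op_offset += dt;
  }
  return out;
}
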