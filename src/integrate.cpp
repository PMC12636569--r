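// Rectified RK4 integration of the rate equation
//   tau * dr/dt = -r + W.r - theta + sum_a w_a * I_a(t),  r >= 0
// Stimuli are rectangular current pulses with per-unit weight vectors.
// Stage evaluations use rectified rates and the state is clamped to zero
// after every full step, so DOWN units sit exactly at zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec pulse_current(double t, const vec& amp, const vec& onset,
                                const vec& dur, const mat& wts, int n_units) {
  vec I(n_units, fill::zeros);
  for (uword a = 0; a < amp.n_elem; ++a) {
    if (t >= onset[a] && t < onset[a] + dur[a])
      I += amp[a] * wts.col(a);
  }
  return I;
}

static inline vec deriv(const vec& r, double t, const mat& W, const vec& theta,
                        double tau, const vec& amp, const vec& onset,
                        const vec& dur, const mat& wts) {
  vec rp = clamp(r, 0.0, datum::inf);
  vec d = -rp + W * rp - theta;
  if (amp.n_elem > 0)
    d += pulse_current(t, amp, onset, dur, wts, r.n_elem);
  return d / tau;
}

static inline void rk4_step(vec& r, double t, double dt, const mat& W,
                            const vec& theta, double tau, const vec& amp,
                            const vec& onset, const vec& dur, const mat& wts) {
  vec k1 = deriv(r, t, W, theta, tau, amp, onset, dur, wts);
  vec k2 = deriv(r + 0.5 * dt * k1, t + 0.5 * dt, W, theta, tau, amp, onset, dur, wts);
  vec k3 = deriv(r + 0.5 * dt * k2, t + 0.5 * dt, W, theta, tau, amp, onset, dur, wts);
  vec k4 = deriv(r + dt * k3, t + dt, W, theta, tau, amp, onset, dur, wts);
  r += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  r = clamp(r, 0.0, datum::inf);
}

// [[Rcpp::export(name = ".rk4_integrate")]]
Rcpp::List rk4_integrate(const arma::mat& W, const arma::vec& theta, double tau,
                         const arma::vec& r0, const arma::vec& stim_amp,
                         const arma::vec& stim_onset, const arma::vec& stim_dur,
                         const arma::mat& stim_weights, double t_end, double dt,
                         int record_every) {
  const int n_steps = (int) std::llround(t_end / dt);
  vec r = clamp(r0, 0.0, datum::inf);
  const int n_rec = n_steps / record_every + 1;
  mat out(r.n_elem, n_rec);
  vec times(n_rec);
  out.col(0) = r; times[0] = 0.0;
  int j = 1;
  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    rk4_step(r, t, dt, W, theta, tau, stim_amp, stim_onset, stim_dur, stim_weights);
    if (!r.is_finite())
      Rcpp::stop("non-finite rates at step %d (t = %g ms): integration diverged",
                 i + 1, t + dt);
    if ((i + 1) % record_every == 0 && j < n_rec) {
      out.col(j) = r; times[j] = (i + 1) * dt; ++j;
    }
  }
  return Rcpp::List::create(Rcpp::Named("times") = times.head(j),
                            Rcpp::Named("rates") = out.head_cols(j).t(),
                            Rcpp::Named("final") = r);
}

// Settle with no stimulus until converged or max_time.  Convergence: the
// max-norm change over a trailing `window` ms is below `tol_change` Hz and
// the fixed point extrapolated from the flow (r + tau * dr/dt for the
// leading-order linear decay) lies within `fp_radius` Hz.
// [[Rcpp::export(name = ".settle_rk4")]]
Rcpp::List settle_rk4(const arma::mat& W, const arma::vec& theta, double tau,
                      const arma::vec& r0, double dt, double max_time,
                      double window, double tol_change, double fp_radius) {
  vec amp, onset, dur; mat wts(r0.n_elem, 0);
  vec r = clamp(r0, 0.0, datum::inf);
  const int n_steps = (int) std::llround(max_time / dt);
  const int check_every = std::max(1, (int) std::llround(1.0 / dt)); // 1 ms
  const int n_snap = std::max(1, (int) std::llround(window / 1.0));
  std::vector<vec> snaps;
  snaps.reserve(n_snap + 1);
  snaps.push_back(r);
  for (int i = 0; i < n_steps; ++i) {
    rk4_step(r, i * dt, dt, W, theta, tau, amp, onset, dur, wts);
    if (!r.is_finite())
      Rcpp::stop("non-finite rates at step %d (t = %g ms): settle diverged",
                 i + 1, (i + 1) * dt);
    if ((i + 1) % check_every == 0) {
      double worst = 0.0;
      for (const vec& s : snaps)
        worst = std::max(worst, (double) abs(r - s).max());
      snaps.push_back(r);
      if ((int) snaps.size() > n_snap) snaps.erase(snaps.begin());
      if ((int) snaps.size() >= n_snap && worst < tol_change) {
        vec dr = deriv(r, (i + 1) * dt, W, theta, tau, amp, onset, dur, wts);
        // effective flow of the clamped system: units pinned at zero with
        // negative drive do not move, so they are at their fixed point
        for (uword u = 0; u < dr.n_elem; ++u)
          if (r[u] <= 0.0 && dr[u] < 0.0) dr[u] = 0.0;
        if (abs(tau * dr).max() < fp_radius) {
          return Rcpp::List::create(Rcpp::Named("rates") = r,
                                    Rcpp::Named("converged") = true,
                                    Rcpp::Named("time") = (i + 1) * dt);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("rates") = r,
                            Rcpp::Named("converged") = false,
                            Rcpp::Named("time") = max_time);
}

// Apply one rectangular pulse then settle; returns the settled state.
// Used heavily by transition-graph construction and FSM extraction, where
// the R-level call overhead of simulate-then-settle would dominate.
// [[Rcpp::export(name = ".pulse_then_settle")]]
Rcpp::List pulse_then_settle(const arma::mat& W, const arma::vec& theta,
                             double tau, const arma::vec& r0, double amp,
                             double dur, const arma::vec& stim_weights,
                             double dt, double max_time, double window,
                             double tol_change, double fp_radius) {
  vec amps(1); amps[0] = amp;
  vec onsets(1); onsets[0] = 0.0;
  vec durs(1); durs[0] = dur;
  mat wts(stim_weights.n_elem, 1); wts.col(0) = stim_weights;
  vec r = clamp(r0, 0.0, datum::inf);
  const int n_steps = (int) std::llround(dur / dt) + 1;
  for (int i = 0; i < n_steps; ++i) {
    rk4_step(r, i * dt, dt, W, theta, tau, amps, onsets, durs, wts);
    if (!r.is_finite())
      Rcpp::stop("non-finite rates during pulse at step %d: integration diverged",
                 i + 1);
  }
  return settle_rk4(W, theta, tau, r, dt, max_time, window, tol_change, fp_radius);
}
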