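#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// threshold-linear response function
static inline double relu_gain(double h, double theta, double G) {
  return h > theta ? G * (h - theta) : 0.0;
}

struct StpPars {
  double tau_P, tau_I;
  double J_PP, J_IP, J_II, J_PI;
  double tr_PP, tr_IP, tr_PI, tr_II;
  double tf_PP, tf_IP, tf_PI, tf_II;
  double U_PP, U_IP, U_PI, U_II;
  double th_P, th_I, G_P, G_I;
};

// state layout: A_P, A_I, x_PP, u_PP, x_IP, u_IP, x_PI, u_PI, x_II, u_II
static inline void rhs(const StpPars &p, const double *s, double eP, double eI,
                       double *d) {
  const double A_P = s[0], A_I = s[1];
  const double x_PP = s[2], u_PP = s[3], x_IP = s[4], u_IP = s[5];
  const double x_PI = s[6], u_PI = s[7], x_II = s[8], u_II = s[9];
  const double h_P = p.J_PP * u_PP * x_PP * A_P - p.J_PI * u_PI * x_PI * A_I + eP;
  const double h_I = p.J_IP * u_IP * x_IP * A_P - p.J_II * u_II * x_II * A_I + eI;
  d[0] = (-A_P + relu_gain(h_P, p.th_P, p.G_P)) / p.tau_P;
  d[1] = (-A_I + relu_gain(h_I, p.th_I, p.G_I)) / p.tau_I;
  d[2] = (1.0 - x_PP) / p.tr_PP - u_PP * x_PP * A_P;
  d[3] = (p.U_PP - u_PP) / p.tf_PP + p.U_PP * (1.0 - u_PP) * A_P;
  d[4] = (1.0 - x_IP) / p.tr_IP - u_IP * x_IP * A_P;
  d[5] = (p.U_IP - u_IP) / p.tf_IP + p.U_IP * (1.0 - u_IP) * A_P;
  d[6] = (1.0 - x_PI) / p.tr_PI - u_PI * x_PI * A_I;
  d[7] = (p.U_PI - u_PI) / p.tf_PI + p.U_PI * (1.0 - u_PI) * A_I;
  d[8] = (1.0 - x_II) / p.tr_II - u_II * x_II * A_I;
  d[9] = (p.U_II - u_II) / p.tf_II + p.U_II * (1.0 - u_II) * A_I;
}

static StpPars unpack(const List &par) {
  StpPars p;
  p.tau_P = par["tau_P"]; p.tau_I = par["tau_I"];
  p.J_PP = par["J_PP"]; p.J_IP = par["J_IP"];
  p.J_II = par["J_II"]; p.J_PI = par["J_PI"];
  p.tr_PP = par["tau_r_PP"]; p.tr_IP = par["tau_r_IP"];
  p.tr_PI = par["tau_r_PI"]; p.tr_II = par["tau_r_II"];
  p.tf_PP = par["tau_f_PP"]; p.tf_IP = par["tau_f_IP"];
  p.tf_PI = par["tau_f_PI"]; p.tf_II = par["tau_f_II"];
  p.U_PP = par["U_PP"]; p.U_IP = par["U_IP"];
  p.U_PI = par["U_PI"]; p.U_II = par["U_II"];
  p.th_P = par["theta_P"]; p.th_I = par["theta_I"];
  p.G_P = par["G_P"]; p.G_I = par["G_I"];
  return p;
}

// [[Rcpp::export(name = ".stprnn_rhs_cpp")]]
NumericVector stprnn_rhs_cpp(NumericVector state, List par, double eP, double eI) {
  StpPars p = unpack(par);
  NumericVector out(10);
  rhs(p, state.begin(), eP, eI, out.begin());
  return out;
}

// Fixed-step 4th-order Runge-Kutta integration of the 10D rate model with
// piecewise-constant pulse inputs. pulses: matrix with columns
// (t_on, t_off, eP, eI); inputs of simultaneous pulses add, on top of the
// baseline drives eP0/eI0. Recording happens every `record_every` steps
// (plus the final state).
// [[Rcpp::export(name = ".stprnn_integrate_cpp")]]
List stprnn_integrate_cpp(NumericVector state0, List par, double t0, double t1,
                          double dt, NumericMatrix pulses, double eP0, double eI0,
                          int record_every) {
  StpPars p = unpack(par);
  const int n_steps = (int)std::ceil((t1 - t0) / dt - 1e-9);
  const int n_rec = n_steps / record_every + 2;
  NumericMatrix states(n_rec, 10);
  NumericVector times(n_rec), hP_tr(n_rec), hI_tr(n_rec),
      eP_tr(n_rec), eI_tr(n_rec);
  double s[10], k1[10], k2[10], k3[10], k4[10], tmp[10];
  for (int i = 0; i < 10; ++i) s[i] = state0[i];
  const int n_pulse = pulses.nrow();
  int row = 0;
  double t = t0;
  auto input_at = [&](double tt, double &eP, double &eI) {
    eP = eP0; eI = eI0;
    for (int q = 0; q < n_pulse; ++q) {
      if (tt >= pulses(q, 0) && tt < pulses(q, 1)) {
        eP += pulses(q, 2);
        eI += pulses(q, 3);
      }
    }
  };
  auto record = [&](double tt) {
    double eP, eI;
    input_at(tt, eP, eI);
    times[row] = tt;
    for (int i = 0; i < 10; ++i) states(row, i) = s[i];
    hP_tr[row] = p.J_PP * s[3] * s[2] * s[0] - p.J_PI * s[7] * s[6] * s[1] + eP;
    hI_tr[row] = p.J_IP * s[5] * s[4] * s[0] - p.J_II * s[9] * s[8] * s[1] + eI;
    eP_tr[row] = eP; eI_tr[row] = eI;
    ++row;
  };
  record(t);
  for (int step = 0; step < n_steps; ++step) {
    double eP_a, eI_a, eP_m, eI_m, eP_b, eI_b;
    input_at(t, eP_a, eI_a);
    input_at(t + 0.5 * dt, eP_m, eI_m);
    input_at(t + dt, eP_b, eI_b);
    rhs(p, s, eP_a, eI_a, k1);
    for (int i = 0; i < 10; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    rhs(p, tmp, eP_m, eI_m, k2);
    for (int i = 0; i < 10; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    rhs(p, tmp, eP_m, eI_m, k3);
    for (int i = 0; i < 10; ++i) tmp[i] = s[i] + dt * k3[i];
    rhs(p, tmp, eP_b, eI_b, k4);
    for (int i = 0; i < 10; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    // enforce state bounds against numerical round-off
    if (s[0] < 0) s[0] = 0;
    if (s[1] < 0) s[1] = 0;
    for (int i = 2; i < 10; i += 2) {          // x in (0, 1]
      if (s[i] > 1.0) s[i] = 1.0;
      if (s[i] < 1e-12) s[i] = 1e-12;
    }
    for (int i = 3; i < 10; i += 2)            // u below 1
      if (s[i] > 1.0 - 1e-12) s[i] = 1.0 - 1e-12;
    if (!R_finite(s[0]) || !R_finite(s[1]))
      stop("non-finite network state at t = %f", t);
    t = t0 + (step + 1) * dt;
    if ((step + 1) % record_every == 0 || step == n_steps - 1) record(t);
  }
  IntegerVector keep = seq(0, row - 1);
  return List::create(
      _["time"] = times[keep],
      _["state"] = states(Range(0, row - 1), Range(0, 9)),
      _["h_P"] = hP_tr[keep], _["h_I"] = hI_tr[keep],
      _["e_P"] = eP_tr[keep], _["e_I"] = eI_tr[keep]);
}

// Spike-time tiling coefficient matrix for a list of sorted 1-based event
// frame vectors. T_X = tiled fraction of [1, duration] by +/- dt windows,
// P_X = fraction of X's events within dt of any event of the other train;
// STTC = mean of (P_A - T_B)/(1 - P_A T_B) and (P_B - T_A)/(1 - P_B T_A).
// Empty trains or vanishing denominators give NA.
// [[Rcpp::export(name = ".sttc_matrix_cpp")]]
NumericMatrix sttc_matrix_cpp(List onsets, int dt, int duration) {
  const int n = onsets.size();
  NumericMatrix out(n, n);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<std::vector<int>> tr(n);
  std::vector<double> tiles(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = onsets[i];
    tr[i] = std::vector<int>(v.begin(), v.end());
    std::sort(tr[i].begin(), tr[i].end());
    if (tr[i].empty()) continue;
    long covered = 0;
    int cur_s = std::max(1, tr[i][0] - dt), cur_e = std::min(duration, tr[i][0] + dt);
    for (size_t k = 1; k < tr[i].size(); ++k) {
      int s = std::max(1, tr[i][k] - dt), e = std::min(duration, tr[i][k] + dt);
      if (s > cur_e + 1) {
        covered += cur_e - cur_s + 1;
        cur_s = s; cur_e = e;
      } else if (e > cur_e) cur_e = e;
    }
    covered += cur_e - cur_s + 1;
    tiles[i] = (double)covered / duration;
  }
  auto prop = [&](const std::vector<int> &a, const std::vector<int> &b) {
    int hits = 0;
    for (int v : a) {
      auto it = std::lower_bound(b.begin(), b.end(), v);
      bool near = false;
      if (it != b.end() && *it - v <= dt) near = true;
      if (!near && it != b.begin() && v - *(it - 1) <= dt) near = true;
      if (near) ++hits;
    }
    return (double)hits / a.size();
  };
  for (int i = 0; i < n - 1; ++i) {
    if (tr[i].empty()) continue;
    for (int j = i + 1; j < n; ++j) {
      if (tr[j].empty()) continue;
      double pA = prop(tr[i], tr[j]), pB = prop(tr[j], tr[i]);
      double d1 = 1 - pA * tiles[j], d2 = 1 - pB * tiles[i];
      if (d1 == 0 || d2 == 0) continue;
      out(i, j) = out(j, i) =
          0.5 * ((pA - tiles[j]) / d1 + (pB - tiles[i]) / d2);
    }
  }
  return out;
}

// Centered moving median with edge truncation. For window w the frame at
// (1-based) index i uses indices [i - (ceil(w/2)-1), i + floor(w/2)],
// clipped to the trace; even-length windows average the two middle order
// statistics.
// [[Rcpp::export(name = ".rolling_median_cpp")]]
NumericVector rolling_median_cpp(NumericVector x, int window) {
  const int n = x.size();
  if (window < 1) stop("window must be >= 1");
  NumericVector out(n);
  const int back = (window + 1) / 2 - 1;   // frames before i
  const int fwd = window / 2;              // frames after i
  std::vector<double> buf;
  buf.reserve(window + 1);
  int lo = 0, hi = -1;  // current inclusive window [lo, hi]
  for (int i = 0; i < n; ++i) {
    int nlo = std::max(0, i - back);
    int nhi = std::min(n - 1, i + fwd);
    while (hi < nhi) {
      ++hi;
      buf.insert(std::upper_bound(buf.begin(), buf.end(), x[hi]), x[hi]);
    }
    while (lo < nlo) {
      buf.erase(std::lower_bound(buf.begin(), buf.end(), x[lo]));
      ++lo;
    }
    const int m = (int)buf.size();
    out[i] = (m % 2 == 1) ? buf[m / 2] : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
  }
  return out;
}
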