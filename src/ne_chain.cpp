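#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Motoneuron action-potential train: each discharge at t_i launches one
// half-sine wave Ve*sin(2*pi/Tap*(t - t_i)) supported on [t_i, t_i + Tap/2].
// Waves from discharges closer than Tap/2 are summed (overlap handling is
// decided at the R level, which warns).
static inline double e_eval(double t, const NumericVector& sp,
                            double Ve, double Tap) {
  // contributions come from discharges in (t - Tap/2, t]
  int hi = static_cast<int>(std::upper_bound(sp.begin(), sp.end(), t) - sp.begin());
  double e = 0.0;
  for (int k = hi - 1; k >= 0 && sp[k] > t - 0.5 * Tap; --k)
    e += Ve * std::sin(2.0 * M_PI / Tap * (t - sp[k]));
  return e;
}

// [[Rcpp::export]]
NumericVector mn_ap_eval_cpp(NumericVector t, NumericVector spike_times,
                             double Ve, double Tap) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = e_eval(t[i], spike_times, Ve, Tap);
  return out;
}

struct NeParams {
  double Ve, Tap;                 // MN AP half-sine
  double a1, a2, a3;              // fibre AP (2nd order)
  double b1, b2, b3, f1, f2;      // free calcium (2nd order, length-scaled)
  double c1, c2, P0, f3, f4, f5;  // calcium-troponin binding
  double d1, d2, d3;              // active state
  double u_drive;                 // V -> drive-unit conversion for b1*u
};

// Right-hand side of the six-state chain:
// y = (u, u', c, c', P, a); e(t) is evaluated analytically.
static inline void ne_deriv(double t, const double* y, double* dy,
                            const NumericVector& sp, const NeParams& p) {
  double e = e_eval(t, sp, p.Ve, p.Tap);
  dy[0] = y[1];
  dy[1] = p.a1 * e - p.a2 * y[0] - p.a3 * y[1];
  dy[2] = y[3];
  dy[3] = p.b1 * (y[0] * p.u_drive) -
          (p.b2 * p.f2 * y[2] + p.b3 * y[3]) / p.f1;
  double c = y[2];
  dy[4] = p.c1 * p.f3 * (p.P0 * p.f4 - y[4]) * c * c - p.c2 * p.f5 * y[4];
  double den = p.d2 + p.d3 * y[4];
  dy[5] = (p.d1 * y[4] - y[5]) / den;
}

// Fixed-step RK4 over the whole chain, sampled on an output grid at fs_out.
// The internal step is (1/fs_out)/ceil(1/(fs_out*dt)) so output samples are
// landed on exactly.
// [[Rcpp::export]]
List ne_chain_cpp(NumericVector spike_times, double duration, double fs_out,
                  double dt, List params) {
  NeParams p;
  p.Ve = params["Ve"]; p.Tap = params["Tap"];
  p.a1 = params["a1"]; p.a2 = params["a2"]; p.a3 = params["a3"];
  p.b1 = params["b1"]; p.b2 = params["b2"]; p.b3 = params["b3"];
  p.f1 = params["f1"]; p.f2 = params["f2"];
  p.c1 = params["c1"]; p.c2 = params["c2"]; p.P0 = params["P0"];
  p.f3 = params["f3"]; p.f4 = params["f4"]; p.f5 = params["f5"];
  p.d1 = params["d1"]; p.d2 = params["d2"]; p.d3 = params["d3"];
  p.u_drive = params["u_drive"];

  const double out_step = 1.0 / fs_out;
  const int n_out = static_cast<int>(std::floor(duration * fs_out + 1e-9)) + 1;
  const int sub = std::max(1, static_cast<int>(std::ceil(out_step / dt - 1e-12)));
  const double h = out_step / sub;

  NumericMatrix out(n_out, 6);
  double y[6] = {0, 0, 0, 0, 0, 0};
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  int n_clamped = 0;
  double a_max_raw = 0.0;

  out(0, 0) = 0.0;
  out(0, 1) = e_eval(0.0, spike_times, p.Ve, p.Tap);

  for (int i = 1; i < n_out; ++i) {
    double t0 = (i - 1) * out_step;
    for (int s = 0; s < sub; ++s) {
      double t = t0 + s * h;
      ne_deriv(t, y, k1, spike_times, p);
      for (int j = 0; j < 6; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
      ne_deriv(t + 0.5 * h, tmp, k2, spike_times, p);
      for (int j = 0; j < 6; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
      ne_deriv(t + 0.5 * h, tmp, k3, spike_times, p);
      for (int j = 0; j < 6; ++j) tmp[j] = y[j] + h * k3[j];
      ne_deriv(t + h, tmp, k4, spike_times, p);
      for (int j = 0; j < 6; ++j)
        y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    }
    double ti = i * out_step;
    double a = y[5];
    if (a > a_max_raw) a_max_raw = a;
    double a_cl = a;
    if (a_cl > 1.0) { a_cl = 1.0; ++n_clamped; }
    if (a_cl < 0.0) { a_cl = 0.0; ++n_clamped; }
    out(i, 0) = ti;
    out(i, 1) = e_eval(ti, spike_times, p.Ve, p.Tap);
    out(i, 2) = y[0];
    out(i, 3) = y[2];
    out(i, 4) = y[4];
    out(i, 5) = a_cl;
  }
  return List::create(_["states"] = out, _["n_clamped"] = n_clamped,
                      _["a_max_raw"] = a_max_raw);
}

// Linear interpolation on a uniform grid starting at t0 with step step.
static inline double interp_u(double t, const NumericVector& y,
                              double t0, double step) {
  double x = (t - t0) / step;
  int n = y.size();
  if (x <= 0.0) return y[0];
  if (x >= n - 1) return y[n - 1];
  int i = static_cast<int>(std::floor(x));
  double w = x - i;
  return y[i] * (1.0 - w) + y[i + 1] * w;
}

// Driven linear second-order stage x'' = A*in(t) - B*x - C*x', solved with
// fixed-step RK4, input linearly interpolated from its sampling grid,
// output on the input grid.
// [[Rcpp::export]]
NumericVector ode2_driven_cpp(NumericVector in_t, NumericVector in_y,
                              double A, double B, double C, double dt) {
  int n = in_t.size();
  NumericVector out(n);
  if (n < 2) { out[0] = 0.0; return out; }
  const double t0 = in_t[0];
  const double step = in_t[1] - in_t[0];
  const int sub = std::max(1, static_cast<int>(std::ceil(step / dt - 1e-12)));
  const double h = step / sub;
  double x = 0.0, v = 0.0;
  out[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double tb = in_t[i - 1];
    for (int s = 0; s < sub; ++s) {
      double t = tb + s * h;
      double f0 = interp_u(t, in_y, t0, step);
      double fm = interp_u(t + 0.5 * h, in_y, t0, step);
      double f1v = interp_u(t + h, in_y, t0, step);
      // RK4 for (x, v)
      double k1x = v,                      k1v = A * f0 - B * x - C * v;
      double k2x = v + 0.5 * h * k1v,     k2v = A * fm - B * (x + 0.5 * h * k1x) - C * (v + 0.5 * h * k1v);
      double k3x = v + 0.5 * h * k2v,     k3v = A * fm - B * (x + 0.5 * h * k2x) - C * (v + 0.5 * h * k2v);
      double k4x = v + h * k3v,           k4v = A * f1v - B * (x + h * k3x) - C * (v + h * k3v);
      x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
      v += h / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    }
    out[i] = x;
  }
  return out;
}

// Calcium-troponin binding: dP/dt = kf*(Pmax - P)*c(t)^2 - kb*P.
// [[Rcpp::export]]
NumericVector ode_catn_cpp(NumericVector in_t, NumericVector in_c,
                           double kf, double kb, double Pmax, double dt) {
  int n = in_t.size();
  NumericVector out(n);
  if (n < 2) { out[0] = 0.0; return out; }
  const double t0 = in_t[0];
  const double step = in_t[1] - in_t[0];
  const int sub = std::max(1, static_cast<int>(std::ceil(step / dt - 1e-12)));
  const double h = step / sub;
  double P = 0.0;
  out[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double tb = in_t[i - 1];
    for (int s = 0; s < sub; ++s) {
      double t = tb + s * h;
      double c0 = interp_u(t, in_c, t0, step);
      double cm = interp_u(t + 0.5 * h, in_c, t0, step);
      double c1v = interp_u(t + h, in_c, t0, step);
      double k1 = kf * (Pmax - P) * c0 * c0 - kb * P;
      double P2 = P + 0.5 * h * k1;
      double k2 = kf * (Pmax - P2) * cm * cm - kb * P2;
      double P3 = P + 0.5 * h * k2;
      double k3 = kf * (Pmax - P3) * cm * cm - kb * P3;
      double P4 = P + h * k3;
      double k4 = kf * (Pmax - P4) * c1v * c1v - kb * P4;
      P += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    }
    out[i] = P;
  }
  return out;
}

// Active state: da/dt = (d1*P(t) - a)/(d2 + d3*P(t)); a returned unclamped.
// [[Rcpp::export]]
NumericVector ode_active_cpp(NumericVector in_t, NumericVector in_P,
                             double d1, double d2, double d3,
                             double a0, double dt) {
  int n = in_t.size();
  NumericVector out(n);
  if (n < 1) return out;
  double a = a0;
  out[0] = a;
  if (n < 2) return out;
  const double t0 = in_t[0];
  const double step = in_t[1] - in_t[0];
  const int sub = std::max(1, static_cast<int>(std::ceil(step / dt - 1e-12)));
  const double h = step / sub;
  for (int i = 1; i < n; ++i) {
    double tb = in_t[i - 1];
    for (int s = 0; s < sub; ++s) {
      double t = tb + s * h;
      double P0v = interp_u(t, in_P, t0, step);
      double Pm = interp_u(t + 0.5 * h, in_P, t0, step);
      double P1v = interp_u(t + h, in_P, t0, step);
      double k1 = (d1 * P0v - a) / (d2 + d3 * P0v);
      double a2v = a + 0.5 * h * k1;
      double k2 = (d1 * Pm - a2v) / (d2 + d3 * Pm);
      double a3v = a + 0.5 * h * k2;
      double k3 = (d1 * Pm - a3v) / (d2 + d3 * Pm);
      double a4v = a + h * k3;
      double k4 = (d1 * P1v - a4v) / (d2 + d3 * P1v);
      a += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    }
    out[i] = a;
  }
  return out;
}
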