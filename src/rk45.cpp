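// Adaptive Dormand-Prince 5(4) integration of the planar oscillator
// models. The right-hand sides are duplicated here from the R definitions
// for speed; tests cross-check the two against each other.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int id;               // 0 = FHN, 1 = S-type cc, 2 = S-type cv
  double tau0, C0, tauL, Ra, I0;        // FHN
  double a, b, c, tauk, Va, R0;         // S-type

  inline double g(double x) const {
    double den = a * (x * x - 3.0 * b * x + 3.0 * b * b) - c;
    if (den <= 0.0)
      stop("conductance undefined: denominator <= 0 at x = %f", x);
    return 1.0 / den;
  }

  inline void rhs(double u, double x, double &du, double &dx) const {
    if (id == 0) {
      du = (u - u * u * u / 3.0) / tau0 + (I0 - x) / C0;
      dx = u / (tauL * Ra) - x / tauL;
    } else {
      double gg = g(x);
      if (id == 1) du = (I0 - gg * u) / C0;
      else du = (Va / R0 - (1.0 / R0 + gg) * u) / C0;
      dx = (gg * u - x) / tauk;
    }
  }
};

} // namespace

// Dormand-Prince RK5(4)7M coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                    c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                    e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                    e6 = 22.0 / 525, e7 = -1.0 / 40;

// [[Rcpp::export(name = ".rk45_integrate")]]
NumericMatrix rk45_integrate(int model_id, NumericVector pars,
                             NumericVector y0, double t_end,
                             double rtol, double atol,
                             double h_max, int max_steps) {
  Model m;
  m.id = model_id;
  if (model_id == 0) {
    m.tau0 = pars["tau0"]; m.C0 = pars["C0"]; m.tauL = pars["tauL"];
    m.Ra = pars["Ra"]; m.I0 = pars["I0"];
  } else {
    m.a = pars["a"]; m.b = pars["b"]; m.c = pars["c"];
    m.tauk = pars["tauk"]; m.C0 = pars["C0"];
    if (model_id == 1) m.I0 = pars["I0"];
    else { m.Va = pars["Va"]; m.R0 = pars["R0"]; }
  }

  double t = 0.0, u = y0[0], x = y0[1];
  double k1u, k1x;
  m.rhs(u, x, k1u, k1x);

  // initial step: conservative fraction of the fastest local scale
  double scale = std::max(std::abs(k1u) / std::max(std::abs(u), 1.0),
                          std::abs(k1x) / std::max(std::abs(x), 1.0));
  double h = (scale > 0.0) ? 0.01 / scale : t_end / 1000.0;
  if (h > h_max) h = h_max;
  if (h > t_end) h = t_end;

  std::vector<double> ts, us, xs;
  ts.reserve(4096); us.reserve(4096); xs.reserve(4096);
  ts.push_back(t); us.push_back(u); xs.push_back(x);

  int steps = 0;
  while (t < t_end) {
    if (++steps > max_steps)
      stop("rk45: step limit (%d) exceeded at t = %f", max_steps, t);
    if (t + h > t_end) h = t_end - t;

    double k2u, k2x, k3u, k3x, k4u, k4x, k5u, k5x, k6u, k6x, k7u, k7x;
    m.rhs(u + h * a21 * k1u, x + h * a21 * k1x, k2u, k2x);
    m.rhs(u + h * (a31 * k1u + a32 * k2u),
          x + h * (a31 * k1x + a32 * k2x), k3u, k3x);
    m.rhs(u + h * (a41 * k1u + a42 * k2u + a43 * k3u),
          x + h * (a41 * k1x + a42 * k2x + a43 * k3x), k4u, k4x);
    m.rhs(u + h * (a51 * k1u + a52 * k2u + a53 * k3u + a54 * k4u),
          x + h * (a51 * k1x + a52 * k2x + a53 * k3x + a54 * k4x),
          k5u, k5x);
    m.rhs(u + h * (a61 * k1u + a62 * k2u + a63 * k3u + a64 * k4u +
                   a65 * k5u),
          x + h * (a61 * k1x + a62 * k2x + a63 * k3x + a64 * k4x +
                   a65 * k5x), k6u, k6x);
    double un = u + h * (b1 * k1u + b3 * k3u + b4 * k4u + b5 * k5u +
                         b6 * k6u);
    double xn = x + h * (b1 * k1x + b3 * k3x + b4 * k4x + b5 * k5x +
                         b6 * k6x);
    m.rhs(un, xn, k7u, k7x);

    double erru = h * (e1 * k1u + e3 * k3u + e4 * k4u + e5 * k5u +
                       e6 * k6u + e7 * k7u);
    double errx = h * (e1 * k1x + e3 * k3x + e4 * k4x + e5 * k5x +
                       e6 * k6x + e7 * k7x);
    double su = atol + rtol * std::max(std::abs(u), std::abs(un));
    double sx = atol + rtol * std::max(std::abs(x), std::abs(xn));
    double err = std::sqrt(0.5 * ((erru / su) * (erru / su) +
                                  (errx / sx) * (errx / sx)));

    if (err <= 1.0 || h <= 1e-14 * std::max(t, 1.0)) {
      t += h; u = un; x = xn; k1u = k7u; k1x = k7x;  // FSAL
      ts.push_back(t); us.push_back(u); xs.push_back(x);
      if (!std::isfinite(u) || !std::isfinite(x))
        stop("rk45: solution became non-finite at t = %f", t);
    }
    double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h > h_max) h = h_max;
  }

  NumericMatrix out(ts.size(), 3);
  for (size_t i = 0; i < ts.size(); ++i) {
    out(i, 0) = ts[i]; out(i, 1) = us[i]; out(i, 2) = xs[i];
  }
  colnames(out) = CharacterVector::create("t", "u", "x");
  return out;
}
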