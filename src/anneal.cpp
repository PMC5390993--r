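#include <Rcpp.h>
using namespace Rcpp;

// Family codes: 0 linear, 1 exponential, 2 harmonic, 3 weibull.
// All share A = value at t = 0 and k > 0 => decline; weibull nests the
// exponential at b = 1.
static inline double curve_value(int fam, double A, double k, double b,
                                 double t) {
  switch (fam) {
  case 0:
    return A - k * t;
  case 1:
    return A * std::exp(-k * t);
  case 2: {
    double den = 1.0 + k * t;
    if (den <= 0.0) return NA_REAL;
    return A / den;
  }
  default: {
    double kt = k * t;
    if (kt < 0.0) return NA_REAL;  // fractional power of a negative base
    return A * std::exp(-std::pow(kt, b));
  }
  }
}

static double sse_of(int fam, const NumericVector& t, const NumericVector& y,
                     const double* par, int npar) {
  double A = par[0], k = par[1], b = (npar > 2) ? par[2] : 1.0;
  double s = 0.0;
  int n = t.size();
  for (int i = 0; i < n; ++i) {
    double v = curve_value(fam, A, k, b, t[i]);
    if (!R_finite(v)) return R_PosInf;
    double r = y[i] - v;
    s += r * r;
  }
  return s;
}

// [[Rcpp::export(name = ".curve_values_cpp")]]
NumericVector curve_values_cpp(int fam, double A, double k, double b,
                               NumericVector t) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = curve_value(fam, A, k, b, t[i]);
  return out;
}

// [[Rcpp::export(name = ".sse_cpp")]]
double sse_cpp(int fam, NumericVector par, NumericVector t, NumericVector y) {
  return sse_of(fam, t, y, REAL(par), par.size());
}

// Bounded simulated annealing for least-squares curve fitting.
// Geometric cooling; Gaussian proposals reflected into the box; the
// acceptance criterion uses SSE normalised by n * var(y) so the initial
// temperature is on a scale-free footing. Uses R's RNG: deterministic
// under set.seed().
// [[Rcpp::export(name = ".sa_fit_cpp")]]
List sa_fit_cpp(int fam, NumericVector t, NumericVector y,
                NumericVector lower, NumericVector upper,
                double t0, double cooling, int steps, double tmin,
                double prop_frac, int restarts) {
  RNGScope scope;
  int npar = lower.size();
  int n = t.size();

  // scale-free objective: SSE / (n * var(y)); fall back to 1 if degenerate
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double yvar = 0.0;
  for (int i = 0; i < n; ++i) yvar += (y[i] - ybar) * (y[i] - ybar);
  yvar = (n > 1) ? yvar / (n - 1) : 0.0;
  double scale = n * yvar;
  if (!(scale > 0.0)) scale = 1.0;

  std::vector<double> width(npar), sd(npar);
  for (int j = 0; j < npar; ++j) {
    width[j] = upper[j] - lower[j];
    sd[j] = prop_frac * width[j];
  }

  std::vector<double> best(npar);
  double best_sse = R_PosInf;

  for (int r = 0; r < restarts; ++r) {
    std::vector<double> cur(npar), prop(npar);
    for (int j = 0; j < npar; ++j)
      cur[j] = lower[j] + unif_rand() * width[j];
    double cur_sse = sse_of(fam, t, y, cur.data(), npar);
    // re-draw a start that evaluates (harmonic/weibull domain holes)
    for (int tries = 0; tries < 50 && !R_finite(cur_sse); ++tries) {
      for (int j = 0; j < npar; ++j)
        cur[j] = lower[j] + unif_rand() * width[j];
      cur_sse = sse_of(fam, t, y, cur.data(), npar);
    }
    if (cur_sse < best_sse) {
      best_sse = cur_sse;
      best.assign(cur.begin(), cur.end());
    }
    for (double temp = t0; temp > tmin; temp *= cooling) {
      for (int s = 0; s < steps; ++s) {
        for (int j = 0; j < npar; ++j) {
          double v = cur[j] + norm_rand() * sd[j];
          // reflect into [lower, upper]
          while (v < lower[j] || v > upper[j]) {
            if (v < lower[j]) v = 2.0 * lower[j] - v;
            if (v > upper[j]) v = 2.0 * upper[j] - v;
          }
          prop[j] = v;
        }
        double prop_sse = sse_of(fam, t, y, prop.data(), npar);
        if (!R_finite(prop_sse)) continue;
        double d = (prop_sse - cur_sse) / scale;
        if (d <= 0.0 || unif_rand() < std::exp(-d / temp)) {
          cur.assign(prop.begin(), prop.end());
          cur_sse = prop_sse;
          if (cur_sse < best_sse) {
            best_sse = cur_sse;
            best.assign(cur.begin(), cur.end());
          }
        }
      }
    }
  }

  return List::create(_["par"] = NumericVector(best.begin(), best.end()),
                      _["sse"] = best_sse);
}
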