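#include <Rcpp.h>
using namespace Rcpp;

// Horner evaluation, coefficients highest-degree-first.
static inline double eval_poly(const NumericVector &c, double x) {
  double v = 0.0;
  for (R_xlen_t i = 0; i < c.size(); ++i) v = v * x + c[i];
  return v;
}

// Euler-Maruyama path of dz = g(z) dt + max(h(z), eps) sqrt(dt) dW.
// Returns n_steps + 1 values including z0. Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_sim_path(NumericVector drift, NumericVector noise, double z0,
                           double dt, int n_steps, double eps) {
  NumericVector z(n_steps + 1);
  const double sdt = std::sqrt(dt);
  double zc = z0;
  z[0] = zc;
  for (int k = 1; k <= n_steps; ++k) {
    double g = eval_poly(drift, zc);
    double h = eval_poly(noise, zc);
    if (h < eps) h = eps;
    zc += g * dt + h * sdt * norm_rand();
    if (!R_finite(zc)) stop("non-finite state at integration step %d", k);
    z[k] = zc;
  }
  return z;
}

// First-passage step count for one run. Crossing is evaluated after every
// Euler step: band rule |z - beta| < band_halfwidth, or first z >= beta.
// Returns k such that wt = k * dt, or 0 if censored at max_steps.
// [[Rcpp::export]]
int cpp_first_passage(NumericVector drift, NumericVector noise, double beta,
                      double dt, double z0, int max_steps, bool band,
                      double band_halfwidth, double eps) {
  const double sdt = std::sqrt(dt);
  double z = z0;
  for (int k = 1; k <= max_steps; ++k) {
    double g = eval_poly(drift, z);
    double h = eval_poly(noise, z);
    if (h < eps) h = eps;
    double draw = norm_rand();
    z += g * dt + h * sdt * draw;
    if (!R_finite(z)) stop("non-finite state at step %d (z update from draw %f)", k, draw);
    bool hit = band ? (std::fabs(z - beta) < band_halfwidth) : (z >= beta);
    if (hit) return k;
  }
  return 0;
}
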