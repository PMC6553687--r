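#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Continuous-time threshold engine on the conical apex.
//
// Time advances in fixed steps of dt (t = step * dt exactly, so birth times
// of primordia inserted in the same step compare equal). After each step the
// inhibitory field is evaluated on the fixed angular grid at the
// primordium-formation circle r = R0 = 1; while its global minimum is below
// the threshold Es, a primordium is inserted at the (first-encountered)
// minimising grid angle and its own contribution is added to the running
// field before re-checking, so several primordia can arise in one step at
// distinct angles but never at adjacent grid points of one basin.
//
// The kernel E(x) = Es * expm1(2 alpha) / expm1(2 alpha x), x = d / d0, is
// the numerically stable form of the coth-based threshold kernel; at d = 0
// it diverges to +Inf (self-exclusion) and at large x it underflows cleanly
// to 0. The conical distance is
//   d^2 = rad_fac * (r1 - r2)^2 + ang_fac * r1 r2 (1 - cos(theta1 - theta2)),
// with (rad_fac, ang_fac) supplied by the R wrapper according to the
// distance reading in the parameter record (the default Euclidean chord has
// rad_fac = 1, ang_fac = 2 N^2). All primordium angles lie on the grid, so
// cos(theta_i - theta_m) is read from a circulant table.
//
// Primordia older than the pruning horizon (maximum possible contribution
// below prune_tol * Es even with age factor 1) are skipped; they only
// recede, so the active window [first_active, count) shrinks monotonically
// from the left. Pruning is disabled when a ramp could re-grow d0.

// [[Rcpp::export]]
List dc2_engine(NumericVector theta0_deg, NumericVector t0,
                double alpha, double N, double Es,
                double Gamma, bool has_ramp,
                double ramp_gi, double ramp_gf, double ramp_ti, double ramp_tau,
                bool extended, double A, double B,
                double res_deg, double dt, int max_prim,
                bool prune, double prune_tol, double t_max, int scan_dir,
                double rad_fac_in, double ang_fac) {
  const int n_grid = (int)std::lround(360.0 / res_deg);
  if (std::fabs(n_grid * res_deg - 360.0) > 1e-9)
    stop("angle resolution must divide 360 degrees");
  const int n_init = theta0_deg.size();
  if (n_init < 1 || n_init > max_prim) stop("invalid initial condition");

  std::vector<double> costab(n_grid);
  for (int i = 0; i < n_grid; ++i)
    costab[i] = std::cos(2.0 * M_PI * i / n_grid);

  std::vector<int> idx(max_prim);
  std::vector<double> birth(max_prim), minf(max_prim);
  int count = 0;
  for (int m = 0; m < n_init; ++m) {
    int j = (int)std::lround(theta0_deg[m] / res_deg) % n_grid;
    if (j < 0) j += n_grid;
    idx[count] = j;
    birth[count] = t0[m];
    minf[count] = NA_REAL;
    ++count;
  }

  const double coef = Es * std::expm1(2.0 * alpha);
  std::vector<double> I(n_grid);
  int first_active = 0;
  const bool prune_ok = prune && (!has_ramp || ramp_gf <= ramp_gi);

  long step = -1;  // first pass evaluates the field at t = 0
  while (count < max_prim) {
    ++step;
    double t = step * dt;
    if (t > t_max)
      stop("simulation exceeded the time guard without reaching the primordium count");

    double gamma_t = Gamma;
    if (has_ramp)
      gamma_t = 0.5 * (ramp_gi + ramp_gf) -
                0.5 * (ramp_gi - ramp_gf) * std::tanh((t - ramp_ti) / ramp_tau);
    const double d0 = gamma_t * N;
    const double k2 = 2.0 * alpha / d0;
    const double rad_fac = rad_fac_in;
    const double sq_rad = std::sqrt(rad_fac);

    if (prune_ok) {
      while (first_active < count - 1) {
        double r = std::exp(t - birth[first_active]);
        double dmin = sq_rad * (r - 1.0);
        double bound = coef / std::expm1(k2 * dmin);  // age factor <= 1
        if (bound < prune_tol * Es) ++first_active; else break;
      }
    }

    // field on the grid from all active primordia
    std::fill(I.begin(), I.end(), 0.0);
    for (int m = first_active; m < count; ++m) {
      double age = t - birth[m];
      double r = std::exp(age);
      double w = extended ? 1.0 / (1.0 + std::exp(-A * (age - B))) : 1.0;
      double c1 = rad_fac * (r - 1.0) * (r - 1.0) + ang_fac * r;
      double c2 = ang_fac * r;
      double cw = coef * w;
      int im = idx[m];
      for (int i = 0; i < n_grid; ++i) {
        int j = i - im; if (j < 0) j += n_grid;
        double d2 = c1 - c2 * costab[j];
        double d = d2 > 0.0 ? std::sqrt(d2) : 0.0;
        I[i] += cw / std::expm1(k2 * d);  // d = 0 -> +Inf (self-exclusion)
      }
    }

    // threshold-triggered insertions, possibly several per step
    int inserted_this_step = 0;
    for (;;) {
      int arg = -1;
      double mn = R_PosInf;
      if (scan_dir >= 0) {
        for (int i = 0; i < n_grid; ++i)
          if (I[i] < mn) { mn = I[i]; arg = i; }
      } else {
        for (int i = n_grid - 1; i >= 0; --i)
          if (I[i] < mn) { mn = I[i]; arg = i; }
      }
      if (!(mn < Es) || count >= max_prim) break;
      if (++inserted_this_step > n_grid)
        stop("runaway insertion: more primordia than grid points in one step "
             "(parameter pathology)");
      idx[count] = arg;
      birth[count] = t;
      minf[count] = mn;
      ++count;
      // add the newborn's own contribution (age 0, r = 1)
      double w = extended ? 1.0 / (1.0 + std::exp(A * B)) : 1.0;
      double cw = coef * w;
      double c1 = ang_fac, c2 = ang_fac;
      for (int i = 0; i < n_grid; ++i) {
        int j = i - arg; if (j < 0) j += n_grid;
        double d2 = c1 - c2 * costab[j];
        double d = d2 > 0.0 ? std::sqrt(d2) : 0.0;
        I[i] += cw / std::expm1(k2 * d);
      }
    }
  }

  NumericVector out_theta(count), out_birth(count), out_minf(count);
  for (int m = 0; m < count; ++m) {
    out_theta[m] = idx[m] * res_deg;
    out_birth[m] = birth[m];
    out_minf[m] = minf[m];
  }
  return List::create(_["theta"] = out_theta,
                      _["birth_time"] = out_birth,
                      _["min_field"] = out_minf);
}
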