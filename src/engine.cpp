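#include <Rcpp.h>
using namespace Rcpp;

// Langevin / steered-dynamics engine for the 1-D toy model systems.
// Atoms live on the x axis; `mobile` marks the propagated coordinates.
// Uses R's RNG (norm_rand) so set.seed() gives bit-identical trajectories.
//
// potential ids: 0 = flat (uniform landscape), 1 = harmonic well,
//                2 = quartic double well.
// control modes: 0 = none (equilibrium), 1 = harmonic restraint on the LCOD
//                CV with target lambda(t), 2 = lambda(t) is the harmonic-well
//                stiffness itself (thermodynamic control parameter).
// Work quadrature: midpoint rule in lambda per integrator step, with
// dU/dlambda evaluated at the pre-step state (documented in the vignette so
// analytic oracles can match the discretization exactly).

static const double KB_KCAL = 0.0019872041; // kcal/(mol K)

struct Potential {
  int id;
  int atom;          // 0-based index the potential acts on
  double p1, p2, p3; // harmonic: kappa, center; quartic: V0, center, half-width
};

static inline double pot_energy(const Potential &P, const double *x,
                                double kappa_override, bool use_override) {
  double xi = x[P.atom];
  switch (P.id) {
  case 0: return 0.0;
  case 1: {
    double kap = use_override ? kappa_override : P.p1;
    double d = xi - P.p2;
    return 0.5 * kap * d * d;
  }
  case 2: {
    double u = (xi - P.p2) / P.p3;
    double q = u * u - 1.0;
    return P.p1 * q * q;
  }
  }
  return 0.0;
}

static inline double pot_force(const Potential &P, const double *x,
                               double kappa_override, bool use_override) {
  // force on P.atom (other atoms feel nothing from these site potentials)
  double xi = x[P.atom];
  switch (P.id) {
  case 0: return 0.0;
  case 1: {
    double kap = use_override ? kappa_override : P.p1;
    return -kap * (xi - P.p2);
  }
  case 2: {
    double u = (xi - P.p2) / P.p3;
    return -4.0 * P.p1 * (u * u - 1.0) * u / P.p3;
  }
  }
  return 0.0;
}

static inline double lcod_value(const double *x, const int *pa, const int *pb,
                                const double *cf, int np) {
  double v = 0.0;
  for (int i = 0; i < np; ++i) v += cf[i] * std::fabs(x[pa[i]] - x[pb[i]]);
  return v;
}

// accumulate -dU_restraint/dx into f for harmonic CV restraint at target lam
static inline double restraint_force(double *f, const double *x, const int *pa,
                                     const int *pb, const double *cf, int np,
                                     double k, double lam) {
  double cv = lcod_value(x, pa, pb, cf, np);
  double pre = -k * (cv - lam); // = -dU/dcv
  for (int i = 0; i < np; ++i) {
    double dx = x[pa[i]] - x[pb[i]];
    double s = (dx > 0) ? 1.0 : ((dx < 0) ? -1.0 : 0.0);
    f[pa[i]] += pre * cf[i] * s;
    f[pb[i]] -= pre * cf[i] * s;
  }
  return 0.5 * k * (cv - lam) * (cv - lam);
}

static inline double flatwell_force(double *f, const double *x, int center,
                                    const int *sat, int ns, double radius,
                                    double kw) {
  double e = 0.0;
  for (int i = 0; i < ns; ++i) {
    double dx = x[sat[i]] - x[center];
    double d = std::fabs(dx);
    if (d > radius) {
      double ex = d - radius;
      e += 0.5 * kw * ex * ex;
      double s = (dx > 0) ? 1.0 : -1.0;
      f[sat[i]] -= kw * ex * s;
      f[center] += kw * ex * s;
    }
  }
  return e;
}

// [[Rcpp::export]]
List engine_run(NumericVector x0, LogicalVector mobile, int potential_id,
                int potential_atom, NumericVector potential_params,
                int control_mode, IntegerVector pair_a, IntegerVector pair_b,
                NumericVector coeff, double k_restraint, double lambda0,
                double lambda1, int fw_center, IntegerVector fw_sat,
                double fw_radius, double fw_k, int n_steps, double dt,
                double temperature, double gamma, double mass,
                int integrator_id, int sample_interval) {
  int na = x0.size();
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (dt <= 0) stop("dt must be > 0");
  if (gamma <= 0) stop("gamma must be > 0");
  if (temperature < 0) stop("temperature must be >= 0");
  if (sample_interval < 1) stop("sample_interval must be >= 1");
  int np = pair_a.size();
  for (int i = 0; i < np; ++i) {
    if (pair_a[i] < 0 || pair_a[i] >= na || pair_b[i] < 0 || pair_b[i] >= na)
      stop("CV atom index out of range");
  }
  int ns = fw_sat.size();

  Potential P;
  P.id = potential_id;
  P.atom = potential_atom;
  P.p1 = potential_params.size() > 0 ? potential_params[0] : 0.0;
  P.p2 = potential_params.size() > 1 ? potential_params[1] : 0.0;
  P.p3 = potential_params.size() > 2 ? potential_params[2] : 1.0;
  if (P.id == 2 && P.p3 <= 0) stop("quartic half-width must be > 0");
  bool stiff_ctrl = (control_mode == 2);
  if (stiff_ctrl && P.id != 1)
    stop("stiffness control requires a harmonic potential");

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(na, 0.0), f(na, 0.0);
  std::vector<int> mob;
  for (int i = 0; i < na; ++i) if (mobile[i]) mob.push_back(i);
  if (mob.empty()) stop("no mobile atoms");

  double kT = KB_KCAL * temperature;
  double dlam = (lambda1 - lambda0) / n_steps;

  // sample bookkeeping
  int n_rec = 1 + n_steps / sample_interval + ((n_steps % sample_interval) ? 1 : 0);
  NumericVector rt(n_rec), rlam(n_rec), rw(n_rec), rcv(n_rec), rre(n_rec);
  NumericMatrix rpos(n_rec, na);

  // BAOAB constants
  double c1 = std::exp(-gamma * dt), c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));
  double em_a = dt / gamma, em_b = std::sqrt(2.0 * kT * dt / gamma);

  double work = 0.0;

  // force at current state under control value lam
  auto eval_forces = [&](double lam) -> double {
    std::fill(f.begin(), f.end(), 0.0);
    double re = 0.0;
    f[P.atom] += pot_force(P, x.data(), lam, stiff_ctrl);
    if (control_mode == 1)
      re = restraint_force(f.data(), x.data(), pair_a.begin(), pair_b.begin(),
                           coeff.begin(), np, k_restraint, lam);
    if (ns > 0)
      flatwell_force(f.data(), x.data(), fw_center, fw_sat.begin(), ns,
                     fw_radius, fw_k);
    return re;
  };

  auto record = [&](int idx, int step, double lam) {
    rt[idx] = step * dt;
    rlam[idx] = lam;
    rw[idx] = work;
    double cv = lcod_value(x.data(), pair_a.begin(), pair_b.begin(),
                           coeff.begin(), np);
    rcv[idx] = cv;
    rre[idx] = (control_mode == 1) ? 0.5 * k_restraint * (cv - lam) * (cv - lam)
                                   : 0.0;
    for (int i = 0; i < na; ++i) {
      if (!R_finite(x[i]))
        stop("non-finite coordinate at step %d (atom %d)", step, i + 1);
      rpos(idx, i) = x[i];
    }
  };

  RNGScope rng;
  record(0, 0, lambda0);
  int rec = 1;

  for (int n = 0; n < n_steps; ++n) {
    double lam_n = lambda0 + dlam * n;
    double lam_np1 = (n + 1 == n_steps) ? lambda1 : lambda0 + dlam * (n + 1);
    double lam_mid = 0.5 * (lam_n + lam_np1);

    // work increment dW = (dU/dlambda) * dlambda at the pre-step state
    if (control_mode == 1 && dlam != 0.0) {
      double cv = lcod_value(x.data(), pair_a.begin(), pair_b.begin(),
                             coeff.begin(), np);
      work += -k_restraint * (cv - lam_mid) * (lam_np1 - lam_n);
    } else if (control_mode == 2 && dlam != 0.0) {
      double d = x[P.atom] - P.p2;
      work += 0.5 * d * d * (lam_np1 - lam_n);
    }

    if (integrator_id == 0) { // overdamped Euler-Maruyama
      eval_forces(lam_np1);
      for (size_t m = 0; m < mob.size(); ++m) {
        int i = mob[m];
        double xi = x[i] + em_a * f[i];
        if (kT > 0) xi += em_b * norm_rand();
        x[i] = xi;
      }
    } else { // BAOAB
      eval_forces(lam_np1);
      for (size_t m = 0; m < mob.size(); ++m) {
        int i = mob[m];
        v[i] += 0.5 * dt * f[i] / mass;
        x[i] += 0.5 * dt * v[i];
      }
      for (size_t m = 0; m < mob.size(); ++m) {
        int i = mob[m];
        v[i] = c1 * v[i];
        if (kT > 0) v[i] += c2 * norm_rand();
        x[i] += 0.5 * dt * v[i];
      }
      eval_forces(lam_np1);
      for (size_t m = 0; m < mob.size(); ++m) {
        int i = mob[m];
        v[i] += 0.5 * dt * f[i] / mass;
      }
    }

    if ((n + 1) % sample_interval == 0 || n + 1 == n_steps) {
      record(rec, n + 1, lam_np1);
      ++rec;
    }
  }

  return List::create(_["time"] = rt, _["lambda"] = rlam, _["work"] = rw,
                      _["cv"] = rcv, _["restraint_energy"] = rre,
                      _["positions"] = rpos);
}
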