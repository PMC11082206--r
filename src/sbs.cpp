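#include <Rcpp.h>
using namespace Rcpp;

// Strings-and-binders (SBS) sampler.
//
// Particles: n_beads chain beads followed by diffusing binders, in reduced
// units (bead diameter sigma = 1, kT = 1, mass = 1). Potentials:
//  - consecutive beads (and the closing pair on circular chains): harmonic
//    bond 0.5*kb*(r-r0)^2;
//  - non-bonded bead-bead: WCA (purely repulsive LJ, cut at 2^(1/6));
//  - bead-binder: truncated-shifted LJ of depth E*multiplicity (cut 2.5) when
//    the bead carries sites of the binder's class and E > 0, else WCA;
//  - binder-binder: none (ideal);
//  - soft wall confining all particles to a cube of side `box` centred at 0.
// Both samplers share the exact same potential so Metropolis Monte Carlo and
// Langevin dynamics target the same Boltzmann ensemble.

struct SBSContext {
  int n_beads, n_part, M;
  const double* binding;     // n_beads x M, column-major
  std::vector<int> binder_class;
  double E, box, kb, r0, kw;
  bool circular;

  bool bonded(int i, int j) const {
    if (i > j) std::swap(i, j);
    if (j == i + 1 && j < n_beads) return true;
    if (circular && i == 0 && j == n_beads - 1) return true;
    return false;
  }
  double mult(int bead, int cls) const {
    return binding[bead + (size_t)n_beads * cls];
  }
};

static const double WCA_CUT2 = 1.259921049894873;        // 2^(1/3) = (2^(1/6))^2
static const double LJ_CUT = 2.5, LJ_CUT2 = 6.25;
static const double LJ_SHIFT = 4.0 * (std::pow(LJ_CUT, -12.0) - std::pow(LJ_CUT, -6.0));

static inline double pair_u(double r2, double eps, bool attractive) {
  if (attractive) {
    if (r2 >= LJ_CUT2) return 0.0;
    double ir6 = 1.0 / (r2 * r2 * r2);
    return 4.0 * eps * (ir6 * ir6 - ir6) - eps * LJ_SHIFT;
  }
  if (r2 >= WCA_CUT2) return 0.0;
  double ir6 = 1.0 / (r2 * r2 * r2);
  return 4.0 * eps * (ir6 * ir6 - ir6) + eps;
}

// returns dU/dr / r (multiply by the separation vector for the force on j);
// clamped at core overlaps so startup configurations cannot blow up the
// integrator (the clamp radius sits far above kT, so equilibrium never
// feels it)
static inline double pair_ffac(double r2, double eps, bool attractive) {
  double cut2 = attractive ? LJ_CUT2 : WCA_CUT2;
  if (r2 >= cut2) return 0.0;
  double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2;
  double f = -24.0 * eps * (2.0 * ir6 * ir6 - ir6) * ir2;
  const double fmax = 1e3;
  if (f > fmax) f = fmax;
  if (f < -fmax) f = -fmax;
  return f;
}

// interaction spec for particles i (bead) and j (bead or binder)
static inline void pair_spec(const SBSContext& ctx, int i, int j,
                             double& eps, bool& attractive) {
  eps = 1.0; attractive = false;
  bool i_bead = i < ctx.n_beads, j_bead = j < ctx.n_beads;
  if (i_bead && j_bead) return;                   // WCA
  if (!i_bead && !j_bead) { eps = 0.0; return; }  // binders ideal
  int bead = i_bead ? i : j;
  int cls = ctx.binder_class[(i_bead ? j : i) - ctx.n_beads];
  double m = ctx.mult(bead, cls);
  if (ctx.E > 0 && m > 0) { eps = ctx.E * m; attractive = true; }
}

static inline double wall_u(const SBSContext& ctx, const double* x) {
  double u = 0.0, half = ctx.box / 2.0;
  for (int d = 0; d < 3; ++d) {
    double ex = std::fabs(x[d]) - half;
    if (ex > 0) u += 0.5 * ctx.kw * ex * ex;
  }
  return u;
}

// energy of particle k against everything else (bond terms counted once here)
static double particle_energy(const SBSContext& ctx, const std::vector<double>& X,
                              int k, const double* xk) {
  double u = wall_u(ctx, xk);
  for (int j = 0; j < ctx.n_part; ++j) {
    if (j == k) continue;
    double dx = xk[0] - X[3 * j], dy = xk[1] - X[3 * j + 1], dz = xk[2] - X[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (k < ctx.n_beads && j < ctx.n_beads && ctx.bonded(k, j)) {
      double r = std::sqrt(r2), d = r - ctx.r0;
      u += 0.5 * ctx.kb * d * d;
      continue;
    }
    double eps; bool attr;
    pair_spec(ctx, k, j, eps, attr);
    if (eps > 0) u += pair_u(r2, eps, attr);
  }
  return u;
}

static void forces(const SBSContext& ctx, const std::vector<double>& X,
                   std::vector<double>& F) {
  std::fill(F.begin(), F.end(), 0.0);
  double half = ctx.box / 2.0;
  for (int i = 0; i < ctx.n_part; ++i)
    for (int d = 0; d < 3; ++d) {
      double xd = X[3 * i + d], ex = std::fabs(xd) - half;
      if (ex > 0) F[3 * i + d] -= ctx.kw * ex * (xd > 0 ? 1.0 : -1.0);
    }
  for (int i = 0; i < ctx.n_part; ++i)
    for (int j = i + 1; j < ctx.n_part; ++j) {
      double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
             dz = X[3 * i + 2] - X[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double ffac = 0.0;
      if (i < ctx.n_beads && j < ctx.n_beads && ctx.bonded(i, j)) {
        double r = std::sqrt(r2);
        ffac = ctx.kb * (r - ctx.r0) / (r > 1e-12 ? r : 1e-12);
      } else {
        double eps; bool attr;
        pair_spec(ctx, i, j, eps, attr);
        if (eps > 0) ffac = pair_ffac(r2, eps, attr);
      }
      if (ffac != 0.0) {
        // F_i = -dU/dr * rhat, with ffac = (dU/dr)/r
        F[3 * i] -= ffac * dx; F[3 * i + 1] -= ffac * dy; F[3 * i + 2] -= ffac * dz;
        F[3 * j] += ffac * dx; F[3 * j + 1] += ffac * dy; F[3 * j + 2] += ffac * dz;
      }
    }
}

static SBSContext make_ctx(const NumericMatrix& binding, const IntegerVector& binder_class,
                           double E, bool circular, double box,
                           double kb, double r0, double kw, int n_part) {
  SBSContext ctx;
  ctx.n_beads = binding.nrow();
  ctx.M = binding.ncol();
  ctx.n_part = n_part;
  ctx.binding = binding.begin();
  ctx.binder_class = as<std::vector<int>>(binder_class);
  ctx.E = E; ctx.box = box; ctx.kb = kb; ctx.r0 = r0; ctx.kw = kw;
  ctx.circular = circular;
  return ctx;
}

static void check_finite(const std::vector<double>& X, int step) {
  for (double v : X)
    if (!std::isfinite(v))
      stop("simulation diverged: non-finite coordinates at step %d", step);
}

// [[Rcpp::export]]
List sbs_mc_cpp(const NumericMatrix& X0, const NumericMatrix& binding,
                const IntegerVector& binder_class, double E, bool circular,
                double box, int n_sweeps, int sample_every,
                double delta, double kb, double r0, double kw) {
  const int n_part = X0.nrow();
  SBSContext ctx = make_ctx(binding, binder_class, E, circular, box, kb, r0, kw, n_part);
  std::vector<double> X(3 * n_part);
  for (int i = 0; i < n_part; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = X0(i, d);

  int n_frames = n_sweeps / sample_every;
  NumericVector frames(Dimension(ctx.n_beads, 3, n_frames));
  long tried = 0, acc = 0;
  int frame = 0;
  double xn[3];

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < n_part; ++m) {
      int k = (int)(unif_rand() * n_part); if (k >= n_part) k = n_part - 1;
      double u_old = particle_energy(ctx, X, k, &X[3 * k]);
      for (int d = 0; d < 3; ++d)
        xn[d] = X[3 * k + d] + delta * (2.0 * unif_rand() - 1.0);
      double u_new = particle_energy(ctx, X, k, xn);
      ++tried;
      double du = u_new - u_old;
      if (du <= 0 || unif_rand() < std::exp(-du)) {
        for (int d = 0; d < 3; ++d) X[3 * k + d] = xn[d];
        ++acc;
      }
    }
    if (sweep % sample_every == 0 && frame < n_frames) {
      check_finite(X, sweep);
      for (int i = 0; i < ctx.n_beads; ++i)
        for (int d = 0; d < 3; ++d)
          frames[i + ctx.n_beads * (d + 3 * frame)] = X[3 * i + d];
      ++frame;
    }
  }

  return List::create(_["frames"] = frames,
                      _["accept_rate"] = tried ? (double)acc / tried : NA_REAL);
}

// [[Rcpp::export]]
List sbs_ld_cpp(const NumericMatrix& X0, const NumericMatrix& binding,
                const IntegerVector& binder_class, double E, bool circular,
                double box, int n_steps, int sample_every,
                double dt, double gamma, double kb, double r0, double kw) {
  const int n_part = X0.nrow();
  SBSContext ctx = make_ctx(binding, binder_class, E, circular, box, kb, r0, kw, n_part);
  std::vector<double> X(3 * n_part), V(3 * n_part), F(3 * n_part);
  for (int i = 0; i < n_part; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = X0(i, d);
  for (double& v : V) v = norm_rand();   // kT = 1, m = 1

  // BAOAB splitting: exact Ornstein-Uhlenbeck middle step
  const double c1 = std::exp(-gamma * dt), c2 = std::sqrt(1.0 - c1 * c1);
  forces(ctx, X, F);

  int n_frames = n_steps / sample_every;
  NumericVector frames(Dimension(ctx.n_beads, 3, n_frames));
  int frame = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n_part; ++i) V[i] += 0.5 * dt * F[i];
    for (int i = 0; i < 3 * n_part; ++i) X[i] += 0.5 * dt * V[i];
    for (int i = 0; i < 3 * n_part; ++i) V[i] = c1 * V[i] + c2 * norm_rand();
    for (int i = 0; i < 3 * n_part; ++i) X[i] += 0.5 * dt * V[i];
    forces(ctx, X, F);
    for (int i = 0; i < 3 * n_part; ++i) V[i] += 0.5 * dt * F[i];

    if (step % sample_every == 0 && frame < n_frames) {
      check_finite(X, step);
      for (int i = 0; i < ctx.n_beads; ++i)
        for (int d = 0; d < 3; ++d)
          frames[i + ctx.n_beads * (d + 3 * frame)] = X[3 * i + d];
      ++frame;
    }
  }

  return List::create(_["frames"] = frames, _["accept_rate"] = NA_REAL);
}
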