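#include <Rcpp.h>
using namespace Rcpp;

// Simulated-annealing inference of binding-site multiplicities.
//
// State: b (n x M integer multiplicities), affinity A_ij = sum_c min(b_ic, b_jc)
// (optionally class-weighted), reconstruction R_ij = p0_ij * (1 + kappa * A_ij).
// Cost = || Tn - R/S ||_{L1 or L2 over upper triangle} + lambda * total sites,
// with S the upper-triangle sum of R, so only shapes are compared.
// Each iteration draws `n_prop` tentative single-site modifications, evaluates
// all of them, and submits the best to a Metropolis accept/reject at the
// current temperature.

static inline int rint_below(int n) {
  // uniform integer in [0, n-1] from R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Move {
  int bead;
  int cls_from;   // -1 when pure addition
  int cls_to;     // -1 when pure removal
};

// [[Rcpp::export]]
List sa_fit_cpp(const NumericMatrix& Tn, const NumericMatrix& p0,
                double kappa, const NumericVector& s_c,
                int M, double lambda, int n_iter, int n_prop,
                double t0, double cooling, int max_mult,
                bool l2, int trace_every, const IntegerMatrix& b0) {
  const int n = Tn.nrow();
  IntegerMatrix b = clone(b0);         // multiplicities, start from b0
  NumericMatrix R(n, n);               // reconstruction (upper triangle used)

  double S = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double a = 0.0;
      for (int c = 0; c < M; ++c)
        a += s_c[c] * std::min((double)b(i, c), (double)b(j, c));
      R(i, j) = p0(i, j) * (1.0 + kappa * a);
      S += R(i, j);
    }

  auto full_cost_fid = [&](int row, const std::vector<double>& newRrow,
                           double Snew) -> double {
    // Cost with row/col `row` replaced by newRrow (row < 0: current state).
    double c = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r = R(i, j);
        if (row >= 0) {
          if (i == row) r = newRrow[j];
          else if (j == row) r = newRrow[i];
        }
        double d = Tn(i, j) - r / Snew;
        c += l2 ? d * d : std::fabs(d);
      }
    return c;
  };

  int total_sites = 0;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < M; ++c) total_sites += b(i, c);
  std::vector<double> dummy;
  double cost_fid = full_cost_fid(-1, dummy, S);
  double cost = cost_fid + lambda * total_sites;

  IntegerMatrix best_b = clone(b);
  double best_cost = cost, best_fid = cost_fid;

  int n_trace = (trace_every > 0) ? (n_iter / trace_every + 1) : 0;
  NumericVector trace_iter(n_trace), trace_cost(n_trace), trace_fid(n_trace);
  int trace_k = 0;
  long accepted = 0;

  std::vector<double> newRrow(n), bestRrow(n);
  std::vector<double> dA(n);

  // full-recompute cost of an arbitrary candidate table (segment moves)
  auto table_cost = [&](const IntegerMatrix& bc, double& fid_out,
                        double& S_out, int& sites_out) {
    double Sc = 0.0;
    fid_out = 0.0;
    std::vector<double> Rrow;
    NumericMatrix Rc(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double a = 0.0;
        for (int c = 0; c < M; ++c)
          a += s_c[c] * std::min((double)bc(i, c), (double)bc(j, c));
        Rc(i, j) = p0(i, j) * (1.0 + kappa * a);
        Sc += Rc(i, j);
      }
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d = Tn(i, j) - Rc(i, j) / Sc;
        fid_out += l2 ? d * d : std::fabs(d);
      }
    S_out = Sc;
    int tot = 0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < M; ++c) tot += bc(i, c);
    sites_out = tot;
  };

  auto rebuild_state = [&]() {
    S = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double a = 0.0;
        for (int c = 0; c < M; ++c)
          a += s_c[c] * std::min((double)b(i, c), (double)b(j, c));
        R(i, j) = p0(i, j) * (1.0 + kappa * a);
        S += R(i, j);
      }
  };

  const double p_seg = (M > 1) ? 0.25 : 0.0;
  double T = t0;
  for (int it = 0; it < n_iter; ++it, T *= cooling) {
    // Occasionally propose relabeling a short run of beads from one class to
    // another: single-site moves cannot cross the barrier between class-
    // labeling optima (splitting a merged class degrades the fit until many
    // beads have moved), segment moves can.
    if (p_seg > 0 && unif_rand() < p_seg) {
      double seg_best_cost = R_PosInf, seg_best_fid = 0.0;
      IntegerMatrix seg_best_b;
      int seg_best_sites = 0;
      int n_seg_prop = std::min(n_prop, 2);
      for (int p = 0; p < n_seg_prop; ++p) {
        int start = rint_below(n);
        int len = 3 + rint_below(23);
        int c_from = rint_below(M);
        int c_to = rint_below(M - 1);
        if (c_to >= c_from) ++c_to;
        IntegerMatrix bc = clone(b);
        bool changed = false;
        for (int i = start; i < std::min(start + len, n); ++i) {
          if (bc(i, c_from) > 0 && bc(i, c_to) < max_mult) {
            bc(i, c_from) -= 1; bc(i, c_to) += 1; changed = true;
          }
        }
        if (!changed) continue;
        double fid, Sc; int sites;
        table_cost(bc, fid, Sc, sites);
        double c_tot = fid + lambda * sites;
        if (c_tot < seg_best_cost) {
          seg_best_cost = c_tot; seg_best_fid = fid;
          seg_best_b = bc; seg_best_sites = sites;
        }
      }
      if (R_finite(seg_best_cost)) {
        double dc = seg_best_cost - cost;
        if (dc <= 0 || (T > 0 && unif_rand() < std::exp(-dc / T))) {
          b = seg_best_b;
          total_sites = seg_best_sites;
          cost = seg_best_cost; cost_fid = seg_best_fid;
          rebuild_state();
          ++accepted;
          if (cost < best_cost) {
            best_cost = cost; best_fid = cost_fid; best_b = clone(b);
          }
        }
      }
      if (trace_every > 0 && it % trace_every == 0 && trace_k < n_trace) {
        trace_iter[trace_k] = it; trace_cost[trace_k] = best_cost;
        trace_fid[trace_k] = best_fid; ++trace_k;
      }
      continue;
    }
    double prop_best_cost = R_PosInf, prop_best_fid = 0.0, prop_best_S = 0.0;
    Move prop_best{-1, -1, -1};
    int prop_best_dsites = 0;

    for (int p = 0; p < n_prop; ++p) {
      int bead = rint_below(n);
      int action = rint_below(3);  // 0 add, 1 remove, 2 swap
      Move mv{bead, -1, -1};
      int dsites = 0;

      if (action == 0) {
        int c = rint_below(M);
        if (b(bead, c) >= max_mult) continue;
        mv.cls_to = c; dsites = 1;
      } else {
        // pick an occupied class uniformly
        int occ = 0;
        for (int c = 0; c < M; ++c) if (b(bead, c) > 0) ++occ;
        if (occ == 0) continue;
        int pick = rint_below(occ), c_from = -1;
        for (int c = 0; c < M; ++c)
          if (b(bead, c) > 0 && pick-- == 0) { c_from = c; break; }
        if (action == 1) {
          mv.cls_from = c_from; dsites = -1;
        } else {
          if (M < 2) continue;
          int c_to = rint_below(M - 1);
          if (c_to >= c_from) ++c_to;
          if (b(bead, c_to) >= max_mult) continue;
          mv.cls_from = c_from; mv.cls_to = c_to; dsites = 0;
        }
      }

      // affinity deltas on row `bead`
      std::fill(dA.begin(), dA.end(), 0.0);
      if (mv.cls_from >= 0) {
        int c = mv.cls_from, bi = b(bead, c);
        for (int j = 0; j < n; ++j) {
          if (j == bead) continue;
          double bj = b(j, c);
          dA[j] += s_c[c] * (std::min((double)(bi - 1), bj) - std::min((double)bi, bj));
        }
      }
      if (mv.cls_to >= 0) {
        int c = mv.cls_to, bi = b(bead, c);
        for (int j = 0; j < n; ++j) {
          if (j == bead) continue;
          double bj = b(j, c);
          dA[j] += s_c[c] * (std::min((double)(bi + 1), bj) - std::min((double)bi, bj));
        }
      }

      double Snew = S;
      for (int j = 0; j < n; ++j) {
        if (j == bead) { newRrow[j] = 0.0; continue; }
        double Rij = (bead < j) ? R(bead, j) : R(j, bead);
        double Rnew = Rij + p0(bead, j) * kappa * dA[j];
        newRrow[j] = Rnew;
        Snew += Rnew - Rij;
      }
      if (Snew <= 0) continue;

      double fid = full_cost_fid(bead, newRrow, Snew);
      double c_tot = fid + lambda * (total_sites + dsites);
      if (c_tot < prop_best_cost) {
        prop_best_cost = c_tot; prop_best_fid = fid; prop_best_S = Snew;
        prop_best = mv; prop_best_dsites = dsites;
        bestRrow = newRrow;
      }
    }

    if (prop_best.bead >= 0) {
      double dc = prop_best_cost - cost;
      bool take = (dc <= 0) || (T > 0 && unif_rand() < std::exp(-dc / T));
      if (take) {
        int bead = prop_best.bead;
        if (prop_best.cls_from >= 0) b(bead, prop_best.cls_from) -= 1;
        if (prop_best.cls_to >= 0)   b(bead, prop_best.cls_to)   += 1;
        for (int j = 0; j < n; ++j) {
          if (j == bead) continue;
          if (bead < j) R(bead, j) = bestRrow[j];
          else          R(j, bead) = bestRrow[j];
        }
        S = prop_best_S;
        total_sites += prop_best_dsites;
        cost = prop_best_cost; cost_fid = prop_best_fid;
        ++accepted;
        if (cost < best_cost) {
          best_cost = cost; best_fid = cost_fid; best_b = clone(b);
        }
      }
    }

    if (trace_every > 0 && it % trace_every == 0 && trace_k < n_trace) {
      trace_iter[trace_k] = it;
      trace_cost[trace_k] = best_cost;
      trace_fid[trace_k] = best_fid;
      ++trace_k;
    }
  }

  return List::create(
    _["binding"] = best_b,
    _["cost"] = best_cost,
    _["fidelity_cost"] = best_fid,
    _["accepted"] = (double)accepted,
    _["trace_iter"] = trace_iter[Range(0, std::max(trace_k - 1, 0))],
    _["trace_cost"] = trace_cost[Range(0, std::max(trace_k - 1, 0))],
    _["trace_fid"] = trace_fid[Range(0, std::max(trace_k - 1, 0))]
  );
}

// Fidelity + penalty cost of a fixed binding table under the same
// normalization path as sa_fit_cpp (used to score ground-truth polymers).
// [[Rcpp::export]]
double sa_cost_cpp(const NumericMatrix& Tn, const NumericMatrix& p0,
                   double kappa, const NumericVector& s_c,
                   const IntegerMatrix& b, double lambda, bool l2) {
  const int n = Tn.nrow(), M = b.ncol();
  double S = 0.0;
  NumericMatrix R(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double a = 0.0;
      for (int c = 0; c < M; ++c)
        a += s_c[c] * std::min((double)b(i, c), (double)b(j, c));
      R(i, j) = p0(i, j) * (1.0 + kappa * a);
      S += R(i, j);
    }
  double cost = 0.0;
  int total = 0;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < M; ++c) total += b(i, c);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = Tn(i, j) - R(i, j) / S;
      cost += l2 ? d * d : std::fabs(d);
    }
  return cost + lambda * total;
}
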