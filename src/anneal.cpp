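#include <Rcpp.h>
using namespace Rcpp;

// Correlation criterion from the state constants; NA_REAL when undefined
// (degenerate block or constant observed vector).
static inline double state_r(int nC, int nP, long long vC, long long vP) {
  if (nC < 2 || nP < 2) return NA_REAL;
  double dC = (double)nC * nC - nC;
  double dP = (double)nP * nP - nP;
  double d = dC + dP;
  double s2x = (dC / d) * (dP / d);
  double s2y = ((dC - vC + vP) / d) * ((dP - vP + vC) / d);
  if (s2x <= 0.0 || s2y <= 0.0) return NA_REAL;
  double sxy = (dC - vC) / d - (dC / d) * ((dC - vC + vP) / d);
  return sxy / std::sqrt(s2x * s2y);
}

// Simulated annealing with reciprocal cooling tau(q) = tau1 / q.
//
// One trajectory of exactly `xi` trials from the supplied initial
// membership. Each trial flips one uniformly chosen actor, updates the
// violation counts incrementally (O(n) per trial), accepts improving or
// equal moves, and accepts worsening moves with probability
// exp((r' - r) / tau(q)). Trials whose state is undefined are rejected.
//
// `checkpoints` (sorted, increasing, last == xi) gives trial indices at
// which the running best correlation is recorded, so several trial budgets
// can be read off one shared trajectory.
//
// Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export(name = ".cpp_anneal")]]
List cpp_anneal(IntegerMatrix A, LogicalVector init_core, double xi,
                double tau1, IntegerVector checkpoints) {
  const int n = A.nrow();
  if (A.ncol() != n) stop("adjacency matrix must be square");
  if (init_core.size() != n) stop("initial partition size mismatch");

  std::vector<int> core(n);
  int nC = 0;
  for (int i = 0; i < n; ++i) {
    core[i] = init_core[i] ? 1 : 0;
    nC += core[i];
  }
  int nP = n - nC;

  // scratch violation counts for the initial partition
  long long vC = 0, vP = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (core[i] && core[j]) vC += 1 - A(i, j);
      else if (!core[i] && !core[j]) vP += A(i, j);
    }

  double r_inc = state_r(nC, nP, vC, vP);
  if (ISNA(r_inc)) stop("initial partition has an undefined correlation");
  double r_best = r_inc;
  std::vector<int> best(core);

  const int n_ck = checkpoints.size();
  NumericVector ck_r(n_ck);
  int ck = 0;

  for (double q = 1; q <= xi; q += 1) {
    int h = (int)(n * unif_rand());
    if (h >= n) h = n - 1;

    // incremental update of (nC, nP, vC, vP) for flipping actor h
    long long dvC = 0, dvP = 0;
    int nC2, nP2;
    if (core[h]) {            // core -> periphery
      for (int j = 0; j < n; ++j) {
        if (j == h) continue;
        if (core[j]) dvC -= (1 - A(h, j)) + (1 - A(j, h));
        else         dvP += A(h, j) + A(j, h);
      }
      nC2 = nC - 1; nP2 = nP + 1;
    } else {                  // periphery -> core
      for (int j = 0; j < n; ++j) {
        if (j == h) continue;
        if (core[j]) dvC += (1 - A(h, j)) + (1 - A(j, h));
        else         dvP -= A(h, j) + A(j, h);
      }
      nC2 = nC + 1; nP2 = nP - 1;
    }
    long long vC2 = vC + dvC, vP2 = vP + dvP;
    double r_new = state_r(nC2, nP2, vC2, vP2);

    bool take = false;
    if (!ISNA(r_new)) {
      if (r_new >= r_inc) {
        take = true;
      } else {
        double tau = tau1 / q;
        if (unif_rand() < std::exp((r_new - r_inc) / tau)) take = true;
      }
    }
    if (take) {
      core[h] = 1 - core[h];
      nC = nC2; nP = nP2; vC = vC2; vP = vP2;
      r_inc = r_new;
      if (r_new > r_best) {
        r_best = r_new;
        best.assign(core.begin(), core.end());
      }
    }
    while (ck < n_ck && q >= checkpoints[ck]) ck_r[ck++] = r_best;
  }
  while (ck < n_ck) ck_r[ck++] = r_best;

  LogicalVector best_core(n);
  for (int i = 0; i < n; ++i) best_core[i] = best[i] == 1;
  return List::create(_["best_core"] = best_core,
                      _["best_r"] = r_best,
                      _["checkpoint_r"] = ck_r,
                      _["incumbent_r"] = r_inc);
}
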