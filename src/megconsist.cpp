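#include <Rcpp.h>
using namespace Rcpp;

// Pairwise phase lag index from an N x R matrix of instantaneous phases.
// [[Rcpp::export]]
NumericMatrix pli_matrix_cpp(NumericMatrix phases) {
  const int n = phases.nrow(), r = phases.ncol();
  NumericMatrix A(r, r);
  for (int i = 0; i < r; ++i) {
    for (int j = i + 1; j < r; ++j) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        double s = std::sin(phases(k, i) - phases(k, j));
        acc += (s > 0) - (s < 0);
      }
      double v = std::fabs(acc / n);
      A(i, j) = v;
      A(j, i) = v;
    }
  }
  return A;
}

// Weighted Newman modularity maximized by simulated annealing.
// Schedule: T0, geometric cooling per proposal, stop when T < t_min or after
// max_idle consecutive rejected proposals. Uses R's RNG (seed via set.seed).
// Returns per-run best Q and module count of the best partition.
// [[Rcpp::export]]
List anneal_modularity_cpp(NumericMatrix W, int n_runs, double t0,
                           double cooling, double t_min, int max_idle) {
  const int r = W.nrow();
  std::vector<double> s(r, 0.0);
  double two_m = 0.0;
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < r; ++j) { s[i] += W(i, j); two_m += W(i, j); }

  NumericVector q_runs(n_runs);
  IntegerVector mod_runs(n_runs);

  for (int run = 0; run < n_runs; ++run) {
    // random initial partition: each node in a uniformly random module label
    std::vector<int> memb(r);
    for (int i = 0; i < r; ++i)
      memb[i] = (int)std::floor(unif_rand() * r);
    // module aggregates
    std::vector<double> Sm(r, 0.0), Wm(r, 0.0);
    for (int i = 0; i < r; ++i) Sm[memb[i]] += s[i];
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < r; ++j)
        if (memb[i] == memb[j]) Wm[memb[i]] += W(i, j);
    double q = 0.0;
    for (int m = 0; m < r; ++m)
      q += Wm[m] / two_m - (Sm[m] / two_m) * (Sm[m] / two_m);

    std::vector<int> best_memb = memb;
    double best_q = q;
    double T = t0;
    int idle = 0;

    while (T >= t_min && idle < max_idle) {
      int i = (int)std::floor(unif_rand() * r);
      int target = (int)std::floor(unif_rand() * r);
      int cur = memb[i];
      T *= cooling;
      if (target == cur) { ++idle; continue; }
      // strength of i's links into its current and the target module
      double k_cur = 0.0, k_tgt = 0.0;
      for (int j = 0; j < r; ++j) {
        if (j == i) continue;
        if (memb[j] == cur) k_cur += W(i, j);
        else if (memb[j] == target) k_tgt += W(i, j);
      }
      double dq = (2.0 * (k_tgt - k_cur)) / two_m
        - 2.0 * s[i] * (Sm[target] - (Sm[cur] - s[i])) / (two_m * two_m);
      bool accept = dq > 0 || unif_rand() < std::exp(dq / T);
      if (accept) {
        Wm[cur] -= 2.0 * k_cur;
        Wm[target] += 2.0 * k_tgt;
        Sm[cur] -= s[i];
        Sm[target] += s[i];
        memb[i] = target;
        q += dq;
        if (q > best_q) { best_q = q; best_memb = memb; }
        idle = 0;
      } else {
        ++idle;
      }
    }

    // count non-empty modules of the best partition
    std::vector<bool> seen(r, false);
    int nm = 0;
    for (int i = 0; i < r; ++i)
      if (!seen[best_memb[i]]) { seen[best_memb[i]] = true; ++nm; }
    q_runs[run] = best_q;
    mod_runs[run] = nm;
  }
  return List::create(_["q"] = q_runs, _["n_modules"] = mod_runs);
}
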