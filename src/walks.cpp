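#include <Rcpp.h>
using namespace Rcpp;

// Random-walk absorption counts on a row-compressed sparse chain.
// p, j, x: CSR slots of the transition matrix (0-based); target[i] > 0
// marks cell i as belonging to target set target[i]; starts are 0-based
// transient start cells.  Returns per-start first-hit counts per target
// set plus the number of walks that exceeded maxSteps.
// [[Rcpp::export]]
List cpp_absorption_walks(IntegerVector p, IntegerVector j, NumericVector x,
                          IntegerVector target, int nTargets,
                          IntegerVector starts, int nWalks,
                          double maxSteps) {
  const int nStarts = starts.size();
  IntegerMatrix counts(nStarts, nTargets);
  IntegerVector failures(nStarts);

  // per-row cumulative probabilities for inverse-cdf sampling
  const int n = p.size() - 1;
  std::vector<std::vector<double>> cum(n);
  for (int r = 0; r < n; ++r) {
    const int a = p[r], b = p[r + 1];
    cum[r].resize(b - a);
    double s = 0.0;
    for (int k = a; k < b; ++k) {
      s += x[k];
      cum[r][k - a] = s;
    }
  }

  for (int si = 0; si < nStarts; ++si) {
    const int start = starts[si];
    for (int w = 0; w < nWalks; ++w) {
      int state = start;
      double steps = 0.0;
      bool ok = true;
      while (target[state] == 0) {
        if (steps >= maxSteps) { ok = false; break; }
        const std::vector<double>& c = cum[state];
        const double total = c.back();
        const double u = unif_rand() * total;
        const int k = std::lower_bound(c.begin(), c.end(), u) - c.begin();
        state = j[p[state] + std::min<int>(k, (int)c.size() - 1)];
        steps += 1.0;
      }
      if (ok) counts(si, target[state] - 1) += 1; else failures[si] += 1;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["failures"] = failures);
}
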