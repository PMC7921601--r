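#include <Rcpp.h>
using namespace Rcpp;

// Optimal partitioning for piecewise-constant least squares.
// Minimises sum of segment SSEs + beta * (number of change points).
// Returns 1-based indices of the last frame of every segment except the final
// one (i.e. a change point at c means the next plateau starts at frame c + 1).
// min_dwell is enforced during the recursion so no segment is shorter.
// [[Rcpp::export]]
IntegerVector cpp_segment_trace(NumericVector x, double beta, int min_dwell) {
  const int n = x.size();
  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
  // F[t] = minimal penalised cost of x[1..t]; F[0] = -beta so the first
  // segment is not charged a change-point penalty.
  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> last(n + 1, 0);
  F[0] = -beta;
  const double tie_eps = 1e-9;
  for (int t = 1; t <= n; ++t) {
    if (t < min_dwell) continue;
    double best = R_PosInf;
    int arg = 0;
    for (int s = 0; s + min_dwell <= t; ++s) {
      if (!R_finite(F[s])) continue;
      const int len = t - s;
      const double sum = S[t] - S[s];
      const double sse = (S2[t] - S2[s]) - sum * sum / len;
      const double v = F[s] + beta + sse;
      // strict improvement required: ties resolve to the fewest segments
      // (smaller s was seen first only for equal segment counts, so prefer
      // the earlier candidate unless clearly better)
      if (v < best - tie_eps) {
        best = v;
        arg = s;
      }
    }
    F[t] = best;
    last[t] = arg;
  }
  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    int s = last[t];
    if (s > 0) cps.push_back(s);
    t = s;
  }
  std::reverse(cps.begin(), cps.end());
  return wrap(cps);
}
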