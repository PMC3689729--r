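// Hot-path kernels: synchronous Boolean simulation and the normalized
// Hamming trajectory error.  The iterated minimum-error search scores up to
// 10^6 sampled networks per run, which is infeasible in interpreted R.
// An R-level reference evaluator in the test suite serves as the
// independent oracle for these kernels.
#include <Rcpp.h>
using namespace Rcpp;

// regs: per-species 0-based regulator index vectors (ascending);
// tts: per-species truth tables, row index MSB-first in regulator order.
static inline void sync_step(const List& regs, const List& tts,
                             const std::vector<int>& cur,
                             std::vector<int>& nxt) {
  const int n = cur.size();
  for (int i = 0; i < n; ++i) {
    IntegerVector r = regs[i];
    IntegerVector tt = tts[i];
    int idx = 0;
    for (int j = 0; j < r.size(); ++j) idx = (idx << 1) | cur[r[j]];
    nxt[i] = tt[idx];
  }
}

// [[Rcpp::export(name = ".sim_sync_cpp")]]
IntegerMatrix sim_sync_cpp(List regs, List tts, IntegerVector start,
                           int steps) {
  const int n = start.size();
  IntegerMatrix out(steps + 1, n);
  std::vector<int> cur(start.begin(), start.end()), nxt(n);
  for (int j = 0; j < n; ++j) out(0, j) = cur[j];
  for (int t = 1; t <= steps; ++t) {
    sync_step(regs, tts, cur, nxt);
    cur = nxt;
    for (int j = 0; j < n; ++j) out(t, j) = cur[j];
  }
  return out;
}

// Trajectory error of a network against a reduced binary trajectory b
// (T x n): synchronously simulate from b[0,] for T-1 steps and count
// mismatching bits over states 2..T, normalized by n * (T - 1).
// [[Rcpp::export(name = ".traj_error_cpp")]]
double traj_error_cpp(List regs, List tts, IntegerMatrix b) {
  const int T = b.nrow(), n = b.ncol();
  std::vector<int> cur(n), nxt(n);
  for (int j = 0; j < n; ++j) cur[j] = b(0, j);
  long mism = 0;
  for (int t = 1; t < T; ++t) {
    sync_step(regs, tts, cur, nxt);
    cur = nxt;
    for (int j = 0; j < n; ++j) mism += (cur[j] != b(t, j));
  }
  return static_cast<double>(mism) / (static_cast<double>(n) * (T - 1));
}

// One synchronous step applied to every row of a state matrix (used by the
// cross-validation one-step predictor).
// [[Rcpp::export(name = ".step_rows_cpp")]]
IntegerMatrix step_rows_cpp(List regs, List tts, IntegerMatrix states) {
  const int m = states.nrow(), n = states.ncol();
  IntegerMatrix out(m, n);
  std::vector<int> cur(n), nxt(n);
  for (int r = 0; r < m; ++r) {
    for (int j = 0; j < n; ++j) cur[j] = states(r, j);
    sync_step(regs, tts, cur, nxt);
    for (int j = 0; j < n; ++j) out(r, j) = nxt[j];
  }
  return out;
}
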