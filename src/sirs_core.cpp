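#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Compartment codes used throughout the package: 0 = S, 1 = I, 2 = R.
//
// Synchronous update, computed entirely from the state at the current step:
//  * an S site with m >= 1 infected neighbours (k per side, periodic) turns
//    I with probability 1 - (1 - lambda)^m (independent per-edge attempts);
//  * an I site turns R after tau_I full steps in I (clock runs 0..tau_I-1);
//  * an R site turns S after tau_R full steps in R.
//
// RNG contract (shared with the pure-R reference stepper): sites are visited
// in ascending index order and exactly one uniform draw from R's RNG stream
// is consumed per S site with at least one infected neighbour.  No other
// draws occur, so two steppers started from the same RNG state stay in
// lockstep.

static inline void count_infected_neighbours(const std::vector<int>& ilist,
                                             int N, int k,
                                             std::vector<int>& ninf) {
  std::fill(ninf.begin(), ninf.end(), 0);
  for (size_t a = 0; a < ilist.size(); ++a) {
    const int j = ilist[a];
    for (int d = 1; d <= k; ++d) {
      int r = j + d; if (r >= N) r -= N;
      int l = j - d; if (l < 0)  l += N;
      ninf[r] += 1;
      if (l != r) ninf[l] += 1;  // guard degenerate wrap (2k >= N)
    }
  }
}

// One synchronous update.  ilist holds the indices of the I sites of the
// input state (ascending); on return comp/clk/ilist describe the new state
// and nI/nR its compartment counts.
static void sirs_step_core(std::vector<int>& comp, std::vector<int>& clk,
                           std::vector<int>& ilist,
                           int N, int k, int tau_I, int tau_R,
                           const std::vector<double>& pinf,
                           std::vector<int>& ninf,
                           std::vector<int>& ncomp, std::vector<int>& nclk,
                           std::vector<int>& nilist,
                           int& nI, int& nR) {
  count_infected_neighbours(ilist, N, k, ninf);
  nilist.clear();
  nI = 0; nR = 0;
  for (int i = 0; i < N; ++i) {
    const int c = comp[i];
    if (c == 0) {
      const int m = ninf[i];
      if (m > 0 && unif_rand() < pinf[m]) {
        ncomp[i] = 1; nclk[i] = 0; nilist.push_back(i); ++nI;
      } else {
        ncomp[i] = 0; nclk[i] = 0;
      }
    } else if (c == 1) {
      if (clk[i] == tau_I - 1) { ncomp[i] = 2; nclk[i] = 0; ++nR; }
      else { ncomp[i] = 1; nclk[i] = clk[i] + 1; nilist.push_back(i); ++nI; }
    } else {
      if (clk[i] == tau_R - 1) { ncomp[i] = 0; nclk[i] = 0; }
      else { ncomp[i] = 2; nclk[i] = clk[i] + 1; ++nR; }
    }
  }
  comp.swap(ncomp);
  clk.swap(nclk);
  ilist.swap(nilist);
}

static std::vector<double> infection_table(int k, double lam) {
  std::vector<double> pinf(2 * k + 1, 0.0);
  for (int m = 1; m <= 2 * k; ++m) pinf[m] = 1.0 - std::pow(1.0 - lam, m);
  return pinf;
}

// Single synchronous step; returns the new compartments and clocks.
// [[Rcpp::export]]
List cpp_sirs_step(IntegerVector comp0, IntegerVector clock0, int k,
                   double lam, int tau_I, int tau_R) {
  const int N = comp0.size();
  std::vector<int> comp(comp0.begin(), comp0.end());
  std::vector<int> clk(clock0.begin(), clock0.end());
  std::vector<int> ilist;
  for (int i = 0; i < N; ++i) if (comp[i] == 1) ilist.push_back(i);
  std::vector<int> ninf(N), ncomp(N), nclk(N), nilist;
  std::vector<double> pinf = infection_table(k, lam);
  int nI, nR;
  sirs_step_core(comp, clk, ilist, N, k, tau_I, tau_R, pinf, ninf,
                 ncomp, nclk, nilist, nI, nR);
  return List::create(_["comp"]  = IntegerVector(comp.begin(), comp.end()),
                      _["clock"] = IntegerVector(clk.begin(), clk.end()));
}

// Full trajectory.  Time steps are recorded 1-based: step 1 is the initial
// configuration, each synchronous update adds one step.  extinct_step is the
// first recorded step free of I sites; absorbed_step the first all-S step.
// win_lo/win_hi (1-based, inclusive; win_lo < 1 disables) request the count
// of I sites inside a fixed observation window at every recorded step.
// [[Rcpp::export]]
List cpp_sirs_run(IntegerVector comp0, IntegerVector clock0, int k,
                  double lam, int tau_I, int tau_R, int max_steps,
                  bool record_spacetime, bool stop_when_absorbed,
                  int win_lo, int win_hi) {
  const int N = comp0.size();
  std::vector<int> comp(comp0.begin(), comp0.end());
  std::vector<int> clk(clock0.begin(), clock0.end());
  std::vector<int> ilist;
  std::vector<int> ninf(N), ncomp(N), nclk(N), nilist;
  std::vector<double> pinf = infection_table(k, lam);
  ilist.reserve(N); nilist.reserve(N);

  int nI = 0, nR = 0;
  for (int i = 0; i < N; ++i) {
    if (comp[i] == 1) { ilist.push_back(i); ++nI; }
    else if (comp[i] == 2) ++nR;
  }

  const bool track_window = (win_lo >= 1);
  std::vector<double> rho;
  std::vector<int> wc;
  std::vector<int> st;  // spacetime rows, row-major
  rho.reserve(std::min(max_steps + 1, 1 << 20));

  int extinct_step = -1, absorbed_step = -1;
  int t = 0;  // synchronous updates performed so far

  for (;;) {
    rho.push_back(static_cast<double>(nI) / N);
    if (track_window) {
      int w = 0;
      for (int i = win_lo - 1; i <= win_hi - 1; ++i) if (comp[i] == 1) ++w;
      wc.push_back(w);
    }
    if (record_spacetime) st.insert(st.end(), comp.begin(), comp.end());

    const int step = t + 1;  // 1-based index of the state just recorded
    if (nI == 0 && extinct_step < 0) extinct_step = step;
    if (nI == 0 && nR == 0) {
      if (absorbed_step < 0) absorbed_step = step;
      if (stop_when_absorbed) break;
    }
    if (t >= max_steps) break;
    sirs_step_core(comp, clk, ilist, N, k, tau_I, tau_R, pinf, ninf,
                   ncomp, nclk, nilist, nI, nR);
    ++t;
    if ((t & 2047) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["rho"]           = NumericVector(rho.begin(), rho.end()),
    _["steps"]         = t,
    _["extinct_step"]  = (extinct_step < 0) ? NA_INTEGER : extinct_step,
    _["absorbed_step"] = (absorbed_step < 0) ? NA_INTEGER : absorbed_step,
    _["survived"]      = (extinct_step < 0),
    _["comp"]          = IntegerVector(comp.begin(), comp.end()),
    _["clock"]         = IntegerVector(clk.begin(), clk.end()));
  if (track_window)
    out["window_counts"] = IntegerVector(wc.begin(), wc.end());
  if (record_spacetime) {
    const int rows = static_cast<int>(st.size()) / N;
    IntegerMatrix m(rows, N);
    for (int r = 0; r < rows; ++r)
      for (int i = 0; i < N; ++i) m(r, i) = st[r * N + i];
    out["spacetime"] = m;
  }
  return out;
}
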