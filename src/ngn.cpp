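#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Shared engine for the glial pattern-cycle dynamics. Genome layout (must
// match the R side): for each layer pair k -> k+1, the weight block with the
// source index varying fastest (element (i, j) at w_off[k] + j*s[k] + i),
// followed by one bias per destination neuron when biases are enabled.
// Biases are never modulated by the glia.

namespace {

struct Net {
  std::vector<int> s;            // layer sizes
  bool use_bias;
  double threshold;
  std::vector<int> w_off, b_off; // per layer pair
  int n_nonout;                  // neurons carrying an astrocyte

  Net(const IntegerVector &sizes, bool bias, double thr)
      : s(sizes.begin(), sizes.end()), use_bias(bias), threshold(thr) {
    int L = (int)s.size();
    int off = 0;
    w_off.resize(L - 1);
    b_off.resize(L - 1);
    for (int k = 0; k < L - 1; ++k) {
      w_off[k] = off;
      off += s[k] * s[k + 1];
      if (use_bias) {
        b_off[k] = off;
        off += s[k + 1];
      }
    }
    n_nonout = 0;
    for (int k = 0; k < L - 1; ++k) n_nonout += s[k];
  }

  int n_layers() const { return (int)s.size(); }
  int n_out() const { return s.back(); }

  // forward pass; act holds per-layer activations (output layer = net input)
  void forward(const double *w, const double *x,
               std::vector<std::vector<double> > &act) const {
    int L = n_layers();
    act.resize(L);
    act[0].assign(x, x + s[0]);
    for (int k = 0; k < L - 1; ++k) {
      act[k + 1].assign(s[k + 1], 0.0);
      const double *wk = w + w_off[k];
      for (int j = 0; j < s[k + 1]; ++j) {
        double net = use_bias ? w[b_off[k] + j] : 0.0;
        const double *col = wk + (size_t)j * s[k];
        for (int i = 0; i < s[k]; ++i) net += act[k][i] * col[i];
        act[k + 1][j] = (k < L - 2) ? std::tanh(net) : net;
      }
    }
  }

  // one full pattern cycle on `w` (modified in place); returns the final
  // iteration's output net inputs in `out`
  void pattern_cycle(double *w, const double *x, int n, int m, double pot,
                     double dep, std::vector<double> &out) const {
    int L = n_layers();
    std::vector<int> counter(n_nonout, 0);
    std::vector<std::vector<double> > act;
    const double up = 1.0 + pot, dn = 1.0 - dep;
    for (int it = 0; it < m; ++it) {
      forward(w, x, act);
      int pos = 0;
      for (int k = 0; k < L - 1; ++k) {
        for (int i = 0; i < s[k]; ++i) {
          bool active = act[k][i] > 0.0;
          int &c = counter[pos + i];
          if (active) {
            if (c < n) ++c;
            if (c == n) { // activation event: potentiate outgoing weights
              double *wk = w + w_off[k];
              for (int j = 0; j < s[k + 1]; ++j)
                wk[(size_t)j * s[k] + i] *= up;
            }
          } else {
            if (c > -n) --c;
            if (c == -n) { // depression event: depress outgoing weights
              double *wk = w + w_off[k];
              for (int j = 0; j < s[k + 1]; ++j)
                wk[(size_t)j * s[k] + i] *= dn;
            }
          }
        }
        pos += s[k];
      }
      if (it == m - 1) out = act[L - 1];
    }
  }

  void plain_output(const double *w, const double *x,
                    std::vector<double> &out) const {
    std::vector<std::vector<double> > act;
    forward(w, x, act);
    out = act[n_layers() - 1];
  }

  double pattern_error(const std::vector<double> &out,
                       const double *target) const {
    double err = 0.0;
    for (int j = 0; j < n_out(); ++j) {
      double b = (out[j] >= threshold) ? 1.0 : 0.0;
      double d = b - target[j];
      err += d * d;
    }
    return err;
  }

  int predicted(const std::vector<double> &out) const {
    if (n_out() == 1) return (out[0] >= threshold) ? 1 : 0;
    int best = 0;
    for (int j = 1; j < n_out(); ++j)
      if (out[j] > out[best]) best = j;
    return best;
  }
};

} // namespace

// Phase-1 evaluation of one individual: present every training pattern (row
// order) for a full pattern cycle, counters reset per pattern; returns the
// cycle-end genome and the MSE (mean over patterns of the summed squared
// binary-output error). With cumulative = true the glial weight changes
// persist from one pattern to the next; with cumulative = false each
// pattern's cycle starts from the individual's genome (the per-pattern
// transient regime). With enabled = false each pattern gets a single plain
// forward pass and the genome is returned unchanged.
// [[Rcpp::export]]
List cpp_phase1(NumericVector genome, IntegerVector sizes, bool use_bias,
                double threshold, NumericMatrix X, NumericMatrix Y,
                int n, int m, double pot, double dep, bool enabled,
                bool cumulative) {
  Net net(sizes, use_bias, threshold);
  NumericVector w = clone(genome);
  int n_pat = X.nrow();
  int p = X.ncol();
  int n_out = net.n_out();
  std::vector<double> x(p), tgt(n_out), out;
  std::vector<double> scratch(genome.begin(), genome.end());
  double total = 0.0;
  for (int r = 0; r < n_pat; ++r) {
    for (int c = 0; c < p; ++c) x[c] = X(r, c);
    for (int c = 0; c < n_out; ++c) tgt[c] = Y(r, c);
    if (enabled) {
      if (cumulative) {
        net.pattern_cycle(REAL(w), x.data(), n, m, pot, dep, out);
      } else {
        std::copy(w.begin(), w.end(), scratch.begin());
        net.pattern_cycle(scratch.data(), x.data(), n, m, pot, dep, out);
      }
    } else {
      net.plain_output(REAL(w), x.data(), out);
    }
    total += net.pattern_error(out, tgt.data());
  }
  return List::create(_["genome"] = w, _["mse"] = total / n_pat);
}

// Classification accuracy with test-phase glia. Each pattern is presented
// for a full cycle and the prediction read from the final iteration, on a
// scratch copy of the genome (the stored genome is never changed). With
// sweep = true the scratch copy is modified cumulatively across the whole
// evaluation set, mirroring the phase-1 training sweep; with sweep = false
// the scratch copy is re-initialized before every pattern (order-invariant).
// enabled = false gives the plain feed-forward accuracy.
// [[Rcpp::export]]
double cpp_accuracy(NumericVector genome, IntegerVector sizes, bool use_bias,
                    double threshold, NumericMatrix X, IntegerVector labels,
                    int n, int m, double pot, double dep, bool enabled,
                    bool sweep) {
  Net net(sizes, use_bias, threshold);
  int n_pat = X.nrow();
  int p = X.ncol();
  std::vector<double> x(p), out;
  std::vector<double> scratch(genome.begin(), genome.end());
  int correct = 0;
  for (int r = 0; r < n_pat; ++r) {
    for (int c = 0; c < p; ++c) x[c] = X(r, c);
    if (enabled) {
      if (!sweep) std::copy(genome.begin(), genome.end(), scratch.begin());
      net.pattern_cycle(scratch.data(), x.data(), n, m, pot, dep, out);
    } else {
      net.plain_output(REAL(genome), x.data(), out);
    }
    if (net.predicted(out) == labels[r]) ++correct;
  }
  return (double)correct / n_pat;
}
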