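// Collapsed Gibbs sampler for the Dirichlet-categorical architecture mixture.
//
// Latent state: per-sequence architecture labels y and per-architecture
// important-position sets I.  All categorical parameters (mixture weights,
// per-position nucleotide distributions) are integrated out analytically, so
// moves only touch integer count tables.  Count bookkeeping:
//   counts[u][j][b]  nucleotide counts at position j over members of u
//                    (kept for every j, important or not, so that position
//                    swap moves are O(1))
//   bgc[j][b]        background counts at j: contributions from sequences
//                    whose architecture does NOT deem j important
//   bgtot[j]         number of sequences contributing to bgc[j]
//   sizes[u]         architecture occupancy
// Invariant: for every j, sum_b bgc[j][b] + sum_{u: j in I_u} sizes[u] == n.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xorshift128+ seeded through splitmix64; self-contained so that chains are
// bit-reproducible across platforms and independent of R's RNG.
class Rng {
  std::uint64_t s0_, s1_;

 public:
  explicit Rng(std::uint64_t seed) {
    std::uint64_t z = seed;
    std::uint64_t out[2];
    for (int i = 0; i < 2; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      std::uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      out[i] = t ^ (t >> 31);
    }
    s0_ = out[0];
    s1_ = out[1] | 1ULL;
  }
  std::uint64_t next() {
    std::uint64_t x = s0_, y = s1_;
    s0_ = y;
    x ^= x << 23;
    s1_ = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1_ + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int m) { return static_cast<int>(next() % static_cast<std::uint64_t>(m)); }
};

struct Chain {
  const int* X;  // n x l, column-major, codes 0..3
  int n, l, k;
  std::vector<int> p;  // important-position count per architecture
  double alpha;        // symmetric Dirichlet pseudocount

  std::vector<int> y;                  // labels, 0-based
  std::vector<std::vector<int>> impl;  // important positions per architecture
  std::vector<std::uint8_t> imp;       // k*l membership flags
  std::vector<int> counts;             // k*l*4
  std::vector<int> bgc;                // l*4
  std::vector<int> bgtot;              // l
  std::vector<int> sizes;              // k

  // lookup tables indexed by integer counts 0..n+1
  std::vector<double> la, lb, lgA, lgB;
  double C4;

  Chain(const int* X_, int n_, int l_, int k_, std::vector<int> p_, double a_)
      : X(X_), n(n_), l(l_), k(k_), p(std::move(p_)), alpha(a_) {
    y.assign(n, 0);
    impl.assign(k, std::vector<int>());
    imp.assign((size_t)k * l, 0);
    counts.assign((size_t)k * l * 4, 0);
    bgc.assign((size_t)l * 4, 0);
    bgtot.assign(l, 0);
    sizes.assign(k, 0);
    la.resize(n + 2);
    lb.resize(n + 2);
    lgA.resize(n + 2);
    lgB.resize(n + 2);
    for (int m = 0; m <= n + 1; ++m) {
      la[m] = std::log(m + alpha);
      lb[m] = std::log(m + 4.0 * alpha);
      lgA[m] = std::lgamma(m + alpha);
      lgB[m] = std::lgamma(m + 4.0 * alpha);
    }
    C4 = std::lgamma(4.0 * alpha) - 4.0 * std::lgamma(alpha);
  }

  inline int xat(int i, int j) const { return X[i + (size_t)n * j]; }
  inline int* cu(int u, int j) { return &counts[((size_t)u * l + j) * 4]; }
  inline const int* cu(int u, int j) const { return &counts[((size_t)u * l + j) * 4]; }

  void set_state(const std::vector<int>& y_in,
                 const std::vector<std::vector<int>>& impl_in) {
    y = y_in;
    impl = impl_in;
    std::fill(imp.begin(), imp.end(), 0);
    std::fill(counts.begin(), counts.end(), 0);
    std::fill(bgc.begin(), bgc.end(), 0);
    std::fill(sizes.begin(), sizes.end(), 0);
    for (int u = 0; u < k; ++u)
      for (int j : impl[u]) imp[(size_t)u * l + j] = 1;
    for (int i = 0; i < n; ++i) {
      sizes[y[i]]++;
      for (int j = 0; j < l; ++j) cu(y[i], j)[xat(i, j)]++;
    }
    for (int j = 0; j < l; ++j) {
      int col[4] = {0, 0, 0, 0};
      for (int i = 0; i < n; ++i) col[xat(i, j)]++;
      int tot = n;
      for (int u = 0; u < k; ++u) {
        if (imp[(size_t)u * l + j]) {
          const int* c = cu(u, j);
          for (int b = 0; b < 4; ++b) col[b] -= c[b];
          tot -= sizes[u];
        }
      }
      for (int b = 0; b < 4; ++b) bgc[(size_t)j * 4 + b] = col[b];
      bgtot[j] = tot;
    }
  }

  void random_init(Rng& rng) {
    std::vector<int> y0(n);
    for (int i = 0; i < n; ++i) y0[i] = rng.below(k);
    std::vector<std::vector<int>> I0(k);
    std::vector<int> perm(l);
    for (int u = 0; u < k; ++u) {
      for (int j = 0; j < l; ++j) perm[j] = j;
      for (int j = l - 1; j > 0; --j) std::swap(perm[j], perm[rng.below(j + 1)]);
      I0[u].assign(perm.begin(), perm.begin() + p[u]);
    }
    set_state(y0, I0);
  }

  void remove_seq(int i) {
    int u = y[i];
    sizes[u]--;
    for (int j = 0; j < l; ++j) {
      int b = xat(i, j);
      cu(u, j)[b]--;
      if (!imp[(size_t)u * l + j]) {
        bgc[(size_t)j * 4 + b]--;
        bgtot[j]--;
      }
    }
  }

  void add_seq(int i, int u) {
    y[i] = u;
    sizes[u]++;
    for (int j = 0; j < l; ++j) {
      int b = xat(i, j);
      cu(u, j)[b]++;
      if (!imp[(size_t)u * l + j]) {
        bgc[(size_t)j * 4 + b]++;
        bgtot[j]++;
      }
    }
  }

  // collapsed conditional log weights for y_i (sequence i must be removed)
  void assignment_logw(int i, std::vector<double>& lw) const {
    double bgsum = 0.0;
    for (int j = 0; j < l; ++j)
      bgsum += la[bgc[(size_t)j * 4 + xat(i, j)]] - lb[bgtot[j]];
    for (int u = 0; u < k; ++u) {
      double w = la[sizes[u]] + bgsum;  // log(size_u + alpha) + background
      for (int j : impl[u]) {
        int b = xat(i, j);
        w += la[cu(u, j)[b]] - lb[sizes[u]];
        w -= la[bgc[(size_t)j * 4 + b]] - lb[bgtot[j]];
      }
      lw[u] = w;
    }
  }

  int sample_y(int i, Rng& rng, std::vector<double>& lw) {
    assignment_logw(i, lw);
    double m = lw[0];
    for (int u = 1; u < k; ++u)
      if (lw[u] > m) m = lw[u];
    double tot = 0.0;
    for (int u = 0; u < k; ++u) {
      lw[u] = std::exp(lw[u] - m);
      tot += lw[u];
    }
    double r = rng.unif() * tot;
    int u = 0;
    for (; u < k - 1; ++u) {
      r -= lw[u];
      if (r <= 0) break;
    }
    return u;
  }

  inline double dm4(const int* c, int tot) const {
    return C4 - lgB[tot] + lgA[c[0]] + lgA[c[1]] + lgA[c[2]] + lgA[c[3]];
  }

  // collapsed score log-ratio for swapping j_out (important) with j_in
  // (unimportant) in architecture u
  double swap_delta(int u, int j_in, int j_out) const {
    const int* co = cu(u, j_out);
    const int* bo = &bgc[(size_t)j_out * 4];
    int mo[4] = {bo[0] + co[0], bo[1] + co[1], bo[2] + co[2], bo[3] + co[3]};
    double d = dm4(mo, bgtot[j_out] + sizes[u]) - dm4(co, sizes[u]) -
               dm4(bo, bgtot[j_out]);
    const int* ci = cu(u, j_in);
    const int* bi = &bgc[(size_t)j_in * 4];
    int ri[4] = {bi[0] - ci[0], bi[1] - ci[1], bi[2] - ci[2], bi[3] - ci[3]};
    d += dm4(ci, sizes[u]) + dm4(ri, bgtot[j_in] - sizes[u]) -
         dm4(bi, bgtot[j_in]);
    return d;
  }

  void apply_swap(int u, int j_in, int out_idx) {
    int j_out = impl[u][out_idx];
    impl[u][out_idx] = j_in;
    imp[(size_t)u * l + j_out] = 0;
    imp[(size_t)u * l + j_in] = 1;
    const int* co = cu(u, j_out);
    const int* ci = cu(u, j_in);
    for (int b = 0; b < 4; ++b) {
      bgc[(size_t)j_out * 4 + b] += co[b];
      bgc[(size_t)j_in * 4 + b] -= ci[b];
    }
    bgtot[j_out] += sizes[u];
    bgtot[j_in] -= sizes[u];
  }

  // one cardinality-preserving sweep of Gibbs swap moves over architecture u
  void swap_sweep(int u, Rng& rng, std::vector<int>& excl) {
    int pu = p[u];
    if (pu == 0 || pu == l) return;
    excl.clear();
    for (int j = 0; j < l; ++j)
      if (!imp[(size_t)u * l + j]) excl.push_back(j);
    for (int j = (int)excl.size() - 1; j > 0; --j)
      std::swap(excl[j], excl[rng.below(j + 1)]);
    for (int j_in : excl) {
      int oi = rng.below(pu);
      double d = swap_delta(u, j_in, impl[u][oi]);
      double pacc = 1.0 / (1.0 + std::exp(-d));
      if (rng.unif() < pacc) apply_swap(u, j_in, oi);
    }
  }

  double score() const {
    double sc = std::lgamma(k * alpha) - std::lgamma(n + k * alpha) -
                k * std::lgamma(alpha);
    for (int u = 0; u < k; ++u) sc += std::lgamma(sizes[u] + alpha);
    for (int u = 0; u < k; ++u)
      for (int j : impl[u]) sc += dm4(cu(u, j), sizes[u]);
    for (int j = 0; j < l; ++j) sc += dm4(&bgc[(size_t)j * 4], bgtot[j]);
    return sc;
  }

  void iteration(Rng& rng, std::vector<double>& lw, std::vector<int>& excl) {
    for (int i = 0; i < n; ++i) {
      remove_seq(i);
      int u = sample_y(i, rng, lw);
      add_seq(i, u);
      swap_sweep(u, rng, excl);
    }
  }
};

std::vector<int> as_p(IntegerVector p, int k) {
  std::vector<int> out(k);
  for (int u = 0; u < k; ++u) out[u] = p[u];
  return out;
}

// build a chain positioned at a caller-supplied state (1-based labels and
// positions on the R side)
Chain chain_from(const IntegerMatrix& X, const IntegerVector& y, const List& I,
                 int k, double alpha) {
  int n = X.nrow(), l = X.ncol();
  std::vector<int> p(k);
  std::vector<std::vector<int>> impl(k);
  for (int u = 0; u < k; ++u) {
    IntegerVector iu = I[u];
    p[u] = iu.size();
    for (int j = 0; j < iu.size(); ++j) impl[u].push_back(iu[j] - 1);
  }
  Chain ch(X.begin(), n, l, k, p, alpha);
  std::vector<int> y0(n);
  for (int i = 0; i < n; ++i) y0[i] = y[i] - 1;
  ch.set_state(y0, impl);
  return ch;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_chain(IntegerMatrix X, int k, IntegerVector p, double alpha,
                   int n_iter, int n_restarts, int seed, bool record_trace,
                   bool record_states) {
  int n = X.nrow(), l = X.ncol();
  std::vector<int> pv = as_p(p, k);

  double best_score = R_NegInf;
  std::vector<int> best_y;
  std::vector<std::vector<int>> best_impl;

  NumericMatrix trace;
  if (record_trace) trace = NumericMatrix((size_t)n_restarts * n_iter, 3);
  bool rec_states = record_states && n_restarts == 1;
  IntegerMatrix y_trace, imp_trace;
  if (rec_states) {
    y_trace = IntegerMatrix(n_iter, n);
    imp_trace = IntegerMatrix(n_iter, k * l);
  }

  Chain ch(X.begin(), n, l, k, pv, alpha);
  std::vector<double> lw(k);
  std::vector<int> excl;
  excl.reserve(l);

  for (int r = 0; r < n_restarts; ++r) {
    Rng rng((static_cast<std::uint64_t>(static_cast<std::uint32_t>(seed)) << 20) +
            static_cast<std::uint64_t>(r));
    ch.random_init(rng);
    for (int it = 0; it < n_iter; ++it) {
      if (it % 16 == 0) Rcpp::checkUserInterrupt();
      ch.iteration(rng, lw, excl);
      double sc = ch.score();
      if (record_trace) {
        size_t row = (size_t)r * n_iter + it;
        trace(row, 0) = r + 1;
        trace(row, 1) = it + 1;
        trace(row, 2) = sc;
      }
      if (rec_states) {
        for (int i = 0; i < n; ++i) y_trace(it, i) = ch.y[i] + 1;
        for (int u = 0; u < k; ++u)
          for (int j = 0; j < l; ++j)
            imp_trace(it, u * l + j) = ch.imp[(size_t)u * l + j];
      }
      if (sc > best_score) {
        best_score = sc;
        best_y = ch.y;
        best_impl = ch.impl;
      }
    }
  }

  IntegerVector out_y(n);
  for (int i = 0; i < n; ++i) out_y[i] = best_y[i] + 1;
  List out_I(k);
  for (int u = 0; u < k; ++u) {
    std::vector<int> iu = best_impl[u];
    std::sort(iu.begin(), iu.end());
    IntegerVector v(iu.size());
    for (size_t j = 0; j < iu.size(); ++j) v[j] = iu[j] + 1;
    out_I[u] = v;
  }

  // final (end-of-last-restart) internal tables, for bookkeeping audits
  IntegerVector fin_y(n);
  for (int i = 0; i < n; ++i) fin_y[i] = ch.y[i] + 1;
  List fin_I(k);
  for (int u = 0; u < k; ++u) {
    IntegerVector v(ch.impl[u].size());
    for (size_t j = 0; j < ch.impl[u].size(); ++j) v[j] = ch.impl[u][j] + 1;
    fin_I[u] = v;
  }
  IntegerVector fin_counts(ch.counts.begin(), ch.counts.end());
  fin_counts.attr("dim") = IntegerVector::create(4, l, k);
  IntegerVector fin_bgc(ch.bgc.begin(), ch.bgc.end());
  fin_bgc.attr("dim") = IntegerVector::create(4, l);

  List out = List::create(
      _["best_y"] = out_y, _["best_I"] = out_I, _["best_score"] = best_score,
      _["final_y"] = fin_y, _["final_I"] = fin_I,
      _["final_counts"] = fin_counts, _["final_bgc"] = fin_bgc,
      _["final_bgtot"] = IntegerVector(ch.bgtot.begin(), ch.bgtot.end()),
      _["final_sizes"] = IntegerVector(ch.sizes.begin(), ch.sizes.end()),
      _["final_score"] = ch.score());
  if (record_trace) out["trace"] = trace;
  if (rec_states) {
    out["y_trace"] = y_trace;
    out["imp_trace"] = imp_trace;
  }
  return out;
}

// Iterated conditional modes refinement of a latent state: sequential
// argmax label reassignment alternating with exact per-architecture
// position-set maximisation (the collapsed score is additive over the
// candidate positions of one architecture given everything else), until
// a fixpoint.  Fully deterministic: sequences are visited in order, ties
// break towards the smaller index.
// [[Rcpp::export]]
List cpp_icm(IntegerMatrix X, IntegerVector y, List I, double alpha,
             int max_rounds, bool canonical_init, bool move_labels) {
  int k = I.size();
  Chain ch = chain_from(X, y, I, k, alpha);
  int n = ch.n, l = ch.l;
  std::vector<double> lw(k);
  if (canonical_init) {
    // re-derive every position set from the partition alone: per
    // architecture, the top-gain positions with all other architectures
    // treated as unimportant.  This makes the refined state a
    // deterministic function of the partition, independent of the
    // sampled position sets.
    std::vector<int> col(l * 4, 0);
    for (int j = 0; j < l; ++j)
      for (int i = 0; i < n; ++i) col[j * 4 + ch.xat(i, j)]++;
    std::vector<std::vector<int>> init(k);
    for (int u = 0; u < k; ++u) {
      int pu = ch.p[u];
      if (pu == 0 || pu == l) {
        init[u] = ch.impl[u];
        std::sort(init[u].begin(), init[u].end());
        continue;
      }
      std::vector<std::pair<double, int>> g(l);
      for (int j = 0; j < l; ++j) {
        const int* c = ch.cu(u, j);
        int bw[4];
        for (int t = 0; t < 4; ++t) bw[t] = col[j * 4 + t] - c[t];
        int nw = n - ch.sizes[u];
        int mg[4] = {col[j * 4], col[j * 4 + 1], col[j * 4 + 2],
                     col[j * 4 + 3]};
        double gain = ch.dm4(c, ch.sizes[u]) + ch.dm4(bw, nw) -
                      ch.dm4(mg, n);
        g[j] = std::make_pair(-gain, j);
      }
      std::sort(g.begin(), g.end());
      std::vector<int> newI(pu);
      for (int t = 0; t < pu; ++t) newI[t] = g[t].second;
      std::sort(newI.begin(), newI.end());
      init[u] = newI;
    }
    ch.set_state(ch.y, init);
  }
  int round = 0;
  bool changed = true;
  while (changed && round < max_rounds) {
    changed = false;
    ++round;
    Rcpp::checkUserInterrupt();
    if (move_labels) {
      for (int i = 0; i < n; ++i) {
        ch.remove_seq(i);
        ch.assignment_logw(i, lw);
        int best = 0;
        for (int u = 1; u < k; ++u)
          if (lw[u] > lw[best]) best = u;
        if (best != ch.y[i]) changed = true;
        ch.add_seq(i, best);
      }
    }
    std::vector<std::vector<int>> newImpl(k);
    bool imp_changed = false;
    for (int u = 0; u < k; ++u) {
      int pu = ch.p[u];
      if (pu == 0 || pu == l) {
        newImpl[u] = ch.impl[u];
        std::sort(newImpl[u].begin(), newImpl[u].end());
        continue;
      }
      std::vector<std::pair<double, int>> g(l);
      for (int j = 0; j < l; ++j) {
        const int* c = ch.cu(u, j);
        const int* b = &ch.bgc[(size_t)j * 4];
        int bw[4];
        int nw;
        if (ch.imp[(size_t)u * l + j]) {
          for (int t = 0; t < 4; ++t) bw[t] = b[t];
          nw = ch.bgtot[j];
        } else {
          for (int t = 0; t < 4; ++t) bw[t] = b[t] - c[t];
          nw = ch.bgtot[j] - ch.sizes[u];
        }
        int mg[4] = {bw[0] + c[0], bw[1] + c[1], bw[2] + c[2], bw[3] + c[3]};
        double gain = ch.dm4(c, ch.sizes[u]) + ch.dm4(bw, nw) -
                      ch.dm4(mg, nw + ch.sizes[u]);
        g[j] = std::make_pair(-gain, j);
      }
      std::sort(g.begin(), g.end());
      std::vector<int> newI(pu);
      for (int t = 0; t < pu; ++t) newI[t] = g[t].second;
      std::sort(newI.begin(), newI.end());
      std::vector<int> curI = ch.impl[u];
      std::sort(curI.begin(), curI.end());
      if (newI != curI) imp_changed = true;
      newImpl[u] = newI;
    }
    if (imp_changed) {
      changed = true;
      ch.set_state(ch.y, newImpl);
    }
  }
  IntegerVector out_y(n);
  for (int i = 0; i < n; ++i) out_y[i] = ch.y[i] + 1;
  List out_I(k);
  for (int u = 0; u < k; ++u) {
    std::vector<int> iu = ch.impl[u];
    std::sort(iu.begin(), iu.end());
    IntegerVector v(iu.size());
    for (size_t j = 0; j < iu.size(); ++j) v[j] = iu[j] + 1;
    out_I[u] = v;
  }
  return List::create(_["y"] = out_y, _["I"] = out_I,
                      _["score"] = ch.score(), _["rounds"] = round);
}

// Exact collapsed conditional P(y_i = u | y_{-i}, I, X), sequence i held out.
// [[Rcpp::export]]
NumericVector cpp_assignment_probs(IntegerMatrix X, IntegerVector y, List I,
                                   int i, double alpha) {
  int k = I.size();
  Chain ch = chain_from(X, y, I, k, alpha);
  ch.remove_seq(i - 1);
  std::vector<double> lw(k);
  ch.assignment_logw(i - 1, lw);
  double m = lw[0];
  for (int u = 1; u < k; ++u)
    if (lw[u] > m) m = lw[u];
  double tot = 0.0;
  NumericVector out(k);
  for (int u = 0; u < k; ++u) {
    out[u] = std::exp(lw[u] - m);
    tot += out[u];
  }
  for (int u = 0; u < k; ++u) out[u] /= tot;
  return out;
}

// Collapsed score log-ratio for the (j_in, j_out) swap in architecture u.
// [[Rcpp::export]]
double cpp_swap_delta(IntegerMatrix X, IntegerVector y, List I, int u,
                      int j_in, int j_out, double alpha) {
  int k = I.size();
  Chain ch = chain_from(X, y, I, k, alpha);
  return ch.swap_delta(u - 1, j_in - 1, j_out - 1);
}

// Collapsed joint score log P(X, y, I | structure) up to the constant
// uniform prior over position sets.
// [[Rcpp::export]]
double cpp_state_score(IntegerMatrix X, IntegerVector y, List I, double alpha) {
  int k = I.size();
  Chain ch = chain_from(X, y, I, k, alpha);
  return ch.score();
}
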