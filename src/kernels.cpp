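#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct form II transposed IIR filter; a[0] must be 1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (nz > 0 ? z[0] : 0.0);
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    if (nz > 0) z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}

// Lempel-Ziv 1976 exhaustive-history phrase count, linear-time via an online
// suffix automaton: each phrase is the shortest prefix of the remainder that
// cannot be copied (with self-overlap allowed) from the already-seen string.
// [[Rcpp::export]]
int lz76_count_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  // suffix automaton over a binary/small alphabet (values must be 0..3)
  struct State { int len, link; int next[4]; };
  std::vector<State> st;
  st.reserve(2 * n + 4);
  State root; root.len = 0; root.link = -1;
  for (int c = 0; c < 4; ++c) root.next[c] = -1;
  st.push_back(root);
  int last = 0;
  int inserted = 0;        // characters of s currently in the automaton
  int ext_q = -1, ext_clone = -1; // set when an extension clones a state
  auto sa_extend = [&](int c) {
    ext_q = -1; ext_clone = -1;
    int cur = (int)st.size();
    State ns; ns.len = st[last].len + 1; ns.link = -1;
    for (int k = 0; k < 4; ++k) ns.next[k] = -1;
    st.push_back(ns);
    int p = last;
    while (p != -1 && st[p].next[c] == -1) { st[p].next[c] = cur; p = st[p].link; }
    if (p == -1) {
      st[cur].link = 0;
    } else {
      int q = st[p].next[c];
      if (st[p].len + 1 == st[q].len) {
        st[cur].link = q;
      } else {
        int clone = (int)st.size();
        State nc = st[q]; nc.len = st[p].len + 1;
        st.push_back(nc);
        while (p != -1 && st[p].next[c] == q) { st[p].next[c] = clone; p = st[p].link; }
        st[q].link = clone; st[cur].link = clone;
        ext_q = q; ext_clone = clone;
      }
    }
    last = cur;
  };
  int count = 0, p = 0, l = 0, cur = 0;
  while (p < n) {
    // matched s[p..p+l-1]; automaton must contain exactly s[0..p+l-1]
    while (inserted < p + l) {
      sa_extend(s[inserted]); ++inserted;
      // a clone may take over the equivalence class of our held match
      if (ext_clone >= 0 && cur == ext_q && l <= st[ext_clone].len) cur = ext_clone;
    }
    if (p + l >= n) { ++count; break; } // matched to the end: final phrase
    int c = s[p + l];
    int nxt = (cur >= 0) ? st[cur].next[c] : -1;
    if (nxt != -1) {
      cur = nxt; ++l;
    } else {
      ++count;          // phrase = matched part plus one unmatched symbol
      p += l + 1;
      l = 0; cur = 0;
    }
  }
  return count;
}

// Kaspar & Schuster form of the same parse; kept as an internal cross-check.
// [[Rcpp::export]]
int lz76_count_ks_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] != s[l + k - 1]) {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    } else {
      ++k;
      if (l + k > n) { ++c; break; }
    }
  }
  return c;
}

// Context-tree weighting entropy rate for a binary sequence, KT estimator at
// every node, tree depth `depth`. The context preceding the first samples is
// zero-padded. Returns -log2 P_w(x) / N in bits per symbol.
struct CtwNode {
  double a = 0.0, b = 0.0;   // counts of 0s and 1s seen at this node
  double le = 0.0, lw = 0.0; // log2 KT estimate, log2 weighted probability
  int child[2] = {-1, -1};
};

// [[Rcpp::export]]
double ctw_rate_cpp(IntegerVector bits, int depth) {
  int n = bits.size();
  if (n == 0) return NA_REAL;
  std::vector<CtwNode> tree;
  tree.reserve((size_t)std::min<long long>((long long)n * (depth + 1) + 1, 4000000LL));
  tree.push_back(CtwNode());
  std::vector<int> path(depth + 1);
  for (int t = 0; t < n; ++t) {
    int x = bits[t];
    // walk down following the context (most recent symbol first)
    path[0] = 0;
    for (int d = 1; d <= depth; ++d) {
      int ctx = (t - d >= 0) ? bits[t - d] : 0;
      int cur = path[d - 1];
      if (tree[cur].child[ctx] < 0) {
        tree[cur].child[ctx] = (int)tree.size();
        tree.push_back(CtwNode());
      }
      path[d] = tree[cur].child[ctx];
    }
    // bottom-up update: KT factor then weighted mixture
    for (int d = depth; d >= 0; --d) {
      CtwNode &nd = tree[path[d]];
      double cx = (x == 0) ? nd.a : nd.b;
      nd.le += std::log2((cx + 0.5) / (nd.a + nd.b + 1.0));
      if (x == 0) nd.a += 1.0; else nd.b += 1.0;
      if (d == depth) {
        nd.lw = nd.le;
      } else {
        double lc = 0.0;
        if (nd.child[0] >= 0) lc += tree[nd.child[0]].lw;
        if (nd.child[1] >= 0) lc += tree[nd.child[1]].lw;
        // log2(0.5*2^le + 0.5*2^lc), stable
        double m = std::max(nd.le, lc);
        nd.lw = m + std::log2(std::exp2(nd.le - m) + std::exp2(lc - m)) - 1.0;
      }
    }
  }
  return -tree[0].lw / (double)n;
}

// Fuzzy (sigmoidal-membership) sample-entropy pair sums. Templates are the
// N - m overlapping vectors of length m (and m+1) starting at the same
// indices; distance is Chebyshev; membership mu(d) = 1/(1+exp((d-0.5)/r)).
// Returns c(B, A): summed memberships at dimension m and m+1 over i < j.
// [[Rcpp::export]]
NumericVector fuzzy_sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m; // number of templates
  double A = 0.0, B = 0.0;
  const double *xp = REAL(x);
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(xp[i + k] - xp[j + k]);
        if (d > dm) dm = d;
      }
      double d1 = std::fabs(xp[i + m] - xp[j + m]);
      double dm1 = (d1 > dm) ? d1 : dm;
      B += 1.0 / (1.0 + std::exp((dm - 0.5) / r));
      A += 1.0 / (1.0 + std::exp((dm1 - 0.5) / r));
    }
  }
  return NumericVector::create(B, A);
}

// Ordinal-pattern symbolization: each window (x_t, x_{t+tau}, ..., m samples)
// is mapped to the lexicographic index of its rank permutation; ties are
// broken by temporal order (earlier sample ranks lower). Returns 0-based
// symbols of length n - (m-1)*tau.
// [[Rcpp::export]]
IntegerVector ordinal_symbols_cpp(NumericVector x, int m, int tau) {
  int n = x.size();
  int ns = n - (m - 1) * tau;
  if (ns <= 0) stop("signal too short for ordinal symbolization");
  IntegerVector out(ns);
  std::vector<int> rank(m), used(m);
  const double *xp = REAL(x);
  for (int t = 0; t < ns; ++t) {
    // rank of each element (0-based): count strictly smaller, or equal-earlier
    for (int i = 0; i < m; ++i) {
      int ri = 0;
      double xi = xp[t + i * tau];
      for (int j = 0; j < m; ++j) {
        double xj = xp[t + j * tau];
        if (xj < xi || (xj == xi && j < i)) ++ri;
      }
      rank[i] = ri;
    }
    // Lehmer code -> lexicographic index of the rank sequence
    int idx = 0, fact = 1;
    for (int i = 2; i <= m; ++i) fact *= i;
    for (int i = 0; i < m; ++i) used[i] = 0;
    for (int i = 0; i < m; ++i) {
      fact /= (m - i);
      int smaller = 0;
      for (int v = 0; v < rank[i]; ++v) if (!used[v]) ++smaller;
      idx += smaller * fact;
      used[rank[i]] = 1;
    }
    out[t] = idx;
  }
  return out;
}

// Weighted symbolic mutual information, normalized by the (unnormalized,
// natural-log) permutation entropies of the two windows:
//   wSMI'(X,Y) = 2 * sum_{k,l} w(k,l) p(k,l) log(p(k,l)/(p(k)p(l)))
//                  / (PE(X) + PE(Y))
// with w = 0 when l == k or l == opposite(k). Computed per window for every
// channel pair; returns an npair x nwin matrix (NA where a window has no
// symbols or both marginal entropies vanish).
// [[Rcpp::export]]
NumericMatrix wsmi_windows_cpp(IntegerMatrix sym, IntegerMatrix pairs,
                               IntegerVector win_start, IntegerVector win_len,
                               IntegerVector opposite, int n_alpha) {
  int npair = pairs.nrow(), nwin = win_start.size();
  NumericMatrix out(npair, nwin);
  std::vector<double> joint(n_alpha * n_alpha), px(n_alpha), py(n_alpha);
  for (int w = 0; w < nwin; ++w) {
    int s0 = win_start[w], len = win_len[w];
    for (int p = 0; p < npair; ++p) {
      int ci = pairs(p, 0), cj = pairs(p, 1);
      std::fill(joint.begin(), joint.end(), 0.0);
      std::fill(px.begin(), px.end(), 0.0);
      std::fill(py.begin(), py.end(), 0.0);
      for (int t = 0; t < len; ++t) {
        int a = sym(ci, s0 + t), b = sym(cj, s0 + t);
        joint[a * n_alpha + b] += 1.0;
        px[a] += 1.0; py[b] += 1.0;
      }
      double N = (double)len;
      if (N <= 0) { out(p, w) = NA_REAL; continue; }
      double mi = 0.0, hx = 0.0, hy = 0.0;
      for (int a = 0; a < n_alpha; ++a) {
        if (px[a] > 0) hx -= (px[a] / N) * std::log(px[a] / N);
        if (py[a] > 0) hy -= (py[a] / N) * std::log(py[a] / N);
      }
      for (int a = 0; a < n_alpha; ++a) {
        for (int b = 0; b < n_alpha; ++b) {
          if (b == a || b == opposite[a]) continue;
          double pj = joint[a * n_alpha + b];
          if (pj > 0 && px[a] > 0 && py[b] > 0) {
            pj /= N;
            mi += pj * std::log(pj * N * N / (px[a] * py[b]));
          }
        }
      }
      double den = hx + hy;
      out(p, w) = (den > 0) ? 2.0 * mi / den : NA_REAL;
    }
  }
  return out;
}
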