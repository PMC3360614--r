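#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=U/T, 4=N/other. Energies in kcal/mol.
// Stack table is a length-625 vector indexed by ((x1*5+y1)*5+x2)*5+y2 for the
// stack 5'-x1 x2-3' / 3'-y1 y2-5'; non-stackable combinations hold +Inf.

static const double INF = std::numeric_limits<double>::infinity();

static inline int sidx(int x1, int y1, int x2, int y2) {
  return ((x1 * 5 + y1) * 5 + x2) * 5 + y2;
}

// Mismatch counts of a short reference against every offset of a longer
// sequence; any position involving code 4 (N) counts as a mismatch.
// [[Rcpp::export]]
IntegerVector hamming_profile_cpp(IntegerVector seq, IntegerVector ref) {
  int n = seq.size(), m = ref.size();
  if (m == 0) stop("reference must be non-empty");
  if (n < m) return IntegerVector(0);
  IntegerVector out(n - m + 1);
  for (int off = 0; off + m <= n; ++off) {
    int mm = 0;
    for (int t = 0; t < m; ++t) {
      int a = seq[off + t], b = ref[t];
      if (a != b || a == 4 || b == 4) ++mm;
    }
    out[off] = mm;
  }
  return out;
}

static inline double loop_cost(int g1, int g2, const NumericVector& bulge,
                               const NumericVector& internal_) {
  int tot = g1 + g2;
  if (g1 == 0 || g2 == 0) {
    if (tot < 1 || tot > bulge.size()) return INF;
    return bulge[tot - 1];
  }
  if (tot < 2 || tot > internal_.size()) return INF;
  return internal_[tot - 1];
}

// Minimum-free-energy single-hairpin (non-branching) structure.
// hairpin_pen[k-1] is the closing penalty of a terminal loop of k unpaired nt
// (entries below index 3 are +Inf on the R side). Returns the open chain
// (dg = 0, no pairs) when no negative-energy hairpin exists.
// [[Rcpp::export]]
List fold_hairpin_cpp(IntegerVector seq, NumericVector stack,
                      LogicalMatrix pair_ok, NumericVector hairpin_pen,
                      NumericVector bulge, NumericVector internal_,
                      int max_interior) {
  int n = seq.size();
  std::vector<std::vector<double>> H(n, std::vector<double>(n, INF));
  // trace: inner pair chosen for (i,j); (-1,-1) means terminal hairpin loop
  std::vector<std::vector<int>> tk(n, std::vector<int>(n, -2));
  std::vector<std::vector<int>> tl(n, std::vector<int>(n, -2));

  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int bi = seq[i], bj = seq[j];
      if (bi > 3 || bj > 3 || !pair_ok(bi, bj)) continue;
      double best = INF;
      int bk = -2, bl = -2;
      int loop = j - i - 1;
      if (loop >= 3 && loop <= hairpin_pen.size()) {
        best = hairpin_pen[loop - 1];
        bk = -1; bl = -1;
      }
      int kmax = std::min(i + 1 + max_interior, j - 1);
      for (int k = i + 1; k <= kmax; ++k) {
        int g1 = k - i - 1;
        int lmin = std::max(k + 4, j - 1 - (max_interior - g1));
        for (int l = j - 1; l >= lmin; --l) {
          if (H[k][l] == INF) continue;
          int g2 = j - l - 1;
          double cost;
          if (g1 == 0 && g2 == 0) {
            cost = stack[sidx(bi, bj, seq[k], seq[l])];
          } else {
            cost = loop_cost(g1, g2, bulge, internal_);
          }
          if (cost == INF) continue;
          double cand = H[k][l] + cost;
          if (cand < best) { best = cand; bk = k; bl = l; }
        }
      }
      H[i][j] = best;
      tk[i][j] = bk; tl[i][j] = bl;
    }
  }

  double mfe = 0.0;
  int oi = -1, oj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 4; j < n; ++j)
      if (H[i][j] < mfe) { mfe = H[i][j]; oi = i; oj = j; }

  std::vector<int> pi, pj;
  if (oi >= 0) {
    int i = oi, j = oj;
    while (i >= 0) {
      pi.push_back(i); pj.push_back(j);
      int k = tk[i][j], l = tl[i][j];
      i = k; j = l;  // (-1,-1) terminates at the terminal loop
      if (i < 0) break;
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t t = 0; t < pi.size(); ++t) { pairs(t, 0) = pi[t]; pairs(t, 1) = pj[t]; }
  return List::create(_["dg"] = mfe, _["pairs"] = pairs);
}

// Intermolecular duplex MFE: a is 5'->3', b_rev is the target site already
// reversed so both indices increase along the duplex; no intramolecular
// pairs. init is charged once at the first base pair.
static void duplex_fill(const IntegerVector& a, const IntegerVector& b,
                        const NumericVector& stack, const LogicalMatrix& pair_ok,
                        const NumericVector& bulge, const NumericVector& internal_,
                        double init, int max_gap,
                        std::vector<std::vector<double>>& E,
                        double& best, int& bi, int& bj,
                        std::vector<std::vector<int>>& ti,
                        std::vector<std::vector<int>>& tj) {
  int n = a.size(), m = b.size();
  best = INF; bi = -1; bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      int xa = a[i], xb = b[j];
      if (xa > 3 || xb > 3 || !pair_ok(xa, xb)) { E[i][j] = INF; continue; }
      double bst = init;
      int fk = -1, fl = -1;
      int i2min = std::max(0, i - 1 - max_gap);
      for (int i2 = i - 1; i2 >= i2min; --i2) {
        int g1 = i - i2 - 1;
        int j2min = std::max(0, j - 1 - (max_gap - g1));
        for (int j2 = j - 1; j2 >= j2min; --j2) {
          if (E[i2][j2] == INF) continue;
          int g2 = j - j2 - 1;
          double cost;
          if (g1 == 0 && g2 == 0) {
            cost = stack[sidx(a[i2], b[j2], xa, xb)];
          } else {
            cost = loop_cost(g1, g2, bulge, internal_);
          }
          if (cost == INF) continue;
          double cand = E[i2][j2] + cost;
          if (cand < bst) { bst = cand; fk = i2; fl = j2; }
        }
      }
      E[i][j] = bst;
      ti[i][j] = fk; tj[i][j] = fl;
      if (bst < best) { best = bst; bi = i; bj = j; }
    }
  }
}

// [[Rcpp::export]]
List duplex_mfe_cpp(IntegerVector a, IntegerVector b_rev, NumericVector stack,
                    LogicalMatrix pair_ok, NumericVector bulge,
                    NumericVector internal_, double init, int max_gap) {
  int n = a.size(), m = b_rev.size();
  std::vector<std::vector<double>> E(n, std::vector<double>(m, INF));
  std::vector<std::vector<int>> ti(n, std::vector<int>(m, -1));
  std::vector<std::vector<int>> tj(n, std::vector<int>(m, -1));
  double best; int bi, bj;
  duplex_fill(a, b_rev, stack, pair_ok, bulge, internal_, init, max_gap,
              E, best, bi, bj, ti, tj);
  std::vector<int> pa, pb;
  if (best < 0) {
    int i = bi, j = bj;
    while (i >= 0) {
      pa.push_back(i); pb.push_back(j);
      int i2 = ti[i][j], j2 = tj[i][j];
      i = i2; j = j2;
    }
  }
  double dg = best < 0 ? best : 0.0;
  IntegerMatrix pairs(pa.size(), 2);
  // traceback collected 3'->5' on a; emit 5'->3'
  int np = pa.size();
  for (int t = 0; t < np; ++t) {
    pairs(t, 0) = pa[np - 1 - t];
    pairs(t, 1) = pb[np - 1 - t];
  }
  return List::create(_["dg"] = dg, _["pairs"] = pairs);
}

// Best duplex of a short fragment against sliding windows of a long target:
// returns per-window-start best energies condensed to the overall best window.
// [[Rcpp::export]]
List duplex_scan_cpp(IntegerVector frag, IntegerVector target, int window_len,
                     NumericVector stack, LogicalMatrix pair_ok,
                     NumericVector bulge, NumericVector internal_,
                     double init, int max_gap) {
  int L = target.size();
  int w = std::min(window_len, L);
  int nstart = L - w + 1;
  double best_dg = 0.0;
  int best_start = -1;
  int n = frag.size();
  std::vector<std::vector<double>> E(n, std::vector<double>(w, INF));
  std::vector<std::vector<int>> ti(n, std::vector<int>(w, -1));
  std::vector<std::vector<int>> tj(n, std::vector<int>(w, -1));
  for (int s = 0; s < nstart; ++s) {
    IntegerVector win(w);
    for (int t = 0; t < w; ++t) win[t] = target[s + w - 1 - t];  // reversed
    double bst; int bi, bj;
    duplex_fill(frag, win, stack, pair_ok, bulge, internal_, init, max_gap,
                E, bst, bi, bj, ti, tj);
    if (bst < best_dg) { best_dg = bst; best_start = s; }
  }
  return List::create(_["dg"] = best_dg, _["start"] = best_start,
                      _["window_len"] = w);
}
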