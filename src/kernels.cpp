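#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Sequence coding convention shared with R/encode.R:
//   0 = non-comparable (gap '-', missing '?', any IUPAC ambiguity code)
//   1 = A, 2 = C, 3 = G, 4 = T
// Transitions are A<->G and C<->T; everything else among {A,C,G,T} is a
// transversion.

static inline bool is_purine(int x) { return x == 1 || x == 3; }

// Pairwise transition / transversion / comparable-site counts for all pairs
// of rows of a coded alignment. The K2P closed form itself is evaluated in R.
// [[Rcpp::export]]
List k2p_pair_counts(const IntegerMatrix& coded) {
  const int n = coded.nrow(), L = coded.ncol();
  NumericMatrix ts(n, n), tv(n, n), nc(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int s = 0, v = 0, m = 0;
      for (int k = 0; k < L; ++k) {
        const int a = coded(i, k), b = coded(j, k);
        if (a == 0 || b == 0) continue;
        ++m;
        if (a != b) {
          if (is_purine(a) == is_purine(b)) ++s; else ++v;
        }
      }
      ts(i, j) = ts(j, i) = s;
      tv(i, j) = tv(j, i) = v;
      nc(i, j) = nc(j, i) = m;
    }
  }
  return List::create(_["transitions"] = ts,
                      _["transversions"] = tv,
                      _["n_compared"] = nc);
}

// Classic neighbor-joining (Saitou & Nei 1987, Studier & Keppler 1988).
// Tips are 0..n-1; internal nodes are created as n, n+1, ..., 2n-3; the last
// created node is the trifurcating center of the unrooted tree.
//
// Tie-breaking: the Q criterion is scanned in ascending (i, j) order of node
// creation (tips in input order first), and a candidate replaces the current
// minimum only when strictly smaller, so the lowest (row, col) pair wins.
//
// Negative branch lengths are clamped to zero with the deficit moved to the
// sister edge (raw values are returned alongside for logging).
// [[Rcpp::export]]
List nj_cpp(const NumericMatrix& dist) {
  const int n = dist.nrow();
  if (n < 3) stop("neighbor joining needs at least 3 leaves");
  const int n_nodes = 2 * n - 2;
  std::vector<std::vector<double>> D(n_nodes, std::vector<double>(n_nodes, 0.0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D[i][j] = dist(i, j);

  std::vector<int> active;
  for (int i = 0; i < n; ++i) active.push_back(i);

  const int n_edges = 2 * n - 3;
  IntegerMatrix edge(n_edges, 2);
  NumericVector elen(n_edges), elen_raw(n_edges);
  int e = 0, next_node = n;

  while ((int)active.size() > 3) {
    const int r = active.size();
    std::vector<double> R(r, 0.0);
    for (int a = 0; a < r; ++a)
      for (int b = 0; b < r; ++b)
        if (a != b) R[a] += D[active[a]][active[b]];

    int bi = -1, bj = -1;
    double bq = R_PosInf;
    for (int a = 0; a < r; ++a) {
      for (int b = a + 1; b < r; ++b) {
        const double q = (r - 2) * D[active[a]][active[b]] - R[a] - R[b];
        if (q < bq) { bq = q; bi = a; bj = b; }
      }
    }
    const int ni = active[bi], nj = active[bj];
    const double dij = D[ni][nj];
    double li = 0.5 * dij + (R[bi] - R[bj]) / (2.0 * (r - 2));
    double lj = dij - li;
    const double li_raw = li, lj_raw = lj;
    if (li < 0) { lj += li; li = 0; }
    if (lj < 0) { li += lj; lj = 0; if (li < 0) li = 0; }

    const int u = next_node++;
    for (int a = 0; a < r; ++a) {
      const int k = active[a];
      if (k == ni || k == nj) continue;
      const double duk = 0.5 * (D[ni][k] + D[nj][k] - dij);
      D[u][k] = D[k][u] = duk;
    }
    edge(e, 0) = u; edge(e, 1) = ni; elen[e] = li; elen_raw[e] = li_raw; ++e;
    edge(e, 0) = u; edge(e, 1) = nj; elen[e] = lj; elen_raw[e] = lj_raw; ++e;

    active.erase(active.begin() + bj);
    active.erase(active.begin() + bi);
    active.push_back(u);
  }

  // Final three nodes joined at the center with the exact 3-point lengths.
  const int a = active[0], b = active[1], c = active[2];
  const int u = next_node++;
  double la = 0.5 * (D[a][b] + D[a][c] - D[b][c]);
  double lb = 0.5 * (D[a][b] + D[b][c] - D[a][c]);
  double lc = 0.5 * (D[a][c] + D[b][c] - D[a][b]);
  const double lar = la, lbr = lb, lcr = lc;
  if (la < 0) la = 0;
  if (lb < 0) lb = 0;
  if (lc < 0) lc = 0;
  edge(e, 0) = u; edge(e, 1) = a; elen[e] = la; elen_raw[e] = lar; ++e;
  edge(e, 0) = u; edge(e, 1) = b; elen[e] = lb; elen_raw[e] = lbr; ++e;
  edge(e, 0) = u; edge(e, 1) = c; elen[e] = lc; elen_raw[e] = lcr; ++e;

  return List::create(_["edge"] = edge,
                      _["edge_length"] = elen,
                      _["edge_length_raw"] = elen_raw,
                      _["n_tip"] = n,
                      _["center"] = u);
}

// Seed-and-extend local alignment ("BLAST-lite").
//
// Stage 1: exact word seeding (words containing any non-ACGT code never
// seed). Stage 2: per seeded diagonal, ungapped X-drop extension (reported
// as the best HSP score). Stage 3: banded affine-gap Smith-Waterman over the
// diagonal band spanned by all seeds, widened by band_pad on both sides.
//
// Gap cost convention: a gap of length L costs gap_open + L * gap_extend
// (both negative), i.e. the first gap character pays open + extend.
// The result equals the full Smith-Waterman optimum whenever the optimal
// local path stays within the seeded band.
// [[Rcpp::export]]
List seed_extend_align(const IntegerVector& q, const IntegerVector& s,
                       int word_size, double match, double mismatch,
                       double gap_open, double gap_extend,
                       int band_pad, double xdrop) {
  const int m = q.size(), n = s.size();
  List no_hit = List::create(_["score"] = 0.0, _["hsp_score"] = 0.0,
                             _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
                             _["s_start"] = NA_INTEGER, _["s_end"] = NA_INTEGER,
                             _["n_seeds"] = 0);
  if (m < word_size || n < word_size) return no_hit;

  // Hash query words (base-5 packing keeps codes 0..4 distinct; words with a
  // 0 code are skipped).
  std::unordered_map<long long, std::vector<int>> words;
  long long key = 0, base = 1;
  for (int k = 0; k < word_size - 1; ++k) base *= 5;
  int valid = 0;
  for (int i = 0; i < m; ++i) {
    if (i == 0) {
      key = 0; valid = 0;
      for (int k = 0; k < word_size && k < m; ++k) {
        key = key * 5 + q[k];
        if (q[k] != 0) ++valid;
      }
      if (word_size <= m && valid == word_size) words[key].push_back(0);
      continue;
    }
    if (i + word_size > m) break;
    if (q[i - 1] != 0) --valid;
    key = (key - (long long)q[i - 1] * base) * 5 + q[i + word_size - 1];
    if (q[i + word_size - 1] != 0) ++valid;
    if (valid == word_size) words[key].push_back(i);
  }
  if (words.empty()) return no_hit;

  // Scan subject, collect seed diagonals (d = j - i).
  std::vector<std::pair<int, int>> seeds;  // (i, j) word starts
  int dmin = n + m, dmax = -(n + m);
  key = 0; valid = 0;
  for (int j = 0; j + word_size <= n; ++j) {
    if (j == 0) {
      key = 0; valid = 0;
      for (int k = 0; k < word_size; ++k) {
        key = key * 5 + s[k];
        if (s[k] != 0) ++valid;
      }
    } else {
      if (s[j - 1] != 0) --valid;
      key = (key - (long long)s[j - 1] * base) * 5 + s[j + word_size - 1];
      if (s[j + word_size - 1] != 0) ++valid;
    }
    if (valid != word_size) continue;
    auto it = words.find(key);
    if (it == words.end()) continue;
    for (int i : it->second) {
      seeds.push_back(std::make_pair(i, j));
      const int d = j - i;
      if (d < dmin) dmin = d;
      if (d > dmax) dmax = d;
    }
  }
  if (seeds.empty()) return no_hit;

  // Ungapped X-drop extension (best HSP score, diagnostics); one extension
  // per distinct diagonal suffices since the extension sweeps the whole
  // diagonal anyway.
  std::vector<std::pair<int, int>> diag_seeds;
  {
    std::unordered_map<int, std::pair<int, int>> first_on_diag;
    for (size_t t = 0; t < seeds.size(); ++t) {
      int d = seeds[t].second - seeds[t].first;
      if (first_on_diag.find(d) == first_on_diag.end())
        first_on_diag[d] = seeds[t];
    }
    for (auto& kv : first_on_diag) diag_seeds.push_back(kv.second);
  }
  double best_hsp = 0.0;
  for (size_t t = 0; t < diag_seeds.size(); ++t) {
    int i0 = diag_seeds[t].first, j0 = diag_seeds[t].second;
    double sc = word_size * match;
    // right
    double cur = sc, best = sc;
    for (int i = i0 + word_size, j = j0 + word_size; i < m && j < n; ++i, ++j) {
      cur += (q[i] != 0 && q[i] == s[j]) ? match : mismatch;
      if (cur > best) best = cur;
      if (best - cur > xdrop) break;
    }
    // left
    cur = best;
    double best2 = best;
    for (int i = i0 - 1, j = j0 - 1; i >= 0 && j >= 0; --i, --j) {
      cur += (q[i] != 0 && q[i] == s[j]) ? match : mismatch;
      if (cur > best2) best2 = cur;
      if (best2 - cur > xdrop) break;
    }
    if (best2 > best_hsp) best_hsp = best2;
  }

  // Banded affine Smith-Waterman over diagonals [dmin - pad, dmax + pad].
  const int lo = dmin - band_pad, hi = dmax + band_pad;
  const int W = hi - lo + 1;
  const double NEG = -1e30;
  std::vector<double> Hprev(W, 0.0), Hcur(W, 0.0);
  std::vector<double> Eprev(W, NEG), Ecur(W, NEG);  // gap in query (consumes subject)
  std::vector<double> Fprev(W, NEG), Fcur(W, NEG);  // gap in subject (consumes query)
  // start-coordinate propagation for span reporting
  std::vector<int> HSq(W, 0), HSs(W, 0), HSqp(W, 0), HSsp(W, 0);
  std::vector<int> ESq(W, 0), ESs(W, 0), ESqp(W, 0), ESsp(W, 0);
  std::vector<int> FSq(W, 0), FSs(W, 0), FSqp(W, 0), FSsp(W, 0);

  double best = 0.0;
  int bqs = NA_INTEGER, bqe = NA_INTEGER, bss = NA_INTEGER, bse = NA_INTEGER;

  for (int i = 0; i < m; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), 0.0);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    const int jlo = std::max(0, i + lo), jhi = std::min(n - 1, i + hi);
    for (int j = jlo; j <= jhi; ++j) {
      const int w = j - i - lo;  // band offset
      // E: gap in query, from (i, j-1) = band offset w-1 in same row
      double e_val = NEG; int esq = 0, ess = 0;
      if (w - 1 >= 0) {
        const double open_new = Hcur[w - 1] + gap_open + gap_extend;
        const double extend_old = Ecur[w - 1] + gap_extend;
        if (open_new >= extend_old) {
          // same row: Hcur / HSq at w-1 are already computed for this i
          e_val = open_new; esq = HSq[w - 1]; ess = HSs[w - 1];
        } else {
          e_val = extend_old; esq = ESq[w - 1]; ess = ESs[w - 1];
        }
      }
      // F: gap in subject, from (i-1, j) = band offset w+1 in previous row
      double f_val = NEG; int fsq = 0, fss = 0;
      if (w + 1 < W && i > 0) {
        const double open_new = Hprev[w + 1] + gap_open + gap_extend;
        const double extend_old = Fprev[w + 1] + gap_extend;
        if (open_new >= extend_old) {
          f_val = open_new; fsq = HSqp[w + 1]; fss = HSsp[w + 1];
        } else {
          f_val = extend_old; fsq = FSqp[w + 1]; fss = FSsp[w + 1];
        }
      }
      // H: diagonal from (i-1, j-1) = same band offset in previous row
      const double sub = (q[i] != 0 && q[i] == s[j]) ? match : mismatch;
      double diag = (i > 0 && j > 0) ? Hprev[w] + sub : sub;
      int dsq, dss;
      if (i > 0 && j > 0 && Hprev[w] > 0) { dsq = HSqp[w]; dss = HSsp[w]; }
      else { dsq = i; dss = j; }

      double h = 0.0; int hsq = i, hss = j;
      if (diag > h) { h = diag; hsq = dsq; hss = dss; }
      if (e_val > h) { h = e_val; hsq = esq; hss = ess; }
      if (f_val > h) { h = f_val; hsq = fsq; hss = fss; }

      Hcur[w] = h; HSq[w] = hsq; HSs[w] = hss;
      Ecur[w] = e_val; ESq[w] = esq; ESs[w] = ess;
      Fcur[w] = f_val; FSq[w] = fsq; FSs[w] = fss;

      if (h > best) {
        best = h; bqs = hsq + 1; bqe = i + 1; bss = hss + 1; bse = j + 1;
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
    HSqp = HSq; HSsp = HSs;
    ESqp = ESq; ESsp = ESs;
    FSqp = FSq; FSsp = FSs;
  }

  return List::create(_["score"] = best, _["hsp_score"] = best_hsp,
                      _["q_start"] = bqs, _["q_end"] = bqe,
                      _["s_start"] = bss, _["s_end"] = bse,
                      _["n_seeds"] = (int)seeds.size());
}
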