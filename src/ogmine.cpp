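#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <string>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Suffix array over a concatenated reference text (reads joined by '#').
// Plain comparison sort; reference subsets at the scales this package targets
// (up to a few Mbp) sort in seconds and the index is built once per subset
// pair.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sa_build_cpp")]]
IntegerVector sa_build_cpp(std::string text) {
  const char* s = text.c_str();
  size_t n = text.size();
  std::vector<int> sa(n);
  for (size_t i = 0; i < n; ++i) sa[i] = (int)i;
  std::sort(sa.begin(), sa.end(), [&](int a, int b) {
    return std::strcmp(s + a, s + b) < 0;
  });
  IntegerVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = sa[i] + 1;  // 1-based for R
  return out;
}

static int sa_cmp(const char* s, size_t n, int pos, const char* pat, size_t k) {
  size_t avail = n - (size_t)pos;
  size_t m = std::min(avail, k);
  int c = std::strncmp(s + pos, pat, m);
  if (c != 0) return c;
  if (avail < k) return -1;  // suffix is a proper prefix of the pattern
  return 0;
}

// binary-search occurrence range; fills `hits` with 1-based positions,
// sorted ascending (deterministic)
static void sa_lookup_range(const std::string& text, const int* sa, int nsa,
                            const char* pat, size_t k,
                            std::vector<int>& hits) {
  const char* s = text.c_str();
  size_t n = text.size();
  int lo = 0, hi = nsa;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (sa_cmp(s, n, sa[mid] - 1, pat, k) < 0) lo = mid + 1; else hi = mid;
  }
  int first = lo;
  hi = nsa;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (sa_cmp(s, n, sa[mid] - 1, pat, k) <= 0) lo = mid + 1; else hi = mid;
  }
  hits.clear();
  for (int i = first; i < lo; ++i) hits.push_back(sa[i]);
  std::sort(hits.begin(), hits.end());
}

// All 1-based occurrence positions of `pattern` in `text`.
// [[Rcpp::export(name = ".sa_lookup_cpp")]]
IntegerVector sa_lookup_cpp(std::string text, IntegerVector sa,
                            std::string pattern) {
  std::vector<int> hits;
  sa_lookup_range(text, sa.begin(), sa.size(), pattern.c_str(),
                  pattern.size(), hits);
  return wrap(hits);
}

// ---------------------------------------------------------------------------
// Banded global (Needleman-Wunsch) alignment of the overlap region implied by
// a seed diagonal. The overlapping substrings are cut to the read ends on the
// seed diagonal; the band allows +-band of drift for internal indels.
// Scoring: match +1, mismatch -1, gap -2.
// ---------------------------------------------------------------------------

struct AlnResult {
  bool ok;
  int cols;     // alignment columns
  int matches;  // identical columns
};

static AlnResult banded_global(const char* a, int m, const char* b, int n,
                               int band, std::vector<int>& S) {
  const int NEG = -1000000000;
  if (m == 0 || n == 0) return {false, 0, 0};
  if (std::abs(m - n) > band) return {false, 0, 0};
  int W = 2 * band + 1;
  // score[i][j-i+band]
  S.assign((size_t)(m + 1) * W, NEG);
  auto idx = [&](int i, int j) { return i * W + (j - i + band); };
  S[idx(0, 0)] = 0;
  for (int j = 1; j <= std::min(n, band); ++j) S[idx(0, j)] = -2 * j;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(n, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG;
      if (j > 0 && j - 1 >= i - band) {  // gap in a
        int v = S[idx(i, j - 1)];
        if (v > NEG) best = std::max(best, v - 2);
      }
      if (j <= (i - 1) + band) {  // gap in b
        int v = S[idx(i - 1, j)];
        if (v > NEG) best = std::max(best, v - 2);
      }
      if (j > 0) {  // diagonal
        int v = S[idx(i - 1, j - 1)];
        if (v > NEG) best = std::max(best, v + (a[i - 1] == b[j - 1] ? 1 : -1));
      }
      S[idx(i, j)] = best;
    }
  }
  if (S[idx(m, n)] <= NEG / 2) return {false, 0, 0};
  // traceback to count columns and matches
  int i = m, j = n, cols = 0, matches = 0;
  while (i > 0 || j > 0) {
    int cur = S[idx(i, j)];
    if (i > 0 && j > 0 && j - 1 >= (i - 1) - band && j - 1 <= (i - 1) + band &&
        S[idx(i - 1, j - 1)] > NEG &&
        cur == S[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 1 : -1)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j; ++cols;
    } else if (i > 0 && j <= (i - 1) + band && S[idx(i - 1, j)] > NEG &&
               cur == S[idx(i - 1, j)] - 2) {
      --i; ++cols;
    } else {
      --j; ++cols;
    }
  }
  return {true, cols, matches};
}

struct SeedOverlap {
  bool ok;
  int cols, matches, type;
};

static SeedOverlap overlap_from_seed(const std::string& query,
                                     const std::string& ref, int qpos,
                                     int rpos, int band,
                                     std::vector<int>& buf) {
  int lq = query.size(), lr = ref.size();
  int d = qpos - rpos;  // implied offset of ref start on query coordinates
  int qs = std::max(0, d), rs = std::max(0, -d);
  int L = std::min(lq - qs, lr - rs);
  if (L <= 0) return {false, 0, 0, 0};
  AlnResult r = banded_global(query.c_str() + qs, L, ref.c_str() + rs, L,
                              band, buf);
  if (!r.ok) return {false, 0, 0, 0};
  int type;
  bool q_cov = (L == lq), r_cov = (L == lr);
  if (r_cov) type = 3;
  else if (q_cov) type = 2;
  else if (d > 0) type = 0;
  else type = 1;
  return {true, r.cols, r.matches, type};
}

// Overlap alignment between query and ref from a seed at (qpos, rpos),
// 0-based. Returns c(found, cols, matches, type):
//   type 0 = query extends left of ref (query suffix ~ ref prefix)
//        1 = ref extends left of query
//        2 = query contained in ref
//        3 = ref contained in query (ties, identical spans -> 3)
// [[Rcpp::export(name = ".overlap_from_seed_cpp")]]
IntegerVector overlap_from_seed_cpp(std::string query, std::string ref,
                                    int qpos, int rpos, int band) {
  std::vector<int> buf;
  SeedOverlap r = overlap_from_seed(query, ref, qpos, rpos, band, buf);
  if (!r.ok) return IntegerVector::create(0, 0, 0, 0);
  return IntegerVector::create(1, r.cols, r.matches, r.type);
}

// ---------------------------------------------------------------------------
// Scan one query subset against one indexed reference subset: k-mer seeds at
// a fixed step, suffix-array lookup, one banded alignment per read pair (the
// first seed seen for a pair decides; later seeds for the same pair are
// skipped). Returns an edge table in subset-local indices.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".scan_subset_pair_cpp")]]
DataFrame scan_subset_pair_cpp(CharacterVector query_seqs,
                               IntegerVector query_gid,
                               CharacterVector ref_seqs,
                               IntegerVector ref_gid,
                               std::string ref_text, IntegerVector sa,
                               IntegerVector ref_start,  // 1-based start in text
                               int k, int step, int band,
                               int min_overlap, double min_identity) {
  int nq = query_seqs.size(), nr = ref_seqs.size();
  std::vector<std::string> refs(nr);
  for (int i = 0; i < nr; ++i) refs[i] = as<std::string>(ref_seqs[i]);
  // map text position -> ref index via sorted starts
  std::vector<int> starts(nr);
  for (int i = 0; i < nr; ++i) starts[i] = ref_start[i];
  std::vector<int> out_q, out_r, out_len, out_type;
  std::vector<double> out_ident;
  std::unordered_set<long long> tried;
  std::vector<int> occ, buf;
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(query_seqs[qi]);
    int lq = q.size();
    if (lq < k) continue;
    tried.clear();
    for (int p = 0; p + k <= lq; p += step) {
      if (std::memchr(q.c_str() + p, 'N', k) != NULL) continue;
      sa_lookup_range(ref_text, sa.begin(), sa.size(), q.c_str() + p, k, occ);
      for (size_t oi = 0; oi < occ.size(); ++oi) {
        int pos = occ[oi];  // 1-based in text
        // find ref read containing pos
        int ri = (int)(std::upper_bound(starts.begin(), starts.end(), pos) -
                       starts.begin()) - 1;
        if (ri < 0 || ri >= nr) continue;
        int off = pos - starts[ri];  // 0-based offset within ref read
        if (off + k > (int)refs[ri].size()) continue;  // spans separator
        if (query_gid[qi] == ref_gid[ri]) continue;    // self
        long long key = ri;
        if (tried.count(key)) continue;
        tried.insert(key);
        SeedOverlap a = overlap_from_seed(q, refs[ri], p, off, band, buf);
        if (!a.ok) continue;
        int cols = a.cols;
        double ident = cols > 0 ? (double)a.matches / cols : 0.0;
        if (cols >= min_overlap && ident >= min_identity) {
          out_q.push_back(qi + 1);
          out_r.push_back(ri + 1);
          out_len.push_back(cols);
          out_ident.push_back(ident);
          out_type.push_back(a.type);
        }
      }
    }
  }
  return DataFrame::create(_["qi"] = out_q, _["ri"] = out_r,
                           _["overlap_len"] = out_len,
                           _["identity"] = out_ident,
                           _["type"] = out_type);
}

// ---------------------------------------------------------------------------
// Transitive reduction on a weighted undirected graph. An edge (a,c) is
// transitive if some surviving witness b is adjacent to both endpoints with
// w(a,b) >= w(a,c) and w(b,c) >= w(a,c). Edges are examined in ascending
// (weight, u, v) order so that light edges are explained by heavier ones;
// already-removed edges cannot serve as witnesses. Returns a keep mask.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".transitive_reduce_cpp")]]
LogicalVector transitive_reduce_cpp(int n_nodes, IntegerVector u,
                                    IntegerVector v, NumericVector w) {
  int m = u.size();
  std::vector<std::vector<std::pair<int, int>>> adj(n_nodes);  // (nbr, edge)
  for (int e = 0; e < m; ++e) {
    adj[u[e] - 1].push_back({v[e] - 1, e});
    adj[v[e] - 1].push_back({u[e] - 1, e});
  }
  std::vector<int> ord(m);
  for (int e = 0; e < m; ++e) ord[e] = e;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (w[a] != w[b]) return w[a] < w[b];
    if (u[a] != u[b]) return u[a] < u[b];
    return v[a] < v[b];
  });
  std::vector<char> alive(m, 1);
  std::vector<double> wc(n_nodes, -1.0);  // weight of alive edge to c's nbrs
  for (int oi = 0; oi < m; ++oi) {
    int e = ord[oi];
    int a = u[e] - 1, c = v[e] - 1;
    double we = w[e];
    // mark neighbors of c (alive, weight >= we)
    for (auto& pr : adj[c])
      if (alive[pr.second] && w[pr.second] >= we) wc[pr.first] = w[pr.second];
    bool drop = false;
    for (auto& pr : adj[a]) {
      int b = pr.first;
      if (b == c) continue;
      if (alive[pr.second] && w[pr.second] >= we && wc[b] >= 0) {
        drop = true;
        break;
      }
    }
    for (auto& pr : adj[c]) wc[pr.first] = -1.0;
    if (drop) alive[e] = 0;
  }
  LogicalVector keep(m);
  for (int e = 0; e < m; ++e) keep[e] = alive[e] == 1;
  return keep;
}
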