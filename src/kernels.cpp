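#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit DNA encoding; 4 marks an unusable base (N or other).
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

// Canonical k-mer multiplicity histogram. counts[m-1] = number of distinct
// canonical k-mers seen exactly m times; multiplicities above `cap` fall in
// the cap bin. k <= 31 (2-bit packing in 64 bits). k-mers containing a
// non-ACGT base are skipped.
// [[Rcpp::export(name = ".kmer_hist_cpp")]]
NumericVector kmer_hist_cpp(CharacterVector seqs, int k, int cap) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (cap < 1) stop("cap must be >= 1");
  std::unordered_map<uint64_t, uint32_t> tab;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    int n = (int) LENGTH(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bit(str[i]);
      if (b > 3) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
      }
    }
  }
  NumericVector counts(cap);
  for (const auto &kv : tab) {
    int m = (int) kv.second;
    if (m > cap) m = cap;
    counts[m - 1] += 1.0;
  }
  return counts;
}

// ---------------------------------------------------------------------------
// Anchor index: exact k-mer positions on the forward strand of each target.

struct AnchorIndex {
  int k;
  int max_occ;
  std::vector<std::string> names;
  std::vector<int> lens;
  // kmer -> packed (target << 32 | pos); over-represented kmers dropped
  std::unordered_map<uint64_t, std::vector<uint64_t> > pos;
  int dropped_seeds;
};

// [[Rcpp::export(name = ".anchor_index_cpp")]]
SEXP anchor_index_cpp(CharacterVector targets, CharacterVector names,
                      int k, int max_occ) {
  if (k < 1 || k > 31) stop("seed k must be in [1, 31]");
  AnchorIndex *idx = new AnchorIndex();
  idx->k = k;
  idx->max_occ = max_occ;
  idx->dropped_seeds = 0;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (R_xlen_t t = 0; t < targets.size(); ++t) {
    const char *str = CHAR(STRING_ELT(targets, t));
    int n = (int) LENGTH(STRING_ELT(targets, t));
    idx->names.push_back(as<std::string>(names[t]));
    idx->lens.push_back(n);
    uint64_t fwd = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bit(str[i]);
      if (b > 3) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) b) & mask;
      if (++valid >= k)
        idx->pos[fwd].push_back(((uint64_t) t << 32) | (uint64_t)(i - k + 1));
    }
  }
  // enforce max_occ
  if (max_occ > 0) {
    for (auto it = idx->pos.begin(); it != idx->pos.end();) {
      if ((int) it->second.size() > max_occ) {
        ++idx->dropped_seeds;
        it = idx->pos.erase(it);
      } else ++it;
    }
  }
  XPtr<AnchorIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".anchor_index_info_cpp")]]
List anchor_index_info_cpp(SEXP xp) {
  XPtr<AnchorIndex> idx(xp);
  return List::create(_["k"] = idx->k, _["max_occ"] = idx->max_occ,
                      _["targets"] = wrap(idx->names),
                      _["target_lens"] = wrap(idx->lens),
                      _["dropped_seeds"] = idx->dropped_seeds);
}

struct RawMatch { int tid, qpos, tpos; };

static void collect_matches(const AnchorIndex *idx, const std::string &q,
                            std::vector<RawMatch> &out) {
  int k = idx->k, n = (int) q.size();
  if (n < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(q[i]);
    if (b > 3) { valid = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) b) & mask;
    if (++valid >= k) {
      auto it = idx->pos.find(fwd);
      if (it != idx->pos.end()) {
        int qp = i - k + 1;
        for (uint64_t packed : it->second) {
          RawMatch m;
          m.tid = (int)(packed >> 32);
          m.qpos = qp;
          m.tpos = (int)(packed & 0xffffffffULL);
          out.push_back(m);
        }
      }
    }
  }
}

// Query the index with both strands of `query`. Returns a matrix with one
// row per maximal exact-match anchor: (tid [1-based], qpos, tpos, len,
// strand [1 = '+', -1 = '-']). For '-' anchors, qpos is a position in the
// REVERSE COMPLEMENT frame of the query; callers reflect coordinates.
// Matches on the same diagonal that abut by single-base steps are merged
// into maximal runs.
// [[Rcpp::export(name = ".anchor_query_cpp")]]
IntegerMatrix anchor_query_cpp(SEXP xp, std::string query) {
  XPtr<AnchorIndex> idx(xp);
  int k = idx->k;
  std::string rc(query.rbegin(), query.rend());
  for (size_t i = 0; i < rc.size(); ++i) rc[i] = comp_base(rc[i]);

  std::vector<RawMatch> fwd_m, rev_m;
  collect_matches(idx.get(), query, fwd_m);
  collect_matches(idx.get(), rc, rev_m);

  std::vector<int> tid, qp, tp, len, strand;
  for (int pass = 0; pass < 2; ++pass) {
    std::vector<RawMatch> &m = pass == 0 ? fwd_m : rev_m;
    if (m.empty()) continue;
    // group by (tid, diagonal), merge +1 runs
    std::sort(m.begin(), m.end(), [](const RawMatch &a, const RawMatch &b) {
      if (a.tid != b.tid) return a.tid < b.tid;
      int da = a.tpos - a.qpos, db = b.tpos - b.qpos;
      if (da != db) return da < db;
      return a.qpos < b.qpos;
    });
    size_t i = 0;
    while (i < m.size()) {
      size_t j = i + 1;
      while (j < m.size() && m[j].tid == m[i].tid &&
             (m[j].tpos - m[j].qpos) == (m[i].tpos - m[i].qpos) &&
             m[j].qpos == m[j - 1].qpos + 1)
        ++j;
      tid.push_back(m[i].tid + 1);
      qp.push_back(m[i].qpos);
      tp.push_back(m[i].tpos);
      len.push_back(k + (int)(j - i) - 1);
      strand.push_back(pass == 0 ? 1 : -1);
      i = j;
    }
  }
  IntegerMatrix out((int) tid.size(), 5);
  for (size_t i = 0; i < tid.size(); ++i) {
    out(i, 0) = tid[i]; out(i, 1) = qp[i]; out(i, 2) = tp[i];
    out(i, 3) = len[i]; out(i, 4) = strand[i];
  }
  colnames(out) = CharacterVector::create("tid", "qpos", "tpos", "len", "strand");
  return out;
}

// ---------------------------------------------------------------------------
// Anchor chaining. Anchors must be on one (target, strand) pair. Sorts by
// (qpos, tpos) and runs a gap-penalised DP with a bounded look-back window;
// chains are then extracted greedily from the best unused end, ties broken
// toward the lower target coordinate. Returns a list of integer vectors of
// 1-based anchor row indices (in chain order).
// [[Rcpp::export(name = ".chain_anchors_cpp")]]
List chain_anchors_cpp(IntegerVector qpos, IntegerVector tpos, IntegerVector len,
                       int max_gap, double gap_open, double gap_ext,
                       int lookback) {
  int n = qpos.size();
  if (n == 0) return List::create();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (qpos[a] != qpos[b]) return qpos[a] < qpos[b];
    if (tpos[a] != tpos[b]) return tpos[a] < tpos[b];
    return a < b;
  });
  std::vector<double> dp(n);
  std::vector<int> parent(n, -1);
  for (int ii = 0; ii < n; ++ii) {
    int i = ord[ii];
    dp[i] = (double) len[i];
    int lo = std::max(0, ii - lookback);
    for (int jj = ii - 1; jj >= lo; --jj) {
      int j = ord[jj];
      if (qpos[j] >= qpos[i] || tpos[j] >= tpos[i]) continue;
      int qg = qpos[i] - (qpos[j] + len[j]);
      int tg = tpos[i] - (tpos[j] + len[j]);
      if (qg > max_gap || tg > max_gap) continue;
      // overlap must be trimmable from anchor i
      int ov = std::max(-std::min(qg, tg), 0);
      if (ov >= len[i]) continue;
      double cost = 0.0;
      if (qg != 0 || tg != 0)
        cost = gap_open + gap_ext * std::abs(qg - tg) +
               0.05 * std::max(std::min(qg, tg), 0);
      double sc = dp[j] + (double) len[i] - ov - cost;
      if (sc > dp[i] ||
          (sc == dp[i] && parent[i] >= 0 && tpos[j] < tpos[parent[i]])) {
        dp[i] = sc;
        parent[i] = j;
      }
    }
  }
  std::vector<int> ends(n);
  for (int i = 0; i < n; ++i) ends[i] = i;
  std::sort(ends.begin(), ends.end(), [&](int a, int b) {
    if (dp[a] != dp[b]) return dp[a] > dp[b];
    if (tpos[a] != tpos[b]) return tpos[a] < tpos[b];
    return qpos[a] < qpos[b];
  });
  std::vector<char> used(n, 0);
  List chains;
  for (int e : ends) {
    if (used[e]) continue;
    std::vector<int> chain;
    int cur = e;
    while (cur >= 0 && !used[cur]) {
      chain.push_back(cur);
      used[cur] = 1;
      cur = parent[cur];
    }
    std::reverse(chain.begin(), chain.end());
    IntegerVector cv((int) chain.size());
    for (size_t i = 0; i < chain.size(); ++i) cv[i] = chain[i] + 1;
    chains.push_back(cv);
  }
  return chains;
}

// ---------------------------------------------------------------------------
// Banded global (Needleman-Wunsch) alignment of a (query) vs b (target)
// with linear gap penalties; returns operation counts and a CIGAR over
// {=, X, I, D} (I = query-only base, D = target-only base). `band` widens
// a corridor around the main diagonal shifted for the length difference;
// band >= max(len) gives the exact full DP.
// [[Rcpp::export(name = ".banded_nw_cpp")]]
List banded_nw_cpp(std::string a, std::string b, int band,
                   double match = 2.0, double mismatch = -4.0,
                   double gap = -4.0) {
  int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) {
    std::string cig;
    if (n > 0) cig = std::to_string(n) + "I";
    else if (m > 0) cig = std::to_string(m) + "D";
    return List::create(_["matches"] = 0, _["mismatches"] = 0,
                        _["ins"] = n, _["del"] = m, _["cigar"] = cig,
                        _["score"] = gap * (n + m));
  }
  int dlo = std::min(0, m - n) - band;
  int dhi = std::max(0, m - n) + band;
  int w = dhi - dlo + 1;
  const double NEG = -1e18;
  std::vector<double> S((size_t)(n + 1) * w, NEG);
  std::vector<signed char> bt((size_t)(n + 1) * w, 0); // 1=diag 2=up(I) 3=left(D)
  auto IDX = [&](int i, int d) { return (size_t) i * w + (d - dlo); };
  S[IDX(0, 0)] = 0.0;
  for (int j = 1; j <= m && j <= dhi; ++j) {
    S[IDX(0, j)] = gap * j;
    bt[IDX(0, j)] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i + dlo), jhi = std::min(m, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      int d = j - i;
      double best = NEG;
      signed char op = 0;
      if (j >= 1 && d >= dlo && d <= dhi) {
        double sdiag = S[IDX(i - 1, d)];
        if (sdiag > NEG / 2) {
          double sc = sdiag + (a[i - 1] == b[j - 1] ? match : mismatch);
          if (sc > best) { best = sc; op = 1; }
        }
      }
      if (d + 1 <= dhi) { // up: consume a[i-1] (I)
        double sup = S[IDX(i - 1, d + 1)];
        if (sup > NEG / 2 && sup + gap > best) { best = sup + gap; op = 2; }
      }
      if (d - 1 >= dlo && j >= 1) { // left: consume b[j-1] (D)
        double sl = S[IDX(i, d - 1)];
        if (sl > NEG / 2 && sl + gap > best) { best = sl + gap; op = 3; }
      }
      if (op) { S[IDX(i, d)] = best; bt[IDX(i, d)] = op; }
    }
  }
  if (S[IDX(n, m - n)] <= NEG / 2)
    stop("band too narrow for global alignment");
  // traceback
  int i = n, j = m;
  int nmatch = 0, nmis = 0, nins = 0, ndel = 0;
  std::vector<std::pair<char, int> > runs;
  auto push_op = [&](char c) {
    if (!runs.empty() && runs.back().first == c) runs.back().second++;
    else runs.push_back(std::make_pair(c, 1));
  };
  while (i > 0 || j > 0) {
    signed char op = bt[IDX(i, j - i)];
    if (op == 1) {
      if (a[i - 1] == b[j - 1]) { ++nmatch; push_op('='); }
      else { ++nmis; push_op('X'); }
      --i; --j;
    } else if (op == 2) { ++nins; push_op('I'); --i; }
    else if (op == 3) { ++ndel; push_op('D'); --j; }
    else stop("traceback failed");
  }
  std::string cig;
  for (auto it = runs.rbegin(); it != runs.rend(); ++it)
    cig += std::to_string(it->second) + it->first;
  return List::create(_["matches"] = nmatch, _["mismatches"] = nmis,
                      _["ins"] = nins, _["del"] = ndel, _["cigar"] = cig,
                      _["score"] = S[IDX(n, m - n)]);
}
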