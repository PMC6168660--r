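#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Lempel-Ziv 1976 exhaustive-history word count. Each word is the
// shortest prefix of the remaining string that cannot be copied from
// the prior history (self-overlapping sources allowed); the final,
// possibly still-copyable word is counted too.
//
// The longest copyable prefix at position p equals the
// longest-previous-factor LPF[p] = max_{i<p} lcp(s[i..], s[p..]),
// computed from the suffix array + LCP array (Kasai) with the
// decreasing-position deletion scheme, so the whole count is
// O(n log n) instead of the quadratic direct scan.

static void build_sa_lcp(const std::vector<int>& s,
                         std::vector<int>& sa, std::vector<int>& lcp,
                         std::vector<int>& rank_) {
  const int n = (int)s.size();
  sa.resize(n);
  rank_.assign(s.begin(), s.end());
  std::vector<int> tmp(n);
  for (int i = 0; i < n; ++i) sa[i] = i;
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
      int ra = a + k < n ? rank_[a + k] : -1;
      int rb = b + k < n ? rank_[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
  }
  // Kasai
  lcp.assign(n, 0); // lcp[i] = lcp(suffix sa[i-1], suffix sa[i]), lcp[0] = 0
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else h = 0;
  }
}

// [[Rcpp::export(name = ".lz76_count_cpp")]]
int lz76_count_cpp(IntegerVector seq) {
  const int n = seq.size();
  if (n == 0) stop("empty sequence");
  if (n == 1) return 1;
  std::vector<int> s(seq.begin(), seq.end());

  std::vector<int> sa, lcp, rank_;
  build_sa_lcp(s, sa, lcp, rank_);

  // LPF by deleting positions from the suffix-array order in
  // decreasing text order: when position p is removed, its list
  // neighbours hold only positions < p, and the lcp across the gap is
  // the min of the two adjacent lcps.
  std::vector<int> prev(n + 2), nxt(n + 2), lcp_with_prev(n + 2, 0);
  // list nodes 1..n map to sa ranks 0..n-1; 0 and n+1 are sentinels
  for (int i = 0; i <= n + 1; ++i) { prev[i] = i - 1; nxt[i] = i + 1; }
  for (int r = 1; r <= n; ++r) lcp_with_prev[r] = (r == 1) ? 0 : lcp[r - 1];

  std::vector<int> lpf(n, 0);
  for (int p = n - 1; p >= 0; --p) {
    int node = rank_[p] + 1;
    int a = lcp_with_prev[node];                       // lcp with list predecessor
    int b = (nxt[node] <= n) ? lcp_with_prev[nxt[node]] : 0; // with successor
    lpf[p] = std::max(a, b);
    if (nxt[node] <= n + 1)
      lcp_with_prev[nxt[node]] = std::min(a, b);
    nxt[prev[node]] = nxt[node];
    prev[nxt[node]] = prev[node];
  }

  // Greedy exhaustive parsing: each word is the copyable prefix plus
  // one fresh symbol; when the remainder is entirely copyable it forms
  // the final (non-exhaustive) word.
  int count = 0, p = 0;
  while (p < n) {
    int L = lpf[p];
    ++count;
    if (p + L >= n) break;
    p += L + 1;
  }
  return count;
}
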