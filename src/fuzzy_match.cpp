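#include <Rcpp.h>
#include <array>
#include <string>
#include <vector>
using namespace Rcpp;

// Map bytes onto a 28-letter alphabet (a-z, space, other) for the
// character-bag lower bound.
static inline int char_class(unsigned char c) {
  if (c >= 'a' && c <= 'z') return c - 'a';
  if (c >= 'A' && c <= 'Z') return c - 'A';
  if (c == ' ') return 26;
  return 27;
}

static void count_chars(const std::string& s, std::array<short, 28>& out) {
  out.fill(0);
  for (unsigned char c : s) out[char_class(c)]++;
}

// Each unit edit changes the character bag's L1 norm by at most 2, so
// levenshtein(a, b) >= ceil(L1(bag_a, bag_b) / 2). This also dominates the
// length-difference bound.
static inline int bag_lower_bound(const std::array<short, 28>& a,
                                  const std::array<short, 28>& b) {
  int l1 = 0;
  for (int k = 0; k < 28; ++k) l1 += std::abs(a[k] - b[k]);
  return (l1 + 1) / 2;
}

// Banded Levenshtein with unit costs; returns the exact distance when it is
// <= cutoff, otherwise any value > cutoff.
static int banded_levenshtein(const std::string& a, const std::string& b,
                              int cutoff) {
  const int n = a.size(), m = b.size();
  if (std::abs(n - m) > cutoff) return cutoff + 1;
  const int INF = cutoff + 1;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  for (int j = 0; j <= std::min(m, cutoff); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    const int lo = std::max(1, i - cutoff), hi = std::min(m, i + cutoff);
    std::fill(cur.begin(), cur.end(), INF);
    int best = INF;
    if (i <= cutoff) {
      cur[0] = i;
      best = i;
    }
    for (int j = lo; j <= hi; ++j) {
      int c = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      if (prev[j] + 1 < c) c = prev[j] + 1;
      if (cur[j - 1] + 1 < c) c = cur[j - 1] + 1;
      cur[j] = c < INF ? c : INF;
      if (cur[j] < best) best = cur[j];
    }
    if (best >= INF) return INF;
    std::swap(prev, cur);
  }
  return prev[m] < INF ? prev[m] : INF;
}

//' @name best_fuzzy_match
//' @noRd
// [[Rcpp::export(rng = false)]]
List best_fuzzy_match(CharacterVector spans, CharacterVector forms,
                      IntegerVector cutoffs, IntegerVector priority) {
  const int ns = spans.size(), nf = forms.size();
  std::vector<std::string> fs(nf);
  std::vector<std::array<short, 28>> fc(nf);
  int max_cutoff = 0;
  for (int j = 0; j < nf; ++j) {
    fs[j] = as<std::string>(forms[j]);
    count_chars(fs[j], fc[j]);
    if (cutoffs[j] > max_cutoff) max_cutoff = cutoffs[j];
  }
  IntegerVector match_idx(ns, NA_INTEGER), match_dist(ns, NA_INTEGER);
  std::array<short, 28> sc;
  for (int i = 0; i < ns; ++i) {
    const std::string s = as<std::string>(spans[i]);
    count_chars(s, sc);
    int best_d = max_cutoff + 1, best_p = INT_MAX, best_j = -1;
    for (int j = 0; j < nf; ++j) {
      const int allow = cutoffs[j];
      // a candidate only improves if its distance is <= allow and <= best_d
      const int cap = allow < best_d ? allow : best_d;
      if (bag_lower_bound(sc, fc[j]) > cap) continue;
      const int d = banded_levenshtein(s, fs[j], cap);
      if (d > cap) continue;
      if (d < best_d || (d == best_d && priority[j] < best_p)) {
        best_d = d;
        best_p = priority[j];
        best_j = j;
      }
    }
    if (best_j >= 0) {
      match_idx[i] = best_j + 1;
      match_dist[i] = best_d;
    }
  }
  return List::create(_["index"] = match_idx, _["distance"] = match_dist);
}

//' @name select_separated
//' @noRd
// [[Rcpp::export(rng = false)]]
IntegerVector select_separated(CharacterVector pool, int n_needed,
                               int min_sep) {
  const int np = pool.size();
  std::vector<std::string> s(np);
  std::vector<std::array<short, 28>> c(np);
  for (int i = 0; i < np; ++i) {
    s[i] = as<std::string>(pool[i]);
    count_chars(s[i], c[i]);
  }
  std::vector<int> acc;
  acc.reserve(n_needed);
  const int cutoff = min_sep - 1;
  for (int i = 0; i < np && (int)acc.size() < n_needed; ++i) {
    bool ok = true;
    for (int j : acc) {
      if (bag_lower_bound(c[i], c[j]) > cutoff) continue;
      if (banded_levenshtein(s[i], s[j], cutoff) <= cutoff) {
        ok = false;
        break;
      }
    }
    if (ok) acc.push_back(i);
  }
  IntegerVector out(acc.size());
  for (size_t k = 0; k < acc.size(); ++k) out[k] = acc[k] + 1;
  return out;
}

//' @name flag_ambiguous_forms
//' @noRd
// [[Rcpp::export(rng = false)]]
LogicalVector flag_ambiguous_forms(CharacterVector forms, IntegerVector owner,
                                   IntegerVector cutoffs) {
  const int nf = forms.size();
  std::vector<std::string> fs(nf);
  std::vector<std::array<short, 28>> fc(nf);
  for (int j = 0; j < nf; ++j) {
    fs[j] = as<std::string>(forms[j]);
    count_chars(fs[j], fc[j]);
  }
  LogicalVector out(nf, false);
  for (int i = 0; i < nf; ++i) {
    for (int j = i + 1; j < nf; ++j) {
      if (owner[i] == owner[j]) continue;
      const int cap = std::max(cutoffs[i], cutoffs[j]);
      if (bag_lower_bound(fc[i], fc[j]) > cap) continue;
      if (banded_levenshtein(fs[i], fs[j], cap) <= cap) {
        out[i] = true;
        out[j] = true;
      }
    }
  }
  return out;
}
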