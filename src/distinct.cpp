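#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>

using namespace Rcpp;

// Generalized suffix automaton over a set of uppercase strings.  The number
// of distinct substrings of the set is sum over non-root states of
// len(v) - len(link(v)); construction is linear in total input length, so
// counting is subquadratic (the naive hash-set count is the test oracle).

namespace {

struct SAM {
  std::vector<std::array<int, 26>> tr;
  std::vector<int> link, len;

  SAM() { new_node(); link[0] = -1; }

  int new_node() {
    std::array<int, 26> t;
    t.fill(-1);
    tr.push_back(t);
    link.push_back(-1);
    len.push_back(0);
    return (int)tr.size() - 1;
  }

  int clone_of(int q, int l) {
    int c = new_node();
    tr[c] = tr[q];
    link[c] = link[q];
    len[c] = l;
    return c;
  }

  // generalized extension: restart from root for each string, reuse existing
  // transitions, cloning where lengths disagree
  int extend(int last, int c) {
    if (tr[last][c] != -1) {
      int q = tr[last][c];
      if (len[q] == len[last] + 1) return q;
      int cl = clone_of(q, len[last] + 1);
      int p = last;
      while (p != -1 && tr[p][c] == q) { tr[p][c] = cl; p = link[p]; }
      link[q] = cl;
      return cl;
    }
    int cur = new_node();
    len[cur] = len[last] + 1;
    int p = last;
    while (p != -1 && tr[p][c] == -1) { tr[p][c] = cur; p = link[p]; }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = tr[p][c];
      if (len[q] == len[p] + 1) {
        link[cur] = q;
      } else {
        int cl = clone_of(q, len[p] + 1);
        while (p != -1 && tr[p][c] == q) { tr[p][c] = cl; p = link[p]; }
        link[q] = cl;
        link[cur] = cl;
      }
    }
    return cur;
  }
};

}  // namespace

// [[Rcpp::export]]
double cpp_count_distinct(CharacterVector sequences) {
  SAM sam;
  size_t total = 0;
  for (int i = 0; i < sequences.size(); ++i) total += LENGTH(STRING_ELT(sequences, i));
  sam.tr.reserve(2 * total + 4);
  for (int i = 0; i < sequences.size(); ++i) {
    std::string s = as<std::string>(sequences[i]);
    int last = 0;
    for (char ch : s) {
      if (ch < 'A' || ch > 'Z')
        stop("sequences must contain only uppercase letters A-Z");
      last = sam.extend(last, ch - 'A');
    }
  }
  double count = 0;
  for (size_t v = 1; v < sam.tr.size(); ++v)
    count += sam.len[v] - sam.len[sam.link[v]];
  return count;
}

// All (possibly overlapping) occurrences of each pattern in each sequence.
// Coordinates are 0-based half-open [start, end).

// [[Rcpp::export]]
DataFrame cpp_find_occurrences(CharacterVector patterns, CharacterVector sequences) {
  std::vector<int> prot, pat, st, en;
  for (int i = 0; i < sequences.size(); ++i) {
    std::string s = as<std::string>(sequences[i]);
    for (int j = 0; j < patterns.size(); ++j) {
      std::string p = as<std::string>(patterns[j]);
      if (p.empty() || p.size() > s.size()) continue;
      size_t pos = s.find(p, 0);
      while (pos != std::string::npos) {
        prot.push_back(i + 1);
        pat.push_back(j + 1);
        st.push_back((int)pos);
        en.push_back((int)(pos + p.size()));
        pos = s.find(p, pos + 1);
      }
    }
  }
  return DataFrame::create(_["protein"] = prot, _["pattern"] = pat,
                           _["start"] = st, _["end"] = en);
}

// Maximality filter: keep[i] is FALSE when strings[i] is a proper substring
// of another candidate (or a duplicate of an earlier one).  Candidates are
// compared longest-first; containment is only possible in longer strings.

// [[Rcpp::export]]
LogicalVector cpp_maximal_keep(CharacterVector strings) {
  int k = strings.size();
  std::vector<std::string> s(k);
  for (int i = 0; i < k; ++i) s[i] = as<std::string>(strings[i]);
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return s[a].size() > s[b].size();
  });
  LogicalVector keep(k, FALSE);
  std::vector<int> kept;
  for (int idx : ord) {
    bool contained = false;
    for (int j : kept) {
      if (s[j].size() > s[idx].size()) {
        if (s[j].find(s[idx]) != std::string::npos) { contained = true; break; }
      } else if (s[j].size() == s[idx].size() && s[j] == s[idx]) {
        contained = true;  // duplicate: keep first occurrence only
        break;
      }
    }
    if (!contained) { keep[idx] = TRUE; kept.push_back(idx); }
  }
  return keep;
}
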