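#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <memory>
#include <array>
#include "fet.h"

using namespace Rcpp;

// Depth-first traversal of the contiguous-pattern prefix tree.
//
// A node is a pattern q; its occurrence list holds, for every match of q in
// the dataset, the 0-based position immediately after the match ("projected
// database").  A child extends q by one residue on the right; its occurrence
// list is obtained by advancing the parent's occurrences whose next residue
// matches.  Support is document frequency: occurrence lists stay sorted by
// protein, so presence counting is a single linear pass.

struct Occ {
  int prot;  // 0-based protein index
  int pos;   // 0-based position after the match (next extension position)
};

struct Ctx {
  const std::vector<std::string>* seqs;
  int min_support;
  int max_len;  // -1 = unlimited
  long long visited = 0;
  long long pruned = 0;
};

static const int GO = 0, CUT = 1;

template <class V>
static void grow(Ctx& ctx, V& vis, std::string& pat, const std::vector<Occ>& occ) {
  std::array<std::vector<Occ>, 26> buckets;
  for (const Occ& o : occ) {
    const std::string& s = (*ctx.seqs)[o.prot];
    if (o.pos < (int)s.size()) {
      int c = s[o.pos] - 'A';
      buckets[c].push_back(Occ{o.prot, o.pos + 1});
    }
  }
  for (int c = 0; c < 26; ++c) {
    const std::vector<Occ>& b = buckets[c];
    if (b.empty()) continue;
    int d_all = 0, last = -1;
    for (const Occ& o : b)
      if (o.prot != last) { ++d_all; last = o.prot; }
    if (d_all < ctx.min_support) continue;
    pat.push_back((char)('A' + c));
    ++ctx.visited;
    int act = vis.visit(pat, b, d_all, ctx);
    if (act == GO && (ctx.max_len < 0 || (int)pat.size() < ctx.max_len))
      grow(ctx, vis, pat, b);
    pat.pop_back();
  }
}

static std::vector<std::string> as_seqs(const CharacterVector& sequences) {
  std::vector<std::string> seqs(sequences.size());
  for (int i = 0; i < sequences.size(); ++i) {
    seqs[i] = as<std::string>(sequences[i]);
    for (char ch : seqs[i])
      if (ch < 'A' || ch > 'Z')
        stop("sequences must contain only uppercase letters A-Z");
  }
  return seqs;
}

static std::vector<Occ> root_occurrences(const std::vector<std::string>& seqs) {
  std::vector<Occ> occ;
  size_t total = 0;
  for (const std::string& s : seqs) total += s.size();
  occ.reserve(total);
  for (int i = 0; i < (int)seqs.size(); ++i)
    for (int p = 0; p < (int)seqs[i].size(); ++p)
      occ.push_back(Occ{i, p});
  return occ;
}

static void presence_from_occ(const std::vector<Occ>& occ, std::vector<int>& prots) {
  prots.clear();
  int last = -1;
  for (const Occ& o : occ)
    if (o.prot != last) { prots.push_back(o.prot); last = o.prot; }
}

// ---------------------------------------------------------------------------
// Full enumeration with optional R callbacks and optional collection.

struct EnumVisitor {
  const IntegerVector* labels;  // +1 / -1 per protein
  bool collect;
  Function* visitF;
  Function* pruneF;
  std::vector<std::string> pats;
  std::vector<int> v_all, v_pos;
  std::vector<int> prots;

  int visit(const std::string& pat, const std::vector<Occ>& occ, int d_all, Ctx& ctx) {
    presence_from_occ(occ, prots);
    int d_pos = 0;
    for (int p : prots)
      if ((*labels)[p] > 0) ++d_pos;
    if (collect) {
      pats.push_back(pat);
      v_all.push_back(d_all);
      v_pos.push_back(d_pos);
    }
    if (visitF) (*visitF)(pat, d_all, d_pos, d_all - d_pos);
    if (pruneF) {
      LogicalVector r = (*pruneF)(pat, d_all, d_pos, d_all - d_pos);
      if (r.size() >= 1 && r[0] == TRUE) { ++ctx.pruned; return CUT; }
    }
    return GO;
  }
};

// [[Rcpp::export]]
List cpp_enumerate(CharacterVector sequences, IntegerVector labels,
                   int min_support, int max_length, bool collect,
                   Nullable<Function> visit, Nullable<Function> prune) {
  std::vector<std::string> seqs = as_seqs(sequences);
  Ctx ctx{&seqs, min_support, max_length};
  EnumVisitor vis;
  vis.labels = &labels;
  vis.collect = collect;
  std::unique_ptr<Function> vf, pf;
  if (visit.isNotNull()) vf.reset(new Function(visit.get()));
  if (prune.isNotNull()) pf.reset(new Function(prune.get()));
  vis.visitF = vf.get();
  vis.pruneF = pf.get();
  std::string pat;
  grow(ctx, vis, pat, root_occurrences(seqs));
  List out = List::create(
      _["nodes_visited"] = (double)ctx.visited,
      _["nodes_pruned"] = (double)ctx.pruned);
  if (collect) {
    out["pattern"] = wrap(vis.pats);
    out["d_all"] = wrap(vis.v_all);
    out["d_pos"] = wrap(vis.v_pos);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Westfall-Young calibration: per-permutation minimum p-values over all
// patterns with support >= min_support, maintained during one traversal.
// Subtrees are cut when the label-free lower bound exceeds the largest
// running minimum: no descendant can then improve ANY permutation's minimum,
// so the result is exactly the full-enumeration vector.

struct WYVisitor {
  int n, n_pos, n_neg, M, words;
  std::vector<uint64_t> posmask;  // M * words bitset of permuted +1 labels
  std::vector<double> minp;
  double maxmin;
  bool prune;
  std::vector<double> pvcache;  // (n+1)*(n+1), -1 = not computed
  std::vector<uint64_t> pres;

  double pval(int d_all, int a) {
    double& v = pvcache[(size_t)d_all * (n + 1) + a];
    if (v < 0) v = fet_p(n_pos, n_neg, d_all, a);
    return v;
  }

  int visit(const std::string&, const std::vector<Occ>& occ, int d_all, Ctx& ctx) {
    if (prune && fet_plow(n_pos, n_neg, d_all) > maxmin) {
      ++ctx.pruned;
      return CUT;
    }
    std::fill(pres.begin(), pres.end(), (uint64_t)0);
    int last = -1;
    for (const Occ& o : occ)
      if (o.prot != last) {
        pres[o.prot >> 6] |= (uint64_t)1 << (o.prot & 63);
        last = o.prot;
      }
    bool updated = false;
    for (int m = 0; m < M; ++m) {
      const uint64_t* pm = &posmask[(size_t)m * words];
      int a = 0;
      for (int w = 0; w < words; ++w)
        a += __builtin_popcountll(pres[w] & pm[w]);
      double p = pval(d_all, a);
      if (p < minp[m]) { minp[m] = p; updated = true; }
    }
    if (updated) {
      maxmin = 0.0;
      for (double x : minp)
        if (x > maxmin) maxmin = x;
    }
    return GO;
  }
};

// [[Rcpp::export]]
List cpp_wy_minp(CharacterVector sequences, LogicalMatrix pos_matrix,
                 int n_pos, int min_support, bool prune) {
  std::vector<std::string> seqs = as_seqs(sequences);
  int n = (int)seqs.size();
  if (pos_matrix.nrow() != n) stop("permutation matrix must have one row per protein");
  WYVisitor vis;
  vis.n = n;
  vis.n_pos = n_pos;
  vis.n_neg = n - n_pos;
  vis.M = pos_matrix.ncol();
  vis.words = (n + 63) / 64;
  vis.posmask.assign((size_t)vis.M * vis.words, 0);
  for (int m = 0; m < vis.M; ++m)
    for (int i = 0; i < n; ++i)
      if (pos_matrix(i, m))
        vis.posmask[(size_t)m * vis.words + (i >> 6)] |= (uint64_t)1 << (i & 63);
  vis.minp.assign(vis.M, 1.0);
  vis.maxmin = 1.0;
  vis.prune = prune;
  vis.pvcache.assign((size_t)(n + 1) * (n + 1), -1.0);
  vis.pres.assign(vis.words, 0);
  Ctx ctx{&seqs, min_support, -1};
  std::string pat;
  grow(ctx, vis, pat, root_occurrences(seqs));
  return List::create(
      _["min_p"] = wrap(vis.minp),
      _["nodes_visited"] = (double)ctx.visited,
      _["nodes_pruned"] = (double)ctx.pruned);
}

// ---------------------------------------------------------------------------
// Significant-pattern collection at a fixed nominal level delta, pruning
// subtrees whose lower bound exceeds delta.

struct SigVisitor {
  int n_pos, n_neg, M_unused = 0;
  double delta;
  int direction;  // +1 allergen-enriched, -1 nonallergen-enriched
  const IntegerVector* labels;
  std::vector<double> pvcache;
  std::vector<int> prots;

  std::vector<std::string> pats;
  std::vector<int> v_all, v_pos;
  std::vector<double> v_p;
  std::vector<std::vector<int>> v_presence;

  double pval(int d_all, int a) {
    double& v = pvcache[(size_t)d_all * (n_pos + n_neg + 1) + a];
    if (v < 0) v = fet_p(n_pos, n_neg, d_all, a);
    return v;
  }

  int visit(const std::string& pat, const std::vector<Occ>& occ, int d_all, Ctx& ctx) {
    if (fet_plow(n_pos, n_neg, d_all) > delta) { ++ctx.pruned; return CUT; }
    presence_from_occ(occ, prots);
    int d_pos = 0;
    for (int p : prots)
      if ((*labels)[p] > 0) ++d_pos;
    int d_neg = d_all - d_pos;
    bool side = direction > 0
                    ? ((long long)d_pos * n_neg > (long long)d_neg * n_pos)
                    : ((long long)d_neg * n_pos > (long long)d_pos * n_neg);
    if (side) {
      double p = pval(d_all, d_pos);
      if (p < delta) {
        pats.push_back(pat);
        v_all.push_back(d_all);
        v_pos.push_back(d_pos);
        v_p.push_back(p);
        std::vector<int> pr(prots);
        for (int& x : pr) ++x;  // 1-based for R
        v_presence.push_back(std::move(pr));
      }
    }
    return GO;
  }
};

// [[Rcpp::export]]
List cpp_significant(CharacterVector sequences, IntegerVector labels,
                     double delta, int direction, int min_support) {
  std::vector<std::string> seqs = as_seqs(sequences);
  int n = (int)seqs.size();
  SigVisitor vis;
  vis.n_pos = 0;
  for (int i = 0; i < n; ++i)
    if (labels[i] > 0) ++vis.n_pos;
  vis.n_neg = n - vis.n_pos;
  vis.delta = delta;
  vis.direction = direction;
  vis.labels = &labels;
  vis.pvcache.assign((size_t)(n + 1) * (n + 1), -1.0);
  Ctx ctx{&seqs, min_support, -1};
  std::string pat;
  grow(ctx, vis, pat, root_occurrences(seqs));
  List pres(vis.v_presence.size());
  for (size_t i = 0; i < vis.v_presence.size(); ++i)
    pres[i] = wrap(vis.v_presence[i]);
  return List::create(
      _["pattern"] = wrap(vis.pats),
      _["d_all"] = wrap(vis.v_all),
      _["d_pos"] = wrap(vis.v_pos),
      _["p_raw"] = wrap(vis.v_p),
      _["presence"] = pres,
      _["nodes_visited"] = (double)ctx.visited,
      _["nodes_pruned"] = (double)ctx.pruned);
}

// ---------------------------------------------------------------------------
// Scalar helpers exposed for cross-checking the R implementations.

// [[Rcpp::export]]
double cpp_fet_pvalue(int n_pos, int n_neg, int d_all, int d_pos) {
  return fet_p(n_pos, n_neg, d_all, d_pos);
}

// [[Rcpp::export]]
double cpp_hypergeom_g(int n_pos, int n_neg, int d_all, int a) {
  return fet_g(n_pos, n_neg, d_all, a);
}

// [[Rcpp::export]]
double cpp_pvalue_lower_bound(int n_pos, int n_neg, int d_all) {
  return fet_plow(n_pos, n_neg, d_all);
}
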