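// Tree ensemble engines: classification forests (random forest / extremely
// randomised trees, gini or entropy impurity) and binary gradient-boosted
// decision trees with three growth policies (depth-wise, leaf-wise, oblivious)
// over quantile-binned feature histograms. Kept deliberately compact: the
// package targets n in the hundreds-to-thousands range typical of bulk RNA-seq
// cohorts, so exact per-node sorting (forests) and <=64-bin histograms
// (boosting) are fast enough without further engineering.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- utilities

std::vector<int> sample_without_replacement(int n, int k, std::mt19937& rng) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    std::uniform_int_distribution<int> u(i, n - 1);
    std::swap(idx[i], idx[u(rng)]);
  }
  idx.resize(k);
  return idx;
}

// --------------------------------------------------------- forest (RF / ET)

struct FNode {
  int feature = -1;  // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  std::vector<double> prob;  // leaf class distribution
};

double impurity(const std::vector<double>& counts, double total, int criterion) {
  if (total <= 0) return 0.0;
  double imp = 0.0;
  for (double c : counts) {
    if (c <= 0) continue;
    double p = c / total;
    imp += (criterion == 0) ? p * (1.0 - p) : -p * std::log2(p);
  }
  return imp;
}

struct ForestParams {
  int n_class, mtry, min_node, criterion, splitter;
};

void grow_fnode(std::vector<FNode>& nodes, int node_id,
                const NumericMatrix& X, const IntegerVector& y,
                std::vector<int>& idx, const ForestParams& par,
                std::mt19937& rng) {
  FNode& self_ref = nodes[node_id];
  const int n = (int)idx.size();
  std::vector<double> counts(par.n_class, 0.0);
  for (int i : idx) counts[y[i]] += 1.0;
  int n_present = 0;
  for (double c : counts) n_present += (c > 0);

  auto make_leaf = [&](FNode& nd) {
    nd.feature = -1;
    nd.prob.assign(par.n_class, 0.0);
    for (int c = 0; c < par.n_class; ++c) nd.prob[c] = counts[c] / n;
  };

  if (n < par.min_node || n_present <= 1) {
    make_leaf(self_ref);
    return;
  }

  const double parent_imp = impurity(counts, n, par.criterion);
  const int p = X.ncol();
  std::vector<int> feats = sample_without_replacement(p, std::min(par.mtry, p), rng);

  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(n);  // (value, label)
  for (int f : feats) {
    for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
    if (par.splitter == 1) {  // extremely randomised: one uniform threshold
      double lo = vals[0].first, hi = vals[0].first;
      for (auto& v : vals) { lo = std::min(lo, v.first); hi = std::max(hi, v.first); }
      if (hi <= lo) continue;
      std::uniform_real_distribution<double> u(lo, hi);
      double thr = u(rng);
      std::vector<double> lc(par.n_class, 0.0);
      double nl = 0;
      for (auto& v : vals) if (v.first <= thr) { lc[v.second] += 1.0; nl += 1.0; }
      double nr = n - nl;
      if (nl < 1 || nr < 1) continue;
      std::vector<double> rc(par.n_class);
      for (int c = 0; c < par.n_class; ++c) rc[c] = counts[c] - lc[c];
      double gain = parent_imp - (nl / n) * impurity(lc, nl, par.criterion)
                               - (nr / n) * impurity(rc, nr, par.criterion);
      if (gain > best_gain) { best_gain = gain; best_feat = f; best_thr = thr; }
    } else {  // exhaustive best split over sorted boundaries
      std::sort(vals.begin(), vals.end());
      if (vals.front().first >= vals.back().first) continue;
      std::vector<double> lc(par.n_class, 0.0);
      double nl = 0;
      for (int i = 0; i + 1 < n; ++i) {
        lc[vals[i].second] += 1.0;
        nl += 1.0;
        if (vals[i].first >= vals[i + 1].first) continue;  // tie block
        double nr = n - nl;
        std::vector<double> rc(par.n_class);
        for (int c = 0; c < par.n_class; ++c) rc[c] = counts[c] - lc[c];
        double gain = parent_imp - (nl / n) * impurity(lc, nl, par.criterion)
                                 - (nr / n) * impurity(rc, nr, par.criterion);
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
  }

  if (best_feat < 0) {
    make_leaf(self_ref);
    return;
  }

  std::vector<int> lidx, ridx;
  for (int i : idx) (X(i, best_feat) <= best_thr ? lidx : ridx).push_back(i);
  if (lidx.empty() || ridx.empty()) {  // random threshold may degenerate
    make_leaf(self_ref);
    return;
  }
  idx.clear();
  idx.shrink_to_fit();

  nodes[node_id].feature = best_feat;
  nodes[node_id].threshold = best_thr;
  int li = (int)nodes.size();
  nodes.push_back(FNode());
  int ri = (int)nodes.size();
  nodes.push_back(FNode());
  nodes[node_id].left = li;
  nodes[node_id].right = ri;
  grow_fnode(nodes, li, X, y, lidx, par, rng);
  grow_fnode(nodes, ri, X, y, ridx, par, rng);
}

List pack_fnodes(const std::vector<FNode>& nodes, int n_class) {
  int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m);
  NumericMatrix prob(m, n_class);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    if (nodes[i].feature < 0)
      for (int c = 0; c < n_class; ++c) prob(i, c) = nodes[i].prob[c];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["prob"] = prob);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int n_class, int n_trees,
                    int mtry, int min_node, int criterion, int splitter,
                    bool bootstrap, int seed) {
  const int n = X.nrow();
  ForestParams par{n_class, mtry, min_node, criterion, splitter};
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng((unsigned)seed + 0x9E3779B9u * (unsigned)(t + 1));
    std::vector<int> idx(n);
    if (bootstrap) {
      std::uniform_int_distribution<int> u(0, n - 1);
      for (int i = 0; i < n; ++i) idx[i] = u(rng);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    std::vector<FNode> nodes(1);
    grow_fnode(nodes, 0, X, y, idx, par, rng);
    trees[t] = pack_fnodes(nodes, n_class);
  }
  return trees;
}

// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericMatrix cpp_forest_predict(List trees, NumericMatrix X, int n_class) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, n_class);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"];
    NumericMatrix prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (feature[nd] >= 0)
        nd = (X(i, feature[nd]) <= threshold[nd]) ? left[nd] : right[nd];
      for (int c = 0; c < n_class; ++c) out(i, c) += prob(nd, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < n_class; ++c) out(i, c) /= T;
  return out;
}

// ------------------------------------------------------------------- GBDT

namespace {

struct GNode {
  int feature = -1;   // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;  // leaf weight (already shrunk)
};

struct Binned {
  std::vector<std::vector<double>> cuts;  // per feature, ascending cut points
  std::vector<std::vector<int>> bin;      // per feature, per sample bin index
};

// bin(x) = index of first cut >= x; split "bin <= b" <=> "x <= cuts[b]"
int bin_of(const std::vector<double>& cuts, double x) {
  return (int)(std::lower_bound(cuts.begin(), cuts.end(), x) - cuts.begin());
}

Binned make_bins(const NumericMatrix& X, int max_bin) {
  const int n = X.nrow(), p = X.ncol();
  Binned B;
  B.cuts.resize(p);
  B.bin.assign(p, std::vector<int>(n));
  std::vector<double> col(n);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) col[i] = X(i, f);
    std::vector<double> s(col);
    std::sort(s.begin(), s.end());
    std::vector<double>& cuts = B.cuts[f];
    // candidate boundaries between distinct adjacent order statistics at
    // ~equally spaced ranks; all boundaries if few distinct values
    int n_unique = 1;
    for (int i = 1; i < n; ++i) n_unique += (s[i] > s[i - 1]);
    if (n_unique <= max_bin) {
      for (int i = 1; i < n; ++i)
        if (s[i] > s[i - 1]) cuts.push_back(0.5 * (s[i] + s[i - 1]));
    } else {
      for (int b = 1; b < max_bin; ++b) {
        int pos = (int)((double)b * n / max_bin);
        pos = std::min(std::max(pos, 1), n - 1);
        if (s[pos] > s[pos - 1]) cuts.push_back(0.5 * (s[pos] + s[pos - 1]));
      }
      cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
    }
    for (int i = 0; i < n; ++i) B.bin[f][i] = bin_of(cuts, col[i]);
  }
  return B;
}

struct GbdtParams {
  double lr, lambda, min_child_weight;
  int max_depth, max_leaves, growth;  // growth: 0 depth, 1 leaf, 2 oblivious
};

double leaf_score(double G, double H, double lambda) {
  return G * G / (H + lambda);
}

struct Split {
  int feature = -1, bin = -1;
  double gain = 0.0;
};

// best (feature, bin) split for the samples in idx
Split best_split(const std::vector<int>& idx, const Binned& B,
                 const std::vector<int>& feats, const std::vector<double>& g,
                 const std::vector<double>& h, const GbdtParams& par) {
  double G = 0, H = 0;
  for (int i : idx) { G += g[i]; H += h[i]; }
  double parent = leaf_score(G, H, par.lambda);
  Split best;
  std::vector<double> Gb, Hb;
  for (int f : feats) {
    int nb = (int)B.cuts[f].size() + 1;
    if (nb < 2) continue;
    Gb.assign(nb, 0.0);
    Hb.assign(nb, 0.0);
    for (int i : idx) { Gb[B.bin[f][i]] += g[i]; Hb[B.bin[f][i]] += h[i]; }
    double GL = 0, HL = 0;
    for (int b = 0; b + 1 < nb; ++b) {
      GL += Gb[b];
      HL += Hb[b];
      double HR = H - HL, GR = G - GL;
      if (HL < par.min_child_weight || HR < par.min_child_weight) continue;
      double gain = 0.5 * (leaf_score(GL, HL, par.lambda) +
                           leaf_score(GR, HR, par.lambda) - parent);
      if (gain > best.gain + 1e-12) { best.gain = gain; best.feature = f; best.bin = b; }
    }
  }
  return best;
}

double leaf_value(const std::vector<int>& idx, const std::vector<double>& g,
                  const std::vector<double>& h, const GbdtParams& par) {
  double G = 0, H = 0;
  for (int i : idx) { G += g[i]; H += h[i]; }
  return -par.lr * G / (H + par.lambda);
}

void grow_depthwise(std::vector<GNode>& nodes, int node_id, std::vector<int>& idx,
                    int depth, const Binned& B, const std::vector<int>& feats,
                    const std::vector<double>& g, const std::vector<double>& h,
                    const GbdtParams& par) {
  if (depth >= par.max_depth) {
    nodes[node_id].value = leaf_value(idx, g, h, par);
    return;
  }
  Split sp = best_split(idx, B, feats, g, h, par);
  if (sp.feature < 0) {
    nodes[node_id].value = leaf_value(idx, g, h, par);
    return;
  }
  std::vector<int> lidx, ridx;
  for (int i : idx) (B.bin[sp.feature][i] <= sp.bin ? lidx : ridx).push_back(i);
  idx.clear();
  idx.shrink_to_fit();
  nodes[node_id].feature = sp.feature;
  nodes[node_id].threshold = B.cuts[sp.feature][sp.bin];
  int li = (int)nodes.size();
  nodes.push_back(GNode());
  int ri = (int)nodes.size();
  nodes.push_back(GNode());
  nodes[node_id].left = li;
  nodes[node_id].right = ri;
  grow_depthwise(nodes, li, lidx, depth + 1, B, feats, g, h, par);
  grow_depthwise(nodes, ri, ridx, depth + 1, B, feats, g, h, par);
}

void grow_leafwise(std::vector<GNode>& nodes, std::vector<int> root_idx,
                   const Binned& B, const std::vector<int>& feats,
                   const std::vector<double>& g, const std::vector<double>& h,
                   const GbdtParams& par) {
  struct Cand {
    int node;
    std::vector<int> idx;
    Split sp;
  };
  std::vector<Cand> leaves;
  leaves.push_back({0, std::move(root_idx), Split()});
  leaves[0].sp = best_split(leaves[0].idx, B, feats, g, h, par);
  int n_leaves = 1;
  while (n_leaves < par.max_leaves) {
    int best = -1;
    for (int i = 0; i < (int)leaves.size(); ++i)
      if (leaves[i].sp.feature >= 0 &&
          (best < 0 || leaves[i].sp.gain > leaves[best].sp.gain))
        best = i;
    if (best < 0) break;
    Cand cand = std::move(leaves[best]);
    leaves.erase(leaves.begin() + best);
    std::vector<int> lidx, ridx;
    for (int i : cand.idx)
      (B.bin[cand.sp.feature][i] <= cand.sp.bin ? lidx : ridx).push_back(i);
    nodes[cand.node].feature = cand.sp.feature;
    nodes[cand.node].threshold = B.cuts[cand.sp.feature][cand.sp.bin];
    int li = (int)nodes.size();
    nodes.push_back(GNode());
    int ri = (int)nodes.size();
    nodes.push_back(GNode());
    nodes[cand.node].left = li;
    nodes[cand.node].right = ri;
    Cand L{li, std::move(lidx), Split()}, R{ri, std::move(ridx), Split()};
    L.sp = best_split(L.idx, B, feats, g, h, par);
    R.sp = best_split(R.idx, B, feats, g, h, par);
    leaves.push_back(std::move(L));
    leaves.push_back(std::move(R));
    ++n_leaves;
  }
  for (auto& lv : leaves) nodes[lv.node].value = leaf_value(lv.idx, g, h, par);
}

// oblivious (symmetric) tree: one (feature, bin) split shared per level
void grow_oblivious(std::vector<GNode>& nodes, const std::vector<int>& root_idx,
                    const Binned& B, const std::vector<int>& feats,
                    const std::vector<double>& g, const std::vector<double>& h,
                    const GbdtParams& par) {
  std::vector<int> leaf_of(root_idx.size(), 0);  // leaf index per sample
  std::vector<std::pair<int, int>> level_splits;  // (feature, bin)
  int L = 1;
  for (int depth = 0; depth < par.max_depth; ++depth) {
    std::vector<double> Gl(L, 0.0), Hl(L, 0.0);
    for (size_t s = 0; s < root_idx.size(); ++s) {
      Gl[leaf_of[s]] += g[root_idx[s]];
      Hl[leaf_of[s]] += h[root_idx[s]];
    }
    std::vector<int> active;  // only leaves holding samples contribute
    double parent_total = 0;
    for (int l = 0; l < L; ++l) {
      if (Hl[l] > 0) {
        active.push_back(l);
        parent_total += leaf_score(Gl[l], Hl[l], par.lambda);
      }
    }
    const int La = (int)active.size();
    double best_gain = 1e-12;
    int best_f = -1, best_b = -1;
    std::vector<int> slot(L, -1);  // leaf id -> active slot
    for (int a = 0; a < La; ++a) slot[active[a]] = a;
    std::vector<double> Gb, Hb;
    for (int f : feats) {
      int nb = (int)B.cuts[f].size() + 1;
      if (nb < 2) continue;
      Gb.assign((size_t)La * nb, 0.0);
      Hb.assign((size_t)La * nb, 0.0);
      for (size_t s = 0; s < root_idx.size(); ++s) {
        int i = root_idx[s];
        size_t cell = (size_t)slot[leaf_of[s]] * nb + B.bin[f][i];
        Gb[cell] += g[i];
        Hb[cell] += h[i];
      }
      std::vector<double> GL(La, 0.0), HL(La, 0.0);
      for (int b = 0; b + 1 < nb; ++b) {
        double total = 0;
        bool ok = true;
        for (int a = 0; a < La; ++a) {
          GL[a] += Gb[(size_t)a * nb + b];
          HL[a] += Hb[(size_t)a * nb + b];
          double HR = Hl[active[a]] - HL[a];
          if ((HL[a] > 0 && HL[a] < par.min_child_weight) ||
              (HR > 0 && HR < par.min_child_weight)) ok = false;
          total += leaf_score(GL[a], HL[a], par.lambda) +
                   leaf_score(Gl[active[a]] - GL[a], HR, par.lambda);
        }
        double gain = 0.5 * (total - parent_total);
        if (ok && gain > best_gain) { best_gain = gain; best_f = f; best_b = b; }
      }
    }
    if (best_f < 0) break;
    level_splits.push_back({best_f, best_b});
    for (size_t s = 0; s < root_idx.size(); ++s)
      leaf_of[s] = 2 * leaf_of[s] + (B.bin[best_f][root_idx[s]] <= best_b ? 0 : 1);
    L *= 2;
  }
  // leaf values
  std::vector<double> Gl(L, 0.0), Hl(L, 0.0);
  for (size_t s = 0; s < root_idx.size(); ++s) {
    Gl[leaf_of[s]] += g[root_idx[s]];
    Hl[leaf_of[s]] += h[root_idx[s]];
  }
  // unroll the symmetric tree into plain node arrays
  int D = (int)level_splits.size();
  std::function<int(int, int)> build = [&](int depth, int leaf_base) -> int {
    int id = (int)nodes.size();
    nodes.push_back(GNode());
    if (depth == D) {
      nodes[id].value = -par.lr * Gl[leaf_base] / (Hl[leaf_base] + par.lambda);
      return id;
    }
    nodes[id].feature = level_splits[depth].first;
    nodes[id].threshold = B.cuts[level_splits[depth].first][level_splits[depth].second];
    int li = build(depth + 1, 2 * leaf_base);
    int ri = build(depth + 1, 2 * leaf_base + 1);
    nodes[id].left = li;
    nodes[id].right = ri;
    return id;
  };
  build(0, 0);
}

List pack_gnodes(const std::vector<GNode>& nodes) {
  int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["value"] = value);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_gbdt_fit")]]
List cpp_gbdt_fit(NumericMatrix X, NumericVector y, int n_rounds, double lr,
                  int max_depth, int max_leaves, int growth, double lambda,
                  double subsample, double colsample, double min_child_weight,
                  int max_bin, int seed) {
  const int n = X.nrow(), p = X.ncol();
  Binned B = make_bins(X, max_bin);
  GbdtParams par{lr, lambda, min_child_weight, max_depth, max_leaves, growth};

  double ybar = 0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double base = std::log(ybar / (1.0 - ybar));

  std::vector<double> margin(n, base), g(n), h(n);
  List trees(n_rounds);
  for (int t = 0; t < n_rounds; ++t) {
    std::mt19937 rng((unsigned)seed + 0x85EBCA6Bu * (unsigned)(t + 1));
    for (int i = 0; i < n; ++i) {
      double prob = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = prob - y[i];
      h[i] = std::max(prob * (1.0 - prob), 1e-12);
    }
    int n_sub = std::max(2, (int)std::round(subsample * n));
    std::vector<int> rows = (n_sub >= n)
        ? sample_without_replacement(n, n, rng)
        : sample_without_replacement(n, n_sub, rng);
    int p_sub = std::max(1, (int)std::round(colsample * p));
    std::vector<int> feats = sample_without_replacement(p, std::min(p_sub, p), rng);
    std::sort(feats.begin(), feats.end());

    std::vector<GNode> nodes;
    if (growth == 2) {
      grow_oblivious(nodes, rows, B, feats, g, h, par);
    } else {
      nodes.push_back(GNode());
      if (growth == 1)
        grow_leafwise(nodes, rows, B, feats, g, h, par);
      else
        grow_depthwise(nodes, 0, rows, 0, B, feats, g, h, par);
    }
    // update margins on ALL samples with the new tree
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (nodes[nd].feature >= 0)
        nd = (X(i, nodes[nd].feature) <= nodes[nd].threshold) ? nodes[nd].left
                                                              : nodes[nd].right;
      margin[i] += nodes[nd].value;
    }
    trees[t] = pack_gnodes(nodes);
  }
  return List::create(_["trees"] = trees, _["base_score"] = base);
}

// [[Rcpp::export(name = ".cpp_gbdt_predict")]]
NumericVector cpp_gbdt_predict(List model, NumericMatrix X) {
  const int n = X.nrow();
  List trees = model["trees"];
  double base = as<double>(model["base_score"]);
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (feature[nd] >= 0)
        nd = (X(i, feature[nd]) <= threshold[nd]) ? left[nd] : right[nd];
      out[i] += value[nd];
    }
  }
  return out;
}
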