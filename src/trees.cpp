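// CART regression trees plus the two tree ensembles built on them:
// bagged forest (with OOB permutation importance) and least-squares
// gradient boosting (with path-dependent SHAP attribution).
//
// All randomness draws from R's RNG stream so set.seed() on the R side
// makes fits bit-reproducible. X matrices are column-major (R layout),
// no missing values allowed.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;     // -1 => leaf
  std::vector<double> thr;      // split: x <= thr goes left
  std::vector<int> left, right; // child node ids, -1 at leaves
  std::vector<double> value;    // mean of training rows in node
  std::vector<double> cover;    // number of training rows in node

  int push_node(double val, double cov) {
    feature.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    value.push_back(val); cover.push_back(cov);
    return (int)feature.size() - 1;
  }
};

// uniform integer in [0, n) from R's RNG
inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// sample `take` feature indices without replacement from [0, p)
void sample_features(int p, int take, std::vector<int> &pool, std::vector<int> &out) {
  pool.resize(p);
  for (int j = 0; j < p; ++j) pool[j] = j;
  out.clear();
  for (int t = 0; t < take; ++t) {
    int k = t + rand_int(p - t);
    std::swap(pool[t], pool[k]);
    out.push_back(pool[t]);
  }
}

struct BuildCtx {
  const double *X; int n, p;
  const double *y;
  int mtry, min_node, max_depth;
  std::vector<int> pool, cand;
  std::vector<std::pair<double,int>> vals; // (feature value, row)
};

// Depth-first recursive builder over the row subset `rows`.
int build_node(Tree &tr, BuildCtx &c, std::vector<int> &rows, int depth) {
  int m = (int)rows.size();
  double sum = 0.0, sum2 = 0.0;
  for (int i = 0; i < m; ++i) { double v = c.y[rows[i]]; sum += v; sum2 += v * v; }
  double mean = sum / m;
  int node = tr.push_node(mean, (double)m);
  double sse = sum2 - sum * sum / m;
  bool stop = m < c.min_node || sse <= 1e-12 ||
              (c.max_depth > 0 && depth >= c.max_depth);
  if (stop) return node;

  sample_features(c.p, c.mtry, c.pool, c.cand);
  int best_f = -1, best_k = -1;
  double best_gain = 1e-12, best_thr = 0.0;
  for (int fi = 0; fi < (int)c.cand.size(); ++fi) {
    int f = c.cand[fi];
    const double *col = c.X + (size_t)f * c.n;
    c.vals.resize(m);
    for (int i = 0; i < m; ++i) c.vals[i] = std::make_pair(col[rows[i]], rows[i]);
    std::sort(c.vals.begin(), c.vals.end());
    double ls = 0.0;
    for (int k = 0; k < m - 1; ++k) {
      ls += c.y[c.vals[k].second];
      if (c.vals[k].first == c.vals[k + 1].first) continue;
      double rs = sum - ls;
      int nl = k + 1, nr = m - nl;
      double gain = ls * ls / nl + rs * rs / nr - sum * sum / m;
      if (gain > best_gain) {
        best_gain = gain; best_f = f; best_k = k;
        best_thr = 0.5 * (c.vals[k].first + c.vals[k + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  std::vector<int> lrows, rrows;
  const double *col = c.X + (size_t)best_f * c.n;
  lrows.reserve(m); rrows.reserve(m);
  for (int i = 0; i < m; ++i) {
    if (col[rows[i]] <= best_thr) lrows.push_back(rows[i]);
    else rrows.push_back(rows[i]);
  }
  if (lrows.empty() || rrows.empty()) return node; // degenerate threshold
  tr.feature[node] = best_f; tr.thr[node] = best_thr;
  rows.clear(); rows.shrink_to_fit();
  int l = build_node(tr, c, lrows, depth + 1);
  tr.left[node] = l;
  int r = build_node(tr, c, rrows, depth + 1);
  tr.right[node] = r;
  return node;
}

inline double tree_predict_row(const Tree &tr, const double *x) {
  int node = 0;
  while (tr.feature[node] >= 0)
    node = (x[tr.feature[node]] <= tr.thr[node]) ? tr.left[node] : tr.right[node];
  return tr.value[node];
}

List tree_to_list(const Tree &tr) {
  return List::create(
      _["feature"] = wrap(tr.feature), _["thr"] = wrap(tr.thr),
      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
      _["value"] = wrap(tr.value), _["cover"] = wrap(tr.cover));
}

Tree tree_from_list(const List &l) {
  Tree tr;
  tr.feature = as<std::vector<int>>(l["feature"]);
  tr.thr = as<std::vector<double>>(l["thr"]);
  tr.left = as<std::vector<int>>(l["left"]);
  tr.right = as<std::vector<int>>(l["right"]);
  tr.value = as<std::vector<double>>(l["value"]);
  tr.cover = as<std::vector<double>>(l["cover"]);
  return tr;
}

// gather a row of X (column-major) into a contiguous buffer
inline void get_row(const double *X, int n, int p, int i, double *buf) {
  for (int j = 0; j < p; ++j) buf[j] = X[(size_t)j * n + i];
}

} // namespace

// [[Rcpp::export(name = ".cart_fit")]]
List cart_fit(NumericMatrix X, NumericVector y, int mtry, int min_node, int max_depth) {
  BuildCtx c;
  c.X = X.begin(); c.n = X.nrow(); c.p = X.ncol(); c.y = y.begin();
  c.mtry = std::min(std::max(mtry, 1), c.p);
  c.min_node = std::max(min_node, 2); c.max_depth = max_depth;
  std::vector<int> rows(c.n);
  for (int i = 0; i < c.n; ++i) rows[i] = i;
  Tree tr;
  build_node(tr, c, rows, 0);
  return tree_to_list(tr);
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  Tree tr = tree_from_list(tree);
  int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  std::vector<double> buf(p);
  for (int i = 0; i < n; ++i) {
    get_row(X.begin(), n, p, i, buf.data());
    out[i] = tree_predict_row(tr, buf.data());
  }
  return out;
}

// Bagged forest. Returns trees plus per-tree in-bag counts so OOB
// statistics can be recomputed; importance is the mean increase in OOB
// MSE when a predictor is permuted (the %IncMSE idea, unscaled).
// [[Rcpp::export(name = ".forest_fit")]]
List forest_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, int max_depth) {
  int n = X.nrow(), p = X.ncol();
  BuildCtx c;
  c.X = X.begin(); c.n = n; c.p = p; c.y = y.begin();
  c.mtry = std::min(std::max(mtry, 1), p);
  c.min_node = std::max(min_node, 2); c.max_depth = max_depth;

  std::vector<Tree> trees(ntree);
  IntegerMatrix inbag(n, ntree);
  std::vector<double> buf(p);

  // OOB accumulation for baseline predictions
  NumericVector oob_sum(n); IntegerVector oob_cnt(n);
  // per-variable permuted-error accumulators
  NumericVector imp(p); IntegerVector imp_cnt(p);
  std::vector<int> oob_rows; std::vector<int> perm;

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int k = rand_int(n);
      rows[i] = k;
      inbag(k, t) += 1;
    }
    build_node(trees[t], c, rows, 0);

    oob_rows.clear();
    for (int i = 0; i < n; ++i) if (inbag(i, t) == 0) oob_rows.push_back(i);
    if (oob_rows.empty()) continue;
    double err0 = 0.0;
    for (size_t k = 0; k < oob_rows.size(); ++k) {
      int i = oob_rows[k];
      get_row(X.begin(), n, p, i, buf.data());
      double pr = tree_predict_row(trees[t], buf.data());
      oob_sum[i] += pr; oob_cnt[i] += 1;
      double d = pr - y[i]; err0 += d * d;
    }
    err0 /= oob_rows.size();
    // permutation importance on this tree's OOB sample
    int no = (int)oob_rows.size();
    perm.resize(no);
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < no; ++k) perm[k] = k;
      for (int k = no - 1; k > 0; --k) std::swap(perm[k], perm[rand_int(k + 1)]);
      double errp = 0.0;
      for (int k = 0; k < no; ++k) {
        int i = oob_rows[k];
        get_row(X.begin(), n, p, i, buf.data());
        buf[j] = X((size_t)oob_rows[perm[k]], j);
        double d = tree_predict_row(trees[t], buf.data()) - y[i];
        errp += d * d;
      }
      errp /= no;
      imp[j] += errp - err0; imp_cnt[j] += 1;
    }
  }
  for (int j = 0; j < p; ++j) if (imp_cnt[j] > 0) imp[j] /= imp_cnt[j];

  List tl(ntree);
  for (int t = 0; t < ntree; ++t) tl[t] = tree_to_list(trees[t]);
  NumericVector oob_pred(n);
  for (int i = 0; i < n; ++i)
    oob_pred[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;
  return List::create(_["trees"] = tl, _["importance"] = imp,
                      _["oob_pred"] = oob_pred, _["inbag"] = inbag);
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List trees, NumericMatrix X) {
  int ntree = trees.size(), n = X.nrow(), p = X.ncol();
  std::vector<Tree> tr(ntree);
  for (int t = 0; t < ntree; ++t) tr[t] = tree_from_list(trees[t]);
  NumericVector out(n);
  std::vector<double> buf(p);
  for (int i = 0; i < n; ++i) {
    get_row(X.begin(), n, p, i, buf.data());
    double s = 0.0;
    for (int t = 0; t < ntree; ++t) s += tree_predict_row(tr[t], buf.data());
    out[i] = s / ntree;
  }
  return out;
}

// Least-squares gradient boosting: each round fits a depth-limited tree
// to the current residuals; trees enter the model scaled by `eta`.
// [[Rcpp::export(name = ".gbt_fit")]]
List gbt_fit(NumericMatrix X, NumericVector y, int nrounds, double eta,
             int max_depth, int min_node, double subsample) {
  int n = X.nrow(), p = X.ncol();
  double init = mean(y);
  std::vector<double> F(n, init), resid(n);
  BuildCtx c;
  c.X = X.begin(); c.n = n; c.p = p;
  c.mtry = p; c.min_node = std::max(min_node, 2); c.max_depth = max_depth;
  std::vector<Tree> trees(nrounds);
  std::vector<double> buf(p);
  std::vector<int> allrows(n), rows;
  for (int i = 0; i < n; ++i) allrows[i] = i;

  for (int m = 0; m < nrounds; ++m) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - F[i];
    c.y = resid.data();
    if (subsample < 1.0) {
      int take = std::max(2, (int)std::floor(subsample * n));
      for (int k = 0; k < take; ++k) {
        int j = k + rand_int(n - k);
        std::swap(allrows[k], allrows[j]);
      }
      rows.assign(allrows.begin(), allrows.begin() + take);
    } else rows = allrows;
    build_node(trees[m], c, rows, 0);
    for (int i = 0; i < n; ++i) {
      get_row(X.begin(), n, p, i, buf.data());
      F[i] += eta * tree_predict_row(trees[m], buf.data());
    }
  }
  List tl(nrounds);
  for (int m = 0; m < nrounds; ++m) tl[m] = tree_to_list(trees[m]);
  return List::create(_["trees"] = tl, _["init"] = init, _["eta"] = eta);
}

// [[Rcpp::export(name = ".gbt_predict")]]
NumericVector gbt_predict(List model, NumericMatrix X) {
  List tl = model["trees"];
  double init = as<double>(model["init"]), eta = as<double>(model["eta"]);
  int ntree = tl.size(), n = X.nrow(), p = X.ncol();
  std::vector<Tree> tr(ntree);
  for (int t = 0; t < ntree; ++t) tr[t] = tree_from_list(tl[t]);
  NumericVector out(n, init);
  std::vector<double> buf(p);
  for (int i = 0; i < n; ++i) {
    get_row(X.begin(), n, p, i, buf.data());
    for (int t = 0; t < ntree; ++t) out[i] += eta * tree_predict_row(tr[t], buf.data());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Path-dependent TreeSHAP (the EXTEND/UNWIND recursion). phi for one tree
// sums to tree(x) minus the cover-weighted root mean; summing over boosted
// trees (times eta) gives exact local attributions for the additive model.
namespace {

struct PathElement {
  int feature_index;
  double zero_fraction, one_fraction, pweight;
};

void extend_path(PathElement *up, int depth, double zf, double of, int fi) {
  up[depth].feature_index = fi;
  up[depth].zero_fraction = zf;
  up[depth].one_fraction = of;
  up[depth].pweight = depth == 0 ? 1.0 : 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    up[i + 1].pweight += of * up[i].pweight * (i + 1) / (double)(depth + 1);
    up[i].pweight = zf * up[i].pweight * (depth - i) / (double)(depth + 1);
  }
}

void unwind_path(PathElement *up, int depth, int pi) {
  double of = up[pi].one_fraction, zf = up[pi].zero_fraction;
  double next_one = up[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (of != 0) {
      double tmp = up[i].pweight;
      up[i].pweight = next_one * (depth + 1) / (double)((i + 1) * of);
      next_one = tmp - up[i].pweight * zf * (depth - i) / (double)(depth + 1);
    } else {
      up[i].pweight = up[i].pweight * (depth + 1) / (double)(zf * (depth - i));
    }
  }
  for (int i = pi; i < depth; ++i) {
    up[i].feature_index = up[i + 1].feature_index;
    up[i].zero_fraction = up[i + 1].zero_fraction;
    up[i].one_fraction = up[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement *up, int depth, int pi) {
  double of = up[pi].one_fraction, zf = up[pi].zero_fraction;
  double next_one = up[depth].pweight, total = 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    if (of != 0) {
      double tmp = next_one * (depth + 1) / (double)((i + 1) * of);
      total += tmp;
      next_one = up[i].pweight - tmp * zf * (depth - i) / (double)(depth + 1);
    } else {
      total += (up[i].pweight / zf) * (depth + 1) / (double)(depth - i);
    }
  }
  return total;
}

void shap_recurse(const Tree &tr, const double *x, double *phi, int node,
                  int depth, PathElement *parent_path,
                  double pzf, double pof, int pfi) {
  PathElement *up = parent_path + depth + 1;
  std::copy(parent_path, parent_path + depth + 1, up);
  extend_path(up, depth, pzf, pof, pfi);

  if (tr.feature[node] < 0) {
    for (int i = 1; i <= depth; ++i) {
      double w = unwound_path_sum(up, depth, i);
      const PathElement &el = up[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) * tr.value[node];
    }
    return;
  }
  int f = tr.feature[node];
  int hot = (x[f] <= tr.thr[node]) ? tr.left[node] : tr.right[node];
  int cold = (hot == tr.left[node]) ? tr.right[node] : tr.left[node];
  double w = tr.cover[node];
  double hot_zf = tr.cover[hot] / w, cold_zf = tr.cover[cold] / w;
  double izf = 1.0, iof = 1.0;
  int pi = 0;
  for (; pi <= depth; ++pi) if (up[pi].feature_index == f) break;
  if (pi != depth + 1) {
    izf = up[pi].zero_fraction; iof = up[pi].one_fraction;
    unwind_path(up, depth, pi);
    depth -= 1;
  }
  shap_recurse(tr, x, phi, hot, depth + 1, up, hot_zf * izf, iof, f);
  shap_recurse(tr, x, phi, cold, depth + 1, up, cold_zf * izf, 0.0, f);
}

int tree_max_depth(const Tree &tr, int node, int d) {
  if (tr.feature[node] < 0) return d;
  return std::max(tree_max_depth(tr, tr.left[node], d + 1),
                  tree_max_depth(tr, tr.right[node], d + 1));
}

void tree_shap_matrix(const Tree &tr, const double *X, int n, int p,
                      double scale, double *phi /* n x p, col-major */) {
  int d = tree_max_depth(tr, 0, 0) + 2;
  std::vector<PathElement> path((size_t)(d + 1) * (d + 1));
  std::vector<double> buf(p), ph(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) buf[j] = X[(size_t)j * n + i];
    std::fill(ph.begin(), ph.end(), 0.0);
    shap_recurse(tr, buf.data(), ph.data(), 0, 0, path.data(), 1.0, 1.0, -1);
    for (int j = 0; j < p; ++j) phi[(size_t)j * n + i] += scale * ph[j];
  }
}

} // namespace

// SHAP matrix for a single CART tree (used by the test oracle harness).
// [[Rcpp::export(name = ".cart_shap")]]
NumericMatrix cart_shap(List tree, NumericMatrix X) {
  Tree tr = tree_from_list(tree);
  int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  tree_shap_matrix(tr, X.begin(), n, p, 1.0, phi.begin());
  return phi;
}

// SHAP matrix for a boosted model: sum of per-tree SHAP times eta.
// Row sums + (init + eta * sum of root means) equal the model prediction.
// [[Rcpp::export(name = ".gbt_shap")]]
NumericMatrix gbt_shap(List model, NumericMatrix X) {
  List tl = model["trees"];
  double eta = as<double>(model["eta"]);
  int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  for (int t = 0; t < tl.size(); ++t) {
    Tree tr = tree_from_list(tl[t]);
    tree_shap_matrix(tr, X.begin(), n, p, eta, phi.begin());
  }
  return phi;
}
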