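#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>

using namespace Rcpp;

// Gradient-boosted decision trees with second-order (Newton) boosting on
// the logistic loss, exact greedy split finding and the standard
// regularization surface: eta, gamma (min split gain), lambda (L2), alpha
// (L1), max_depth, min_child_weight (on the hessian sum), subsample (rows
// per tree) and colsample_bytree. No bundled boosting library exists in
// the target environment, so the booster is implemented here; it follows
// the canonical split-gain and leaf-weight formulas:
//   gain = 1/2 [ GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda) ] - gamma
//   w    = -T(G, alpha) / (H + lambda),  T = L1 soft threshold
// Leaf outputs are stored with eta already applied.

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value;  // leaf output (eta applied)
  std::vector<double> gain;   // split gain, 0 for leaves
};

static inline double soft_threshold(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

struct Builder {
  const NumericMatrix& X;
  const std::vector<std::vector<int> >& order;  // presorted row order per col
  const std::vector<double>& grad;
  const std::vector<double>& hess;
  std::vector<int> node_of;   // node id per row, -1 = not in this tree
  const std::vector<int>& cols;
  double lambda, alpha, gamma, eta, min_child_weight;
  int max_depth;
  Tree tree;

  Builder(const NumericMatrix& X_, const std::vector<std::vector<int> >& order_,
          const std::vector<double>& g_, const std::vector<double>& h_,
          const std::vector<int>& cols_)
      : X(X_), order(order_), grad(g_), hess(h_), cols(cols_) {}

  double leaf_weight(double G, double H) const {
    return -soft_threshold(G, alpha) / (H + lambda);
  }

  int new_node() {
    tree.feat.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(0.0);
    tree.gain.push_back(0.0);
    return (int)tree.feat.size() - 1;
  }

  // rows: indices belonging to this node; id: its node index in the tree
  void build(std::vector<int>& rows, int id, int depth) {
    double G = 0.0, H = 0.0;
    for (size_t r = 0; r < rows.size(); ++r) {
      G += grad[rows[r]];
      H += hess[rows[r]];
    }
    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    double parent_score = soft_threshold(G, alpha) * soft_threshold(G, alpha) / (H + lambda);

    if (depth < max_depth && rows.size() >= 2) {
      for (size_t ci = 0; ci < cols.size(); ++ci) {
        int f = cols[ci];
        const std::vector<int>& ord = order[f];
        double GL = 0.0, HL = 0.0;
        double prev_val = 0.0;
        bool have_prev = false;
        for (size_t k = 0; k < ord.size(); ++k) {
          int r = ord[k];
          if (node_of[r] != id) continue;
          double v = X(r, f);
          if (have_prev && v > prev_val) {
            double GR = G - GL, HR = H - HL;
            if (HL >= min_child_weight && HR >= min_child_weight) {
              double sl = soft_threshold(GL, alpha), sr = soft_threshold(GR, alpha);
              double gain = 0.5 * (sl * sl / (HL + lambda) + sr * sr / (HR + lambda)
                                   - parent_score) - gamma;
              if (gain > best_gain + 1e-12) {
                best_gain = gain;
                best_feat = f;
                best_thr = 0.5 * (prev_val + v);
              }
            }
          }
          GL += grad[r];
          HL += hess[r];
          prev_val = v;
          have_prev = true;
        }
      }
    }

    if (best_feat < 0) {
      tree.value[id] = eta * leaf_weight(G, H);
      return;
    }

    tree.feat[id] = best_feat;
    tree.thr[id] = best_thr;
    tree.gain[id] = best_gain;
    int lid = new_node(), rid = new_node();
    tree.left[id] = lid;
    tree.right[id] = rid;

    std::vector<int> lrows, rrows;
    lrows.reserve(rows.size());
    rrows.reserve(rows.size());
    for (size_t r = 0; r < rows.size(); ++r) {
      int row = rows[r];
      if (X(row, best_feat) < best_thr) {
        node_of[row] = lid;
        lrows.push_back(row);
      } else {
        node_of[row] = rid;
        rrows.push_back(row);
      }
    }
    rows.clear();
    rows.shrink_to_fit();
    build(lrows, lid, depth + 1);
    build(rrows, rid, depth + 1);
  }
};

static double tree_predict_row(const IntegerVector& feat, const NumericVector& thr,
                               const IntegerVector& left, const IntegerVector& right,
                               const NumericVector& value,
                               const NumericMatrix& X, int row) {
  int node = 0;
  while (feat[node] >= 0) {
    node = (X(row, feat[node]) < thr[node]) ? left[node] : right[node];
  }
  return value[node];
}

// [[Rcpp::export]]
List boost_train_cpp(NumericMatrix X, NumericVector y, List params) {
  const int n = X.nrow(), p = X.ncol();
  const double eta = as<double>(params["eta"]);
  const double gamma = as<double>(params["gamma"]);
  const double lambda = as<double>(params["lambda"]);
  const double alpha = as<double>(params["alpha"]);
  const int max_depth = as<int>(params["max_depth"]);
  const double min_child_weight = as<double>(params["min_child_weight"]);
  const double subsample = as<double>(params["subsample"]);
  const double colsample = as<double>(params["colsample_bytree"]);
  const int nrounds = as<int>(params["nrounds"]);
  const double base_score = as<double>(params["base_score"]);
  const unsigned int seed = (unsigned int)as<double>(params["seed"]);
  const double spw = as<double>(params["scale_pos_weight"]);

  std::mt19937 rng(seed);

  // presort row order per column (stable ties)
  std::vector<std::vector<int> > order(p);
  for (int f = 0; f < p; ++f) {
    order[f].resize(n);
    for (int r = 0; r < n; ++r) order[f][r] = r;
    const int ff = f;
    std::stable_sort(order[f].begin(), order[f].end(),
                     [&X, ff](int a, int b) { return X(a, ff) < X(b, ff); });
  }

  const double base_margin = std::log(base_score / (1.0 - base_score));
  std::vector<double> margin(n, base_margin);
  std::vector<double> grad(n), hess(n);

  List trees(nrounds);
  const int nsub = std::max(2, (int)std::floor(subsample * n + 1e-9));
  const int psub = std::max(1, (int)std::floor(colsample * p + 1e-9));
  std::vector<int> all_rows(n), all_cols(p);
  for (int r = 0; r < n; ++r) all_rows[r] = r;
  for (int f = 0; f < p; ++f) all_cols[f] = f;

  for (int round = 0; round < nrounds; ++round) {
    for (int r = 0; r < n; ++r) {
      double pr = 1.0 / (1.0 + std::exp(-margin[r]));
      double w = (y[r] > 0.5) ? spw : 1.0;
      grad[r] = w * (pr - y[r]);
      hess[r] = w * std::max(pr * (1.0 - pr), 1e-16);
    }

    std::vector<int> rows = all_rows;
    if (nsub < n) {
      std::shuffle(rows.begin(), rows.end(), rng);
      rows.resize(nsub);
      std::sort(rows.begin(), rows.end());
    }
    std::vector<int> cols = all_cols;
    if (psub < p) {
      std::shuffle(cols.begin(), cols.end(), rng);
      cols.resize(psub);
      std::sort(cols.begin(), cols.end());
    }

    Builder b(X, order, grad, hess, cols);
    b.lambda = lambda;
    b.alpha = alpha;
    b.gamma = gamma;
    b.eta = eta;
    b.min_child_weight = min_child_weight;
    b.max_depth = max_depth;
    b.node_of.assign(n, -1);
    int root = b.new_node();
    for (size_t r = 0; r < rows.size(); ++r) b.node_of[rows[r]] = root;
    std::vector<int> rows_copy = rows;
    b.build(rows_copy, root, 0);

    List tr = List::create(
        _["feat"] = IntegerVector(b.tree.feat.begin(), b.tree.feat.end()),
        _["thr"] = NumericVector(b.tree.thr.begin(), b.tree.thr.end()),
        _["left"] = IntegerVector(b.tree.left.begin(), b.tree.left.end()),
        _["right"] = IntegerVector(b.tree.right.begin(), b.tree.right.end()),
        _["value"] = NumericVector(b.tree.value.begin(), b.tree.value.end()),
        _["gain"] = NumericVector(b.tree.gain.begin(), b.tree.gain.end()));
    trees[round] = tr;

    IntegerVector tf = tr["feat"], tl = tr["left"], trr = tr["right"];
    NumericVector tt = tr["thr"], tv = tr["value"];
    for (int r = 0; r < n; ++r)
      margin[r] += tree_predict_row(tf, tt, tl, trr, tv, X, r);
  }

  return List::create(_["trees"] = trees, _["base_margin"] = base_margin);
}

// [[Rcpp::export]]
NumericVector boost_predict_cpp(List trees, NumericMatrix X, double base_margin) {
  const int n = X.nrow();
  NumericVector out(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector tf = tr["feat"], tl = tr["left"], trr = tr["right"];
    NumericVector tt = tr["thr"], tv = tr["value"];
    for (int r = 0; r < n; ++r)
      out[r] += tree_predict_row(tf, tt, tl, trr, tv, X, r);
  }
  for (int r = 0; r < n; ++r) out[r] = 1.0 / (1.0 + std::exp(-out[r]));
  return out;
}
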