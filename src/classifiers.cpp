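// Compiled learners: an SMO solver for the soft-margin RBF SVM dual, and a
// second-order softmax gradient-boosted tree ensemble (exact greedy splits,
// shrinkage, row subsampling). Both are deterministic: the SMO is
// derandomized (maximal-violating-pair selection) and the booster uses a
// seeded Mersenne Twister for subsampling.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- SVM (SMO)

// Solve: min 0.5 a'Qa - e'a, 0 <= a <= C, y'a = 0, with Q_ij = y_i y_j K_ij.
// Maximal-violating-pair working-set selection, stopping at gap < eps.
// [[Rcpp::export]]
List svm_smo_cpp(NumericMatrix K, IntegerVector y, double C,
                 double eps = 1e-3, int max_iter = 200000) {
  const int n = y.size();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double tau = 1e-12;

  for (int iter = 0; iter < max_iter; ++iter) {
    // select i in I_up maximizing -y G, j in I_low minimizing -y G
    int i = -1, j = -1;
    double m_up = -std::numeric_limits<double>::infinity();
    double m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool in_low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      double val = -y[t] * G[t];
      if (in_up && val > m_up) { m_up = val; i = t; }
      if (in_low && val < m_low) { m_low = val; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;

    double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = tau;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = tau;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }
    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
  }

  // intercept: mean over free SVs of y_i - g_i, else midpoint of bounds
  double b_sum = 0; int n_free = 0;
  double lb = -std::numeric_limits<double>::infinity();
  double ub = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    double gi = 0;
    for (int k = 0; k < n; ++k) gi += alpha[k] * y[k] * K(i, k);
    double bi = y[i] - gi;
    if (alpha[i] > 1e-10 && alpha[i] < C - 1e-10) { b_sum += bi; ++n_free; }
    else if ((alpha[i] <= 1e-10 && y[i] == 1) || (alpha[i] >= C - 1e-10 && y[i] == -1)) {
      lb = std::max(lb, bi);
    } else {
      ub = std::min(ub, bi);
    }
  }
  double b;
  if (n_free > 0) b = b_sum / n_free;
  else if (std::isfinite(lb) && std::isfinite(ub)) b = (lb + ub) / 2.0;
  else if (std::isfinite(lb)) b = lb;
  else b = std::isfinite(ub) ? ub : 0.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b);
}

// ------------------------------------------------- gradient-boosted trees

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> thresh, value;
};

static double tree_predict_row(const Tree& tr, const NumericMatrix& X, int row) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    node = (X(row, tr.feature[node]) < tr.thresh[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

// Exact greedy depth-wise tree on (g, h) over the sampled rows.
static Tree build_tree(const NumericMatrix& X,
                       const std::vector<std::vector<int>>& sorted_idx,
                       const std::vector<double>& g, const std::vector<double>& h,
                       const std::vector<char>& sampled,
                       int max_depth, double lambda, double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  Tree tr;
  std::vector<int> node_of(n, -1);
  std::vector<double> node_G, node_H;
  double G0 = 0, H0 = 0;
  for (int i = 0; i < n; ++i) if (sampled[i]) { node_of[i] = 0; G0 += g[i]; H0 += h[i]; }
  tr.feature.push_back(-1); tr.left.push_back(-1); tr.right.push_back(-1);
  tr.thresh.push_back(0); tr.value.push_back(0);
  node_G.push_back(G0); node_H.push_back(H0);
  std::vector<int> active{0};

  for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
    int n_nodes = tr.feature.size();
    std::vector<double> best_gain(n_nodes, 0.0), best_thresh(n_nodes, 0.0);
    std::vector<int> best_feat(n_nodes, -1);
    std::vector<char> is_active(n_nodes, 0);
    for (int nd : active) is_active[nd] = 1;

    std::vector<double> GL(n_nodes), HL(n_nodes), lastval(n_nodes);
    std::vector<int> cntL(n_nodes);
    for (int f = 0; f < p; ++f) {
      std::fill(GL.begin(), GL.end(), 0.0);
      std::fill(HL.begin(), HL.end(), 0.0);
      std::fill(cntL.begin(), cntL.end(), 0);
      for (int idx : sorted_idx[f]) {
        int nd = node_of[idx];
        if (nd < 0 || !is_active[nd]) continue;
        double v = X(idx, f);
        if (cntL[nd] > 0 && v > lastval[nd] + 1e-12) {
          double GR = node_G[nd] - GL[nd], HR = node_H[nd] - HL[nd];
          if (HL[nd] >= min_child_weight && HR >= min_child_weight) {
            double gain = GL[nd] * GL[nd] / (HL[nd] + lambda)
                        + GR * GR / (HR + lambda)
                        - node_G[nd] * node_G[nd] / (node_H[nd] + lambda);
            if (gain > best_gain[nd] + 1e-12) {
              best_gain[nd] = gain;
              best_feat[nd] = f;
              best_thresh[nd] = 0.5 * (lastval[nd] + v);
            }
          }
        }
        GL[nd] += g[idx]; HL[nd] += h[idx]; ++cntL[nd]; lastval[nd] = v;
      }
    }

    std::vector<int> next_active;
    std::vector<int> remap_left(n_nodes, -1), remap_right(n_nodes, -1);
    for (int nd : active) {
      if (best_feat[nd] < 0) {
        tr.value[nd] = -node_G[nd] / (node_H[nd] + lambda);
        continue;
      }
      int li = tr.feature.size();
      tr.feature[nd] = best_feat[nd];
      tr.thresh[nd] = best_thresh[nd];
      tr.left[nd] = li; tr.right[nd] = li + 1;
      for (int c = 0; c < 2; ++c) {
        tr.feature.push_back(-1); tr.left.push_back(-1); tr.right.push_back(-1);
        tr.thresh.push_back(0); tr.value.push_back(0);
        node_G.push_back(0); node_H.push_back(0);
      }
      remap_left[nd] = li; remap_right[nd] = li + 1;
      next_active.push_back(li); next_active.push_back(li + 1);
    }
    for (int i = 0; i < n; ++i) {
      int nd = node_of[i];
      if (nd < 0 || nd >= n_nodes || remap_left[nd] < 0) continue;
      int child = (X(i, tr.feature[nd]) < tr.thresh[nd]) ? remap_left[nd] : remap_right[nd];
      node_of[i] = child;
      node_G[child] += g[i]; node_H[child] += h[i];
    }
    active = std::move(next_active);
  }
  for (int nd : active) {  // nodes still open at max depth become leaves
    tr.value[nd] = -node_G[nd] / (node_H[nd] + lambda);
  }
  return tr;
}

static List tree_to_list(const Tree& tr) {
  return List::create(
      _["feature"] = IntegerVector(tr.feature.begin(), tr.feature.end()),
      _["thresh"] = NumericVector(tr.thresh.begin(), tr.thresh.end()),
      _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
      _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
      _["value"] = NumericVector(tr.value.begin(), tr.value.end()));
}

static Tree tree_from_list(const List& l) {
  Tree tr;
  IntegerVector f = l["feature"], le = l["left"], ri = l["right"];
  NumericVector th = l["thresh"], va = l["value"];
  tr.feature.assign(f.begin(), f.end());
  tr.left.assign(le.begin(), le.end());
  tr.right.assign(ri.begin(), ri.end());
  tr.thresh.assign(th.begin(), th.end());
  tr.value.assign(va.begin(), va.end());
  return tr;
}

// [[Rcpp::export]]
List gbt_train_cpp(NumericMatrix X, IntegerVector y, int n_class, int n_rounds,
                   double eta, int max_depth, double subsample,
                   double lambda, double min_child_weight, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int>> sorted_idx(p);
  for (int f = 0; f < p; ++f) {
    sorted_idx[f].resize(n);
    for (int i = 0; i < n; ++i) sorted_idx[f][i] = i;
    std::stable_sort(sorted_idx[f].begin(), sorted_idx[f].end(),
                     [&](int a, int b) { return X(a, f) < X(b, f); });
  }

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<std::vector<double>> F(n_class, std::vector<double>(n, 0.0));
  std::vector<double> g(n), h(n), prob(n_class);
  List trees(n_rounds * n_class);

  for (int r = 0; r < n_rounds; ++r) {
    // one shared subsample per boosting round
    std::vector<char> sampled(n, 1);
    if (subsample < 1.0) {
      std::vector<int> perm(n);
      for (int i = 0; i < n; ++i) perm[i] = i;
      std::shuffle(perm.begin(), perm.end(), rng);
      int keep = std::max(1, (int)std::floor(subsample * n + 0.5));
      std::fill(sampled.begin(), sampled.end(), 0);
      for (int i = 0; i < keep; ++i) sampled[perm[i]] = 1;
    }
    for (int k = 0; k < n_class; ++k) {
      // softmax gradients/hessians for class k
      for (int i = 0; i < n; ++i) {
        double mx = F[0][i];
        for (int c = 1; c < n_class; ++c) mx = std::max(mx, F[c][i]);
        double denom = 0;
        for (int c = 0; c < n_class; ++c) denom += std::exp(F[c][i] - mx);
        double pk = std::exp(F[k][i] - mx) / denom;
        g[i] = pk - (y[i] == k ? 1.0 : 0.0);
        h[i] = std::max(pk * (1.0 - pk), 1e-16);
      }
      Tree tr = build_tree(X, sorted_idx, g, h, sampled, max_depth, lambda,
                           min_child_weight);
      for (int i = 0; i < n; ++i) F[k][i] += eta * tree_predict_row(tr, X, i);
      trees[r * n_class + k] = tree_to_list(tr);
    }
  }
  return List::create(_["trees"] = trees, _["n_class"] = n_class,
                      _["n_rounds"] = n_rounds, _["eta"] = eta);
}

// Raw scores F (n x n_class) using the first `round_limit` boosting rounds
// (<= 0 means all).
// [[Rcpp::export]]
NumericMatrix gbt_predict_cpp(List model, NumericMatrix X, int round_limit = 0) {
  List trees = model["trees"];
  int n_class = as<int>(model["n_class"]);
  int n_rounds = as<int>(model["n_rounds"]);
  double eta = as<double>(model["eta"]);
  if (round_limit <= 0 || round_limit > n_rounds) round_limit = n_rounds;
  const int n = X.nrow();
  NumericMatrix F(n, n_class);
  for (int r = 0; r < round_limit; ++r) {
    for (int k = 0; k < n_class; ++k) {
      Tree tr = tree_from_list(trees[r * n_class + k]);
      for (int i = 0; i < n; ++i) F(i, k) += eta * tree_predict_row(tr, X, i);
    }
  }
  return F;
}
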