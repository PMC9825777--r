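// Gradient-boosted regression trees with second-order (Newton) boosting:
// exact greedy splits, L2 leaf regularization, logistic / softmax
// objectives and validation-based early stopping.  Trees are returned to R
// as node matrices so the SHAP code can walk them.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Node {
  int feat = -1;       // -1 marks a leaf
  double thr = 0.0;    // go left when x[feat] < thr
  int left = -1, right = -1;
  double val = 0.0;    // leaf weight (eta already applied)
  double cover = 0.0;  // sum of hessians reaching the node
};

struct SplitResult {
  int feat = -1;
  double thr = 0.0, gain = 0.0;
};

static SplitResult best_split(const NumericMatrix& X,
                              const std::vector<int>& idx,
                              const std::vector<double>& g,
                              const std::vector<double>& h, double G,
                              double H, double lambda,
                              double min_child_weight) {
  SplitResult best;
  const double parent = G * G / (H + lambda);
  const int p = X.ncol();
  std::vector<int> ord(idx);
  for (int f = 0; f < p; ++f) {
    const double* xf = &X(0, f);
    std::sort(ord.begin(), ord.end(),
              [xf](int a, int b) { return xf[a] < xf[b]; });
    double GL = 0.0, HL = 0.0;
    for (size_t i = 0; i + 1 < ord.size(); ++i) {
      GL += g[ord[i]];
      HL += h[ord[i]];
      if (xf[ord[i]] == xf[ord[i + 1]]) continue;
      const double HR = H - HL, GR = G - GL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      const double gain =
          GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feat = f;
        best.thr = xf[ord[i]] / 2.0 + xf[ord[i + 1]] / 2.0;
      }
    }
  }
  return best;
}

static int build_node(std::vector<Node>& nodes, const NumericMatrix& X,
                      std::vector<int>& idx, const std::vector<double>& g,
                      const std::vector<double>& h, int depth, int max_depth,
                      double eta, double lambda, double min_child_weight) {
  double G = 0.0, H = 0.0;
  for (int i : idx) {
    G += g[i];
    H += h[i];
  }
  const int me = (int)nodes.size();
  nodes.push_back(Node());
  nodes[me].cover = H;
  SplitResult sp;
  if (depth < max_depth && idx.size() >= 2)
    sp = best_split(X, idx, g, h, G, H, lambda, min_child_weight);
  if (sp.feat < 0) {
    nodes[me].val = -G / (H + lambda) * eta;
    return me;
  }
  std::vector<int> li, ri;
  for (int i : idx)
    (X(i, sp.feat) < sp.thr ? li : ri).push_back(i);
  nodes[me].feat = sp.feat;
  nodes[me].thr = sp.thr;
  const int l = build_node(nodes, X, li, g, h, depth + 1, max_depth, eta,
                           lambda, min_child_weight);
  const int r = build_node(nodes, X, ri, g, h, depth + 1, max_depth, eta,
                           lambda, min_child_weight);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

static NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m((int)nodes.size(), 6);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feat;
    m(i, 1) = nodes[i].thr;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].val;
    m(i, 5) = nodes[i].cover;
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "value", "cover");
  return m;
}

static double predict_tree(const NumericMatrix& t, const NumericMatrix& X,
                           int row) {
  int node = 0;
  while (t(node, 0) >= 0)
    node = (X(row, (int)t(node, 0)) < t(node, 1)) ? (int)t(node, 2)
                                                  : (int)t(node, 3);
  return t(node, 4);
}

static void softmax_row(std::vector<double>& z) {
  double mx = *std::max_element(z.begin(), z.end());
  double s = 0.0;
  for (double& v : z) {
    v = std::exp(v - mx);
    s += v;
  }
  for (double& v : z) v /= s;
}

// [[Rcpp::export]]
List gbt_train_cpp(NumericMatrix X, IntegerVector y, NumericMatrix Xval,
                   IntegerVector yval, int n_class, int max_depth,
                   double eta, int nrounds, double lambda,
                   double min_child_weight, int early_stopping_rounds) {
  const int n = X.nrow(), nv = Xval.nrow();
  const int K = (n_class <= 2) ? 1 : n_class;  // trees per round
  std::vector<std::vector<double>> F(K, std::vector<double>(n, 0.0));
  std::vector<std::vector<double>> Fv(K, std::vector<double>(nv, 0.0));
  std::vector<double> g(n), h(n);
  List trees;
  NumericVector val_hist;
  double best_loss = R_PosInf;
  int best_round = 0, round = 0;
  const double eps = 1e-15;
  for (round = 1; round <= nrounds; ++round) {
    for (int k = 0; k < K; ++k) {
      if (K == 1) {
        for (int i = 0; i < n; ++i) {
          const double p = 1.0 / (1.0 + std::exp(-F[0][i]));
          g[i] = p - (y[i] == 1 ? 1.0 : 0.0);
          h[i] = std::max(p * (1.0 - p), 1e-16);
        }
      } else {
        for (int i = 0; i < n; ++i) {
          std::vector<double> z(K);
          for (int kk = 0; kk < K; ++kk) z[kk] = F[kk][i];
          softmax_row(z);
          g[i] = z[k] - (y[i] == k ? 1.0 : 0.0);
          h[i] = std::max(z[k] * (1.0 - z[k]), 1e-16);
        }
      }
      std::vector<Node> nodes;
      std::vector<int> idx(n);
      for (int i = 0; i < n; ++i) idx[i] = i;
      build_node(nodes, X, idx, g, h, 0, max_depth, eta, lambda,
                 min_child_weight);
      NumericMatrix tm = pack_tree(nodes);
      trees.push_back(tm);
      for (int i = 0; i < n; ++i) F[k][i] += predict_tree(tm, X, i);
      for (int i = 0; i < nv; ++i) Fv[k][i] += predict_tree(tm, Xval, i);
    }
    // validation loss after this round
    double loss = 0.0;
    if (K == 1) {
      for (int i = 0; i < nv; ++i) {
        double p = 1.0 / (1.0 + std::exp(-Fv[0][i]));
        p = std::min(1.0 - eps, std::max(eps, p));
        loss -= (yval[i] == 1) ? std::log(p) : std::log(1.0 - p);
      }
    } else {
      for (int i = 0; i < nv; ++i) {
        std::vector<double> z(K);
        for (int kk = 0; kk < K; ++kk) z[kk] = Fv[kk][i];
        softmax_row(z);
        loss -= std::log(std::max(z[yval[i]], eps));
      }
    }
    loss /= std::max(nv, 1);
    val_hist.push_back(loss);
    if (loss < best_loss - 1e-10) {
      best_loss = loss;
      best_round = round;
    } else if (round - best_round >= early_stopping_rounds) {
      break;
    }
  }
  return List::create(Named("trees") = trees, Named("best_iter") = best_round,
                      Named("best_val_loss") = best_loss,
                      Named("val_loss") = val_hist,
                      Named("trees_per_round") = K);
}

// [[Rcpp::export]]
NumericMatrix gbt_predict_cpp(List trees, NumericMatrix X, int n_class,
                              int nrounds_use) {
  const int K = (n_class <= 2) ? 1 : n_class;
  const int n = X.nrow();
  NumericMatrix margin(n, K);
  const int nt = std::min((int)trees.size(), nrounds_use * K);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tm = trees[t];
    const int k = t % K;
    for (int i = 0; i < n; ++i) margin(i, k) += predict_tree(tm, X, i);
  }
  return margin;
}
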