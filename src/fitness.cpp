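// Fast cross-validated linear-SVM accuracy for the GA wrapper fitness.
//
// Dual coordinate descent on the L1-loss (hinge) soft-margin SVM dual
// (Hsieh et al. 2008, the liblinear algorithm), with the bias handled as an
// augmented constant feature. Deterministic: coordinate order is shuffled
// with a fixed-seed LCG, so identical inputs always give identical models.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Lcg {
  uint64_t s;
  explicit Lcg(uint64_t seed) : s(seed) {}
  uint64_t next() { s = 6364136223846793005ULL * s + 1442695040888963407ULL; return s >> 33; }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

// Train L1-SVM by dual CD. Rows of Xs are training vectors (dense, column-major
// flattened as Xs[i + n*j]); y in {-1,+1}. Returns weight vector of length p+1,
// last entry the bias weight (constant feature 1).
std::vector<double> dcd_train(const std::vector<double>& Xs, int n, int p,
                              const std::vector<double>& y, double C,
                              int max_epochs, double tol) {
  std::vector<double> w(p + 1, 0.0), alpha(n, 0.0), qdiag(n);
  for (int i = 0; i < n; ++i) {
    double q = 1.0; // augmented bias feature
    for (int j = 0; j < p; ++j) { double v = Xs[i + n * j]; q += v * v; }
    qdiag[i] = q;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Lcg rng(88172645463325252ULL);
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates with the deterministic LCG
    for (int i = n - 1; i > 0; --i) std::swap(idx[i], idx[rng.below(i + 1)]);
    double pg_max = -1e30, pg_min = 1e30;
    for (int k = 0; k < n; ++k) {
      int i = idx[k];
      double g = -1.0 + y[i] * w[p]; // bias feature contribution
      for (int j = 0; j < p; ++j) g += y[i] * w[j] * Xs[i + n * j];
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (pg > pg_max) pg_max = pg;
      if (pg < pg_min) pg_min = pg;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - g / qdiag[i];
        if (a_new < 0.0) a_new = 0.0; else if (a_new > C) a_new = C;
        double d = (a_new - a_old) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * Xs[i + n * j];
          w[p] += d;
          alpha[i] = a_new;
        }
      }
    }
    if (pg_max - pg_min < tol) break;
  }
  return w;
}

} // namespace

// Train a binary linear SVM and return the (p+1)-vector of weights
// (last entry = bias via augmented constant feature).
// [[Rcpp::export(name = ".linear_svm_weights")]]
NumericVector linear_svm_weights(NumericMatrix X, NumericVector y, double C,
                                 int max_epochs = 60, double tol = 0.1) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> Xs(X.begin(), X.end()), yy(y.begin(), y.end());
  std::vector<double> w = dcd_train(Xs, n, p, yy, C, max_epochs, tol);
  return NumericVector(w.begin(), w.end());
}

// Mean K-fold cross-validated accuracy of a (one-vs-one, majority-vote)
// linear SVM restricted to the columns in `cols` (1-based).
//   X:     n x p feature matrix
//   yint:  integer class codes 1..ncls
//   folds: fold id 1..K per row (a fixed partition; determinism lives here)
// [[Rcpp::export(name = ".cv_linear_svm_accuracy")]]
double cv_linear_svm_accuracy(NumericMatrix X, IntegerVector yint,
                              IntegerVector folds, IntegerVector cols,
                              double C, int max_epochs = 60, double tol = 0.1) {
  int n = X.nrow(), psel = cols.size();
  int K = 0, ncls = 0;
  for (int i = 0; i < n; ++i) {
    if (folds[i] > K) K = folds[i];
    if (yint[i] > ncls) ncls = yint[i];
  }
  int correct = 0, total = 0;
  std::vector<int> votes(ncls);
  for (int f = 1; f <= K; ++f) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; ++i) (folds[i] == f ? te : tr).push_back(i);
    if (te.empty()) continue;
    int ntr = static_cast<int>(tr.size());
    // one weight vector per class pair (a < b)
    std::vector<std::vector<double> > W;
    std::vector<std::pair<int, int> > tasks;
    for (int a = 1; a <= ncls; ++a)
      for (int b = a + 1; b <= ncls; ++b) {
        std::vector<int> sub;
        for (int i = 0; i < ntr; ++i)
          if (yint[tr[i]] == a || yint[tr[i]] == b) sub.push_back(tr[i]);
        int ns = static_cast<int>(sub.size());
        std::vector<double> Xs(static_cast<size_t>(ns) * psel), yy(ns);
        for (int i = 0; i < ns; ++i) {
          yy[i] = (yint[sub[i]] == a) ? 1.0 : -1.0;
          for (int j = 0; j < psel; ++j)
            Xs[i + static_cast<size_t>(ns) * j] = X(sub[i], cols[j] - 1);
        }
        W.push_back(dcd_train(Xs, ns, psel, yy, C, max_epochs, tol));
        tasks.push_back(std::make_pair(a, b));
      }
    for (size_t t = 0; t < te.size(); ++t) {
      int i = te[t];
      std::fill(votes.begin(), votes.end(), 0);
      for (size_t m = 0; m < tasks.size(); ++m) {
        double s = W[m][psel];
        for (int j = 0; j < psel; ++j) s += W[m][j] * X(i, cols[j] - 1);
        ++votes[(s >= 0.0 ? tasks[m].first : tasks[m].second) - 1];
      }
      int best = 0;
      for (int c = 1; c < ncls; ++c) if (votes[c] > votes[best]) best = c;
      if (best + 1 == yint[i]) ++correct;
      ++total;
    }
  }
  return total > 0 ? static_cast<double>(correct) / total : NA_REAL;
}
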