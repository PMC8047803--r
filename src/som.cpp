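#include <Rcpp.h>
using namespace Rcpp;

// Online SOM training.
//
// X        n x P data matrix (rows presented sequentially, epoch after epoch)
// codebook m x P initial codebook (modified copy returned)
// grid_d2  m x m squared distances between neuron positions on the lattice
// epochs   full passes over X
// alpha0/1 learning rate, linear decay over all presentations
// radius0/1 Gaussian neighborhood radius (lattice units), linear decay
//
// order is an n x epochs matrix of 0-based presentation orders (one
// seeded permutation per epoch, generated in R), so the result is fully
// determined by the initial codebook and the order. BMU ties resolve to
// the lowest neuron index (strict < comparison).
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix X, NumericMatrix codebook,
                            NumericMatrix grid_d2, int epochs,
                            double alpha0, double alpha1,
                            double radius0, double radius1,
                            IntegerMatrix order) {
  const int n = X.nrow(), P = X.ncol(), m = codebook.nrow();
  NumericMatrix W = clone(codebook);
  const double total = (double)epochs * (double)n;
  double t = 0.0;
  for (int e = 0; e < epochs; ++e) {
    for (int fi = 0; fi < n; ++fi, t += 1.0) {
      const int f = order(fi, e);
      const double frac = (total > 1.0) ? t / (total - 1.0) : 0.0;
      const double alpha = alpha0 + (alpha1 - alpha0) * frac;
      const double radius = radius0 + (radius1 - radius0) * frac;
      int best = 0;
      double bestd = R_PosInf;
      for (int j = 0; j < m; ++j) {
        double d = 0.0;
        for (int k = 0; k < P; ++k) {
          const double diff = W(j, k) - X(f, k);
          d += diff * diff;
        }
        if (d < bestd) { bestd = d; best = j; }
      }
      const double denom = 2.0 * radius * radius;
      for (int j = 0; j < m; ++j) {
        const double h = std::exp(-grid_d2(best, j) / denom);
        if (h < 1e-12) continue;
        const double ah = alpha * h;
        for (int k = 0; k < P; ++k)
          W(j, k) += ah * (X(f, k) - W(j, k));
      }
    }
  }
  return W;
}

// Batch BMU assignment: for each row of X, the index (1-based) of the
// closest codebook row and the Euclidean distance to it. Ties -> lowest id.
// [[Rcpp::export]]
List bmu_assign_cpp(NumericMatrix codebook, NumericMatrix X) {
  const int n = X.nrow(), P = X.ncol(), m = codebook.nrow();
  IntegerVector bmu(n);
  NumericVector dist(n);
  for (int f = 0; f < n; ++f) {
    int best = 0;
    double bestd = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double d = 0.0;
      for (int k = 0; k < P; ++k) {
        const double diff = codebook(j, k) - X(f, k);
        d += diff * diff;
      }
      if (d < bestd) { bestd = d; best = j; }
    }
    bmu[f] = best + 1;
    dist[f] = std::sqrt(bestd);
  }
  return List::create(_["bmu"] = bmu, _["dist"] = dist);
}
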