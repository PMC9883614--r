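// Linear max-margin decoding engine.
//
// L2-regularized L1-loss (hinge) linear SVM trained by dual coordinate
// descent (Hsieh et al. 2008, as in LIBLINEAR), with the bias handled as an
// augmented constant feature. Multiclass is one-vs-rest with argmax decision.
// The per-timepoint loop lives here because time-resolved decoding trains
// one classifier per timepoint per cross-validation fold.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// deterministic LCG for the coordinate permutation (keeps results
// independent of R's RNG state)
struct Lcg {
  uint64_t s;
  explicit Lcg(uint64_t seed) : s(seed * 6364136223846793005ULL + 1442695040888963407ULL) {}
  uint32_t next() {
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    return static_cast<uint32_t>(s >> 33);
  }
};

// Xt holds one sample per COLUMN (bias row already appended); y in {-1, +1}
vec dcd_train(const mat& Xt, const vec& y, const vec& qdiag, double C,
              int max_pass, double tol) {
  const uword d = Xt.n_rows, n = Xt.n_cols;
  vec w(d, fill::zeros);
  vec alpha(n, fill::zeros);
  std::vector<uword> active(n);
  for (uword i = 0; i < n; ++i) active[i] = i;
  uword n_active = n;
  Lcg rng(20240101ULL + n * 131ULL + d);
  double pg_max_old = std::numeric_limits<double>::infinity();
  double pg_min_old = -std::numeric_limits<double>::infinity();

  for (int pass = 0; pass < max_pass; ++pass) {
    // Fisher-Yates shuffle of the active set
    for (uword i = n_active - 1; i > 0; --i) {
      uword j = rng.next() % (i + 1);
      std::swap(active[i], active[j]);
    }
    double pg_max = -std::numeric_limits<double>::infinity();
    double pg_min = std::numeric_limits<double>::infinity();
    for (uword k = 0; k < n_active; ++k) {
      const uword i = active[k];
      const double* xi = Xt.colptr(i);
      double wx = 0.0;
      for (uword j = 0; j < d; ++j) wx += w(j) * xi[j];
      const double g = y(i) * wx - 1.0;
      double pg = 0.0;
      // projected gradient with liblinear-style shrinking of bound-tight
      // samples whose gradient moved past last pass's extremes
      if (alpha(i) <= 0.0) {
        if (g > pg_max_old) {  // shrink: swap out of the active set
          active[k--] = active[--n_active];
          active[n_active] = i;
          continue;
        }
        pg = std::min(g, 0.0);
      } else if (alpha(i) >= C) {
        if (g < pg_min_old) {
          active[k--] = active[--n_active];
          active[n_active] = i;
          continue;
        }
        pg = std::max(g, 0.0);
      } else {
        pg = g;
      }
      pg_max = std::max(pg_max, pg);
      pg_min = std::min(pg_min, pg);
      if (std::fabs(pg) > 1e-12) {
        const double a_old = alpha(i);
        double a_new = a_old - g / qdiag(i);
        a_new = std::min(std::max(a_new, 0.0), C);
        if (a_new != a_old) {
          const double step = (a_new - a_old) * y(i);
          for (uword j = 0; j < d; ++j) w(j) += step * xi[j];
          alpha(i) = a_new;
        }
      }
    }
    if (pg_max - pg_min < tol) {
      if (n_active == n) break;
      n_active = n;  // converged on the shrunken problem: re-check everything
      pg_max_old = std::numeric_limits<double>::infinity();
      pg_min_old = -std::numeric_limits<double>::infinity();
      continue;
    }
    pg_max_old = pg_max <= 0 ? std::numeric_limits<double>::infinity() : pg_max;
    pg_min_old = pg_min >= 0 ? -std::numeric_limits<double>::infinity() : pg_min;
  }
  return w;
}

// one-vs-rest training on column-major samples; returns d x K weight matrix
mat ovr_train(const mat& Xt, const ivec& y, const ivec& classes, double C,
              int max_pass, double tol) {
  const uword n = Xt.n_cols;
  vec qdiag(n);
  for (uword i = 0; i < n; ++i) {
    qdiag(i) = dot(Xt.col(i), Xt.col(i));
    if (qdiag(i) <= 0) qdiag(i) = 1e-12;
  }
  mat W(Xt.n_rows, classes.n_elem);
  for (uword k = 0; k < classes.n_elem; ++k) {
    vec yk(n);
    for (uword i = 0; i < n; ++i) yk(i) = (y(i) == classes(k)) ? 1.0 : -1.0;
    W.col(k) = dcd_train(Xt, yk, qdiag, C, max_pass, tol);
  }
  return W;
}

ivec ovr_predict(const mat& X, const mat& W, const ivec& classes) {
  mat scores = X * W;
  ivec pred(X.n_rows);
  for (uword i = 0; i < X.n_rows; ++i) {
    uword best = scores.row(i).index_max();  // ties -> lowest index
    pred(i) = classes(best);
  }
  return pred;
}

}  // namespace

//' One-vs-rest linear SVM train/predict on a single feature matrix
//'
//' @param Xtr,Xte Numeric matrices (rows = samples).
//' @param ytr Integer class labels for the training rows.
//' @param C Regularization constant.
//' @param max_pass,tol Dual-coordinate-descent stopping controls.
//' @return Integer predictions for the rows of `Xte`.
//' @keywords internal
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_svm_ovr(const arma::mat& Xtr, const arma::ivec& ytr,
                                const arma::mat& Xte, double C = 1.0,
                                int max_pass = 15, double tol = 0.1) {
  ivec classes = unique(ytr);
  mat Xtr_t = join_cols(Xtr.t(), ones<rowvec>(Xtr.n_rows));
  mat Xte_b = join_rows(Xte, ones<vec>(Xte.n_rows));
  mat W = ovr_train(Xtr_t, ytr, classes, C, max_pass, tol);
  ivec pred = ovr_predict(Xte_b, W, classes);
  return Rcpp::wrap(Rcpp::IntegerVector(pred.begin(), pred.end()));
}

//' Per-timepoint decoding accuracy for one cross-validation fold
//'
//' Trains an independent one-vs-rest linear SVM at every timepoint on the
//' training trials' channel patterns (standardized with training-fold
//' statistics) and scores the held-out trials.
//'
//' @param train,test Cubes `[channel, trial, time]`.
//' @param ytr,yte Integer labels per trial.
//' @param C Regularization constant.
//' @param max_pass,tol Optimizer controls.
//' @return Accuracy per timepoint.
//' @keywords internal
// [[Rcpp::export]]
arma::vec cpp_decode_timepoints(const arma::cube& train, const arma::ivec& ytr,
                                const arma::cube& test, const arma::ivec& yte,
                                double C = 1.0, int max_pass = 15,
                                double tol = 0.1) {
  const uword n_t = train.n_slices;
  if (test.n_slices != n_t) Rcpp::stop("train/test time axes differ");
  ivec classes = unique(ytr);
  vec acc(n_t);
  for (uword t = 0; t < n_t; ++t) {
    // slices are channel x trial: samples are already column-major
    mat Xtr_t = train.slice(t);
    mat Xte_t = test.slice(t);
    vec mu = mean(Xtr_t, 1);
    vec sd = stddev(Xtr_t, 0, 1);
    sd.transform([](double v) { return v > 1e-12 ? v : 1.0; });
    Xtr_t.each_col() -= mu; Xtr_t.each_col() /= sd;
    Xte_t.each_col() -= mu; Xte_t.each_col() /= sd;
    mat Xtr_b = join_cols(Xtr_t, ones<rowvec>(Xtr_t.n_cols));
    mat Xte_b = join_rows(Xte_t.t(), ones<vec>(Xte_t.n_cols));
    mat W = ovr_train(Xtr_b, ytr, classes, C, max_pass, tol);
    ivec pred = ovr_predict(Xte_b, W, classes);
    acc(t) = mean(conv_to<vec>::from(pred == yte));
  }
  return acc;
}
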