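#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feed-forward pass for a 1-hidden-layer logistic network.
// W1t is hidden x input (transposed layout keeps the inner gemm cache
// friendly); X holds one example per column.
static inline arma::rowvec ff_batch(const arma::mat& W1t, const arma::vec& b1,
                                    const arma::vec& w2, double b2,
                                    const arma::mat& X) {
  arma::mat H = W1t * X;
  H.each_col() += b1;
  H = 1.0 / (1.0 + arma::exp(-H));
  arma::rowvec o = w2.t() * H;
  o += b2;
  return 1.0 / (1.0 + arma::exp(-o));
}

// [[Rcpp::export]]
NumericVector cpp_forward_batch(const arma::mat& W1t, const arma::vec& b1,
                                const arma::vec& w2, double b2,
                                const arma::mat& X) {
  arma::rowvec o = ff_batch(W1t, b1, w2, b2, X);
  return NumericVector(o.begin(), o.end());
}

// Best core per record: X stacks the candidate encodings of all records
// column-wise; record r owns columns start[r] .. start[r]+noff[r]-1.
// Ties go to the smallest offset (index_max returns the first maximum).
// [[Rcpp::export]]
List cpp_best_core(const arma::mat& W1t, const arma::vec& b1,
                   const arma::vec& w2, double b2, const arma::mat& X,
                   const IntegerVector& start, const IntegerVector& noff) {
  const int n = start.size();
  IntegerVector off(n);
  NumericVector sc(n);
  for (int r = 0; r < n; ++r) {
    arma::rowvec o = ff_batch(W1t, b1, w2, b2,
                              X.cols(start[r], start[r] + noff[r] - 1));
    arma::uword k = o.index_max();
    off[r] = (int)k;
    sc[r] = o[k];
  }
  return List::create(_["offset"] = off, _["score"] = sc);
}

static double assigned_core_mse(const arma::mat& W1t, const arma::vec& b1,
                                const arma::vec& w2, double b2,
                                const arma::mat& X, const IntegerVector& start,
                                const IntegerVector& noff,
                                const arma::vec& target) {
  double sse = 0.0;
  const int n = start.size();
  for (int r = 0; r < n; ++r) {
    arma::rowvec o = ff_batch(W1t, b1, w2, b2,
                              X.cols(start[r], start[r] + noff[r] - 1));
    double e = o.max() - target[r];
    sse += e * e;
  }
  return sse / n;
}

// Concurrent core alignment + online backpropagation on squared error.
// Per cycle, each record (in the pre-drawn order for that cycle) first has
// its binding core re-identified under the current weights, then contributes
// one gradient step at that core.  All randomness (initial weights, visit
// orders) is drawn on the R side, so the function is deterministic.
// order: n x n_cycles matrix of 0-based record indices.
// [[Rcpp::export]]
List cpp_train_nnalign(arma::mat W1t, arma::vec b1, arma::vec w2, double b2,
                       const arma::mat& X, const IntegerVector& start,
                       const IntegerVector& noff, const arma::vec& target,
                       const IntegerMatrix& order, double lr,
                       int trace_every) {
  const int n_cycles = order.ncol();
  const int n = start.size();
  std::vector<double> trace;
  for (int c = 0; c < n_cycles; ++c) {
    for (int j = 0; j < n; ++j) {
      const int r = order(j, c);
      const arma::mat Xc = X.cols(start[r], start[r] + noff[r] - 1);
      arma::mat H = W1t * Xc;
      H.each_col() += b1;
      H = 1.0 / (1.0 + arma::exp(-H));
      arma::rowvec o = w2.t() * H;
      o += b2;
      o = 1.0 / (1.0 + arma::exp(-o));
      const arma::uword k = o.index_max();
      const double ok = o[k];
      const arma::vec h = H.col(k);
      const double go = (ok - target[r]) * ok * (1.0 - ok);
      const arma::vec gh = (go * w2) % h % (1.0 - h);
      w2 -= lr * go * h;
      b2 -= lr * go;
      W1t -= lr * (gh * Xc.col(k).t());
      b1 -= lr * gh;
    }
    if (!W1t.is_finite() || !b1.is_finite() || !w2.is_finite() ||
        !std::isfinite(b2))
      stop("non-finite weights after cycle %d: learning rate too large", c + 1);
    if (trace_every > 0 && ((c + 1) % trace_every == 0 || c + 1 == n_cycles))
      trace.push_back(assigned_core_mse(W1t, b1, w2, b2, X, start, noff,
                                        target));
  }
  return List::create(_["W1t"] = W1t, _["b1"] = b1, _["w2"] = w2,
                      _["b2"] = b2, _["mse_trace"] = wrap(trace));
}
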