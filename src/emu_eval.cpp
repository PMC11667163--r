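// Compiled core of the EMU balance evaluation: per size level, assemble the
// flux-weighted balance matrices, convolve the smaller-EMU inputs, and solve
// the dense linear system. Structures are precomputed in R (emu_decompose);
// this function is called once per flux vector per tracer.
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List emu_eval_core(List levels, const arma::vec& vdir, List input_mids,
                   int n_state, IntegerVector target_ids, bool ridge) {
  std::vector<arma::vec> vals(n_state + input_mids.size());
  for (int i = 0; i < input_mids.size(); ++i)
    vals[n_state + i] = as<arma::vec>(input_mids[i]);

  for (int li = 0; li < levels.size(); ++li) {
    List lev = levels[li];
    int n = as<int>(lev["n"]);
    int size = as<int>(lev["size"]);
    NumericMatrix MAr = lev["MA"];
    arma::mat MAm(MAr.begin(), MAr.nrow(), MAr.ncol(), false);
    arma::vec avals = MAm * vdir;
    arma::mat A(avals.memptr(), n, n, false);

    if (Rf_isNull(lev["MB"]))
      stop("EMU level of size %d has no external inputs", size);
    NumericMatrix MBr = lev["MB"];
    arma::mat MBm(MBr.begin(), MBr.nrow(), MBr.ncol(), false);
    arma::vec bvals = MBm * vdir;
    List conv = lev["conv"];
    int k = conv.size();
    arma::mat B(bvals.memptr(), n, k, false);

    arma::mat Y(k, size + 1, arma::fill::zeros);
    for (int m = 0; m < k; ++m) {
      IntegerVector ids = conv[m];
      arma::vec mid = vals[ids[0] - 1];
      for (int j = 1; j < ids.size(); ++j) {
        const arma::vec& other = vals[ids[j] - 1];
        arma::vec out(mid.n_elem + other.n_elem - 1, arma::fill::zeros);
        for (arma::uword a = 0; a < mid.n_elem; ++a) {
          const double ma = mid[a];
          if (ma == 0.0) continue;
          for (arma::uword b2 = 0; b2 < other.n_elem; ++b2)
            out[a + b2] += ma * other[b2];
        }
        mid = out;
      }
      Y.row(m) = mid.t();
    }

    arma::mat RHS = -(B * Y);
    arma::mat X;
    bool ok = arma::solve(X, A, RHS, arma::solve_opts::no_approx);
    if (!ok) {
      if (!ridge) stop("singular EMU balance system at size %d", size);
      double lam = arma::abs(A).max() * 1e-9 + 1e-12;
      for (int t = 0; t < 4 && !ok; ++t, lam *= 1e3)
        ok = arma::solve(X, A - lam * arma::eye(n, n), RHS,
                         arma::solve_opts::force_approx);
      if (!ok) stop("singular EMU balance system at size %d", size);
    }
    X.elem(arma::find(X < 0)).zeros();
    IntegerVector rows = lev["rows"];
    for (int i = 0; i < n; ++i) vals[rows[i] - 1] = X.row(i).t();
  }

  List out(target_ids.size());
  for (int i = 0; i < target_ids.size(); ++i) {
    arma::vec v = vals[target_ids[i] - 1] / arma::accu(vals[target_ids[i] - 1]);
    out[i] = NumericVector(v.begin(), v.end());
  }
  return out;
}
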