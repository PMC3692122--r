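// Iterative TM-score superposition search.
//
// For each contiguous fragment seed and each distance cutoff, the pair is
// superposed by least squares (Kabsch) on the current residue subset, all
// aligned distances are recomputed, and the subset is replaced by the
// residues within the cutoff until it stabilizes; the transform with the
// highest TM sum over all matched pairs wins.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Least-squares proper rotation/translation mapping B onto A (rows = points).
static void kabschFit(const mat& A, const mat& B, mat& R, rowvec& tr) {
  rowvec cA = mean(A, 0), cB = mean(B, 0);
  mat H = (B.each_row() - cB).t() * (A.each_row() - cA);
  mat U, V;
  vec s;
  svd(U, s, V, H);
  mat D = eye(3, 3);
  if (det(V * U.t()) < 0) D(2, 2) = -1.0;
  R = V * D * U.t();
  tr = cA - (R * cB.t()).t();
}

struct Best {
  double tm = -1.0;
  mat R = eye(3, 3);
  rowvec tr = rowvec(3, fill::zeros);
  vec d;
};

// Refine one seed subset at one cutoff, updating the running best.
static void refine(const mat& xa, const mat& xb, double d0, int L,
                   uvec seed, double dcut, Best& best) {
  const int n = xa.n_rows;
  uvec idx = std::move(seed), prev;
  mat R;
  rowvec tr;
  for (int iter = 0; iter < 30; ++iter) {
    kabschFit(xa.rows(idx), xb.rows(idx), R, tr);
    mat fitted = xb * R.t();
    fitted.each_row() += tr;
    vec d = sqrt(sum(square(xa - fitted), 1));
    double tm = accu(1.0 / (1.0 + square(d / d0))) / L;
    if (tm > best.tm) {
      best.tm = tm;
      best.R = R;
      best.tr = tr;
      best.d = d;
    }
    uvec sel = find(d < dcut);
    if (sel.n_elem < 3) {
      uvec ord = sort_index(d);
      sel = sort(ord.head(std::min(4, n)));
    }
    bool same = (sel.n_elem == idx.n_elem && all(sel == idx)) ||
                (sel.n_elem == prev.n_elem && all(sel == prev));
    if (same) break;
    prev = idx;
    idx = sel;
  }
}

// [[Rcpp::export(name = ".tmSearchCpp")]]
Rcpp::List tmSearchCpp(const arma::mat& xa, const arma::mat& xb,
                       double d0, int L,
                       const Rcpp::IntegerVector& lens,
                       const Rcpp::NumericVector& dcuts) {
  const int n = xa.n_rows;
  Best best;
  best.d = vec(n, fill::zeros);

  for (int li = 0; li < lens.size(); ++li) {
    const int len = lens[li];
    if (len < 3 || len > n) continue;
    const int step = std::max(1, len / 4);
    for (int start = 0;; start += step) {
      if (start > n - len) start = n - len;  // always try the terminal seed
      uvec seed = regspace<uvec>(start, start + len - 1);
      for (int di = 0; di < dcuts.size(); ++di)
        refine(xa, xb, d0, L, seed, dcuts[di], best);
      if (start == n - len) break;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("tm") = best.tm, Rcpp::Named("rotation") = best.R,
      Rcpp::Named("translation") = Rcpp::NumericVector(best.tr.begin(),
                                                       best.tr.end()),
      Rcpp::Named("distances") = Rcpp::NumericVector(best.d.begin(),
                                                     best.d.end()));
}
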