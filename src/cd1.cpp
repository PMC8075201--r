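// Compiled core of the one-step contrastive divergence update. The full
// training schedule stays in R; this kernel performs the gemms, logistic
// activations, hidden sampling and the fused momentum/weight-decay update
// in place on the caller's parameter matrices. Hidden sampling consumes
// R's random stream element by element in column-major order, so results
// are reproducible under set.seed() and identical to a pure-R replay.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(mat z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export(name = ".cpp_cd1_inplace")]]
double cpp_cd1_inplace(Rcpp::NumericMatrix W_, Rcpp::NumericVector vb_,
                       Rcpp::NumericVector hb_, Rcpp::NumericMatrix Winc_,
                       Rcpp::NumericVector vbinc_, Rcpp::NumericVector hbinc_,
                       Rcpp::NumericMatrix batch_, double lr, double mom,
                       double wd) {
  const uword nv = W_.nrow(), nh = W_.ncol(), n = batch_.nrow();
  if ((uword)batch_.ncol() != nv)
    Rcpp::stop("batch has %d columns but the layer expects %d visible units",
               batch_.ncol(), (int)nv);

  mat W(W_.begin(), nv, nh, false, true);
  mat Winc(Winc_.begin(), nv, nh, false, true);
  vec vb(vb_.begin(), nv, false, true), hb(hb_.begin(), nh, false, true);
  vec vbinc(vbinc_.begin(), nv, false, true);
  vec hbinc(hbinc_.begin(), nh, false, true);
  mat B(batch_.begin(), n, nv, false, true);

  mat hp = B * W;
  hp.each_row() += hb.t();
  hp = sigmoid(hp);

  // binary hidden states from R's uniform stream (column-major order)
  mat hs(n, nh);
  for (uword j = 0; j < nh; ++j)
    for (uword i = 0; i < n; ++i)
      hs(i, j) = (R::unif_rand() < hp(i, j)) ? 1.0 : 0.0;

  mat vr = hs * W.t();
  vr.each_row() += vb.t();
  vr = sigmoid(vr);

  mat hr = vr * W;
  hr.each_row() += hb.t();
  hr = sigmoid(hr);

  const double invn = 1.0 / (double)n;
  // positive minus negative statistics as one gemm
  mat X = join_cols(B, vr);        // 2n x nv
  mat Y = join_cols(hp, -hr);      // 2n x nh
  mat dw = X.t() * Y;

  double *w = W.memptr(), *wi = Winc.memptr(), *g = dw.memptr();
  const uword nw = nv * nh;
  const double lrn = lr * invn, lwd = lr * wd;
  for (uword k = 0; k < nw; ++k) {
    wi[k] = mom * wi[k] + lrn * g[k] - lwd * w[k];
    w[k] += wi[k];
  }

  vbinc *= mom;
  vbinc += lrn * (sum(B, 0) - sum(vr, 0)).t();
  vb += vbinc;

  hbinc *= mom;
  hbinc += lrn * (sum(hp, 0) - sum(hr, 0)).t();
  hb += hbinc;

  if (!W.is_finite())
    Rcpp::stop("non-finite weights after CD-1 update; reduce the learning rate");

  return accu(square(B - vr)) / (double)(n * nv);
}
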