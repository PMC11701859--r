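// Gated recurrent unit over a batch of scalar sequences, with
// backpropagation through time. Gate order (r, z, n) and update rule
// h_t = (1 - z) * n + z * h_{t-1} follow the usual GRU convention.
// Each ROI series is one row of X; weights are shared across rows.
//
// Step caches stay on the C++ side behind an external pointer so the
// forward pass never copies hundreds of megabytes back into R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct GruCache {
  cube H, R, Z, Nn;
};

// X: N x T (scalar input per step); Wx: 1 x 3h; Wh: h x 3h; bx, bh: 1 x 3h.
// Returns the final hidden state (N x h) and, when want_cache, an external
// pointer to the step caches for the backward pass.
// [[Rcpp::export]]
Rcpp::List gru_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                           const arma::mat& Wh, const arma::rowvec& bx,
                           const arma::rowvec& bh, bool want_cache = true) {
  const uword N = X.n_rows, T = X.n_cols, h = Wh.n_rows;
  GruCache* cache = nullptr;
  mat hcur(N, h, fill::zeros), hnext(N, h);
  if (want_cache) {
    cache = new GruCache();
    cache->H.set_size(N, h, T + 1);
    cache->R.set_size(N, h, T);
    cache->Z.set_size(N, h, T);
    cache->Nn.set_size(N, h, T);
    cache->H.slice(0).zeros();
  }

  mat ax(N, 3 * h), ah(N, 3 * h);
  mat rbuf(N, h), zbuf(N, h), nbuf(N, h);
  for (uword t = 0; t < T; ++t) {
    const mat& hprev = hcur;
    // in-place gate writes (aliases into the cache when it exists)
    mat r(want_cache ? cache->R.slice_memptr(t) : rbuf.memptr(), N, h, false, true);
    mat z(want_cache ? cache->Z.slice_memptr(t) : zbuf.memptr(), N, h, false, true);
    mat n(want_cache ? cache->Nn.slice_memptr(t) : nbuf.memptr(), N, h, false, true);

    ax = X.col(t) * Wx;              // N x 3h (outer product)
    ax.each_row() += bx;
    ah = hprev * Wh;
    ah.each_row() += bh;
    r = 1.0 / (1.0 + exp(-(ax.cols(0, h - 1) + ah.cols(0, h - 1))));
    z = 1.0 / (1.0 + exp(-(ax.cols(h, 2 * h - 1) + ah.cols(h, 2 * h - 1))));
    n = tanh(ax.cols(2 * h, 3 * h - 1) + r % ah.cols(2 * h, 3 * h - 1));
    hnext = (1.0 - z) % n + z % hprev;
    hcur = hnext;
    if (want_cache) cache->H.slice(t + 1) = hcur;
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("h") = hcur);
  if (want_cache)
    out["cache"] = Rcpp::XPtr<GruCache>(cache, true);
  return out;
}

// dhT: gradient of the loss in the final hidden state (N x h).
// [[Rcpp::export]]
Rcpp::List gru_backward_cpp(const arma::mat& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::rowvec& bx,
                            const arma::rowvec& bh, SEXP cache_ptr,
                            const arma::mat& dhT) {
  Rcpp::XPtr<GruCache> cache(cache_ptr);
  const uword T = X.n_cols, h = Wh.n_rows, N = X.n_rows;
  mat dWx(size(Wx), fill::zeros), dWh(size(Wh), fill::zeros);
  rowvec dbx(3 * h, fill::zeros), dbh(3 * h, fill::zeros);
  mat dh = dhT;
  const mat Whn = Wh.cols(2 * h, 3 * h - 1);
  const rowvec bhn = bh.cols(2 * h, 3 * h - 1);
  mat q(N, h), dz(N, h), dn(N, h), dhprev(N, h), dan(N, h), dr(N, h),
      daz(N, h), dar(N, h);
  mat gx(N, 3 * h), gh(N, 3 * h);

  for (uword tt = T; tt >= 1; --tt) {
    const uword t = tt - 1;
    const mat hprev(cache->H.slice_memptr(t), N, h, false, true);
    const mat r(cache->R.slice_memptr(t), N, h, false, true);
    const mat z(cache->Z.slice_memptr(t), N, h, false, true);
    const mat n(cache->Nn.slice_memptr(t), N, h, false, true);
    q = hprev * Whn;                 // n-gate hidden preactivation (recomputed)
    q.each_row() += bhn;

    dz = dh % (hprev - n);
    dn = dh % (1.0 - z);
    dhprev = dh % z;
    dan = dn % (1.0 - n % n);
    dr = dan % q;
    daz = dz % z % (1.0 - z);
    dar = dr % r % (1.0 - r);

    gx.cols(0, h - 1) = dar;                  // x-side preactivation grads
    gx.cols(h, 2 * h - 1) = daz;
    gx.cols(2 * h, 3 * h - 1) = dan;
    gh.cols(0, h - 1) = dar;                  // h-side preactivation grads
    gh.cols(h, 2 * h - 1) = daz;
    gh.cols(2 * h, 3 * h - 1) = r % dan;

    dWx += X.col(t).t() * gx;
    dbx += sum(gx, 0);
    dWh += hprev.t() * gh;
    dbh += sum(gh, 0);
    dhprev += gh * Wh.t();
    dh = dhprev;
  }
  return Rcpp::List::create(Rcpp::Named("dWx") = dWx, Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("dbx") = dbx, Rcpp::Named("dbh") = dbh);
}
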