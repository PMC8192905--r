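// 1-D convolutional feature extractor: forward and backward passes.
//
// Layout conventions:
//   activations: arma::Cube<eT> (length, channels, batch)
//   conv weights: arma::mat (C_in * klen, C_out), row index = tap * C_in + c
//   flattened features: arma::mat (L_last * C_out, N), column-major per slice
//
// The arithmetic is templated over the element type: single precision is the
// default for training (the standard choice for convolutional networks, and
// about twice as fast through BLAS), double precision is available for
// verification against finite-difference gradients. Parameters and gradients
// cross the R boundary as doubles in both cases.
//
// Batch norm uses biased batch variance; running statistics are updated with
// momentum `bn_momentum` during training and used verbatim at inference.
// Dropout is "inverted" (masks scaled by 1/(1-p)) and draws from R's RNG so
// a single seed governs the whole training run.
//
// To keep memory traffic low, the training cache stores only the post-ReLU
// activations plus the batch statistics and dropout masks; every other
// intermediate is recomputed during the backward pass from those.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static int conv_out_len(int L_in, int klen, int stride) {
  return (L_in - klen) / stride + 1;
}

// --- element buffers shared with R ---------------------------------------
// double: NumericVector; float: RawVector of 4*n bytes.

template <typename eT> struct rbuf;

template <> struct rbuf<double> {
  static SEXP alloc(std::size_t n, double*& ptr) {
    NumericVector v((R_xlen_t)n);
    ptr = v.begin();
    return v;
  }
  static double* ptr_of(SEXP s) { return REAL(s); }
};

template <> struct rbuf<float> {
  static SEXP alloc(std::size_t n, float*& ptr) {
    RawVector v((R_xlen_t)(4 * n));
    ptr = reinterpret_cast<float*>(RAW(v));
    return v;
  }
  static float* ptr_of(SEXP s) { return reinterpret_cast<float*>(RAW(s)); }
};

template <typename eT>
static Mat<eT> to_T(const mat& m) { return conv_to<Mat<eT>>::from(m); }
template <typename eT>
static Col<eT> to_Tv(const vec& v) { return conv_to<Col<eT>>::from(v); }

// --- kernels --------------------------------------------------------------

template <typename eT>
static void im2col(const Mat<eT>& A, int klen, int stride, Mat<eT>& M) {
  const int C_in = A.n_cols;
  const int L_out = M.n_rows;
  for (int tap = 0; tap < klen; ++tap) {
    for (int c = 0; c < C_in; ++c) {
      const eT* src = A.colptr(c);
      eT* dst = M.colptr(tap * C_in + c);
      for (int t = 0; t < L_out; ++t) dst[t] = src[t * stride + tap];
    }
  }
}

template <typename eT>
static void col2im_add(const Mat<eT>& dM, int klen, int stride, Mat<eT>& dA) {
  const int C_in = dA.n_cols;
  const int L_out = dM.n_rows;
  for (int tap = 0; tap < klen; ++tap) {
    for (int c = 0; c < C_in; ++c) {
      const eT* src = dM.colptr(tap * C_in + c);
      eT* dst = dA.colptr(c);
      for (int t = 0; t < L_out; ++t) dst[t * stride + tap] += src[t];
    }
  }
}

template <typename eT>
static void conv_forward_into(const Cube<eT>& A, const Mat<eT>& W,
                              const Col<eT>& b, int klen, int stride,
                              Cube<eT>& Z, Mat<eT>& M) {
  const int N = A.n_slices;
  for (int n = 0; n < N; ++n) {
    im2col(A.slice(n), klen, stride, M);
    Z.slice(n) = M * W;
    Z.slice(n).each_row() += b.t();
  }
}

template <typename eT>
static void bn_stats(const Cube<eT>& A, vec& mu, vec& var_) {
  const int C = A.n_cols;
  const double m = (double)A.n_rows * A.n_slices;
  mu.zeros(C); var_.zeros(C);
  for (uword n = 0; n < A.n_slices; ++n) {
    for (int c = 0; c < C; ++c) {
      const eT* p = A.slice_colptr(n, c);
      double s = 0, s2 = 0;
      for (uword t = 0; t < A.n_rows; ++t) { s += p[t]; s2 += (double)p[t] * p[t]; }
      mu[c] += s; var_[c] += s2;
    }
  }
  mu /= m;
  var_ = var_ / m - square(mu);
  var_.transform([](double v) { return v < 0 ? 0 : v; });
}

template <typename eT>
static void bn_apply(Cube<eT>& A, const vec& mu, const vec& var_,
                     const vec& gamma, const vec& beta, double eps) {
  const vec sc = gamma / sqrt(var_ + eps);
  const vec sh = beta - mu % sc;
  const int C = A.n_cols;
  for (uword n = 0; n < A.n_slices; ++n) {
    for (int c = 0; c < C; ++c) {
      eT* p = A.slice_colptr(n, c);
      const eT s = (eT)sc[c], h = (eT)sh[c];
      for (uword t = 0; t < A.n_rows; ++t) p[t] = p[t] * s + h;
    }
  }
}

// Rebuild the output of block l (input of conv l+1) from its cached
// post-ReLU activations: batch norm, then dropout mask if present.
template <typename eT>
static Cube<eT> block_output(const Cube<eT>& act, const vec& mu,
                             const vec& var_, const vec& gamma,
                             const vec& beta, double eps, SEXP mask_sexp) {
  Cube<eT> O(act.n_rows, act.n_cols, act.n_slices);
  const int L = act.n_rows, C = act.n_cols, N = act.n_slices;
  const eT* pm = Rf_isNull(mask_sexp) ? nullptr : rbuf<eT>::ptr_of(mask_sexp);
  const vec sc = gamma / sqrt(var_ + eps);
  const vec sh = beta - mu % sc;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const eT* pa = act.slice_colptr(n, c);
      eT* po = O.slice_colptr(n, c);
      const eT s = (eT)sc[c], h = (eT)sh[c];
      const std::size_t off = ((std::size_t)n * C + c) * L;
      if (pm) {
        for (int t = 0; t < L; ++t) po[t] = (pa[t] * s + h) * pm[off + t];
      } else {
        for (int t = 0; t < L; ++t) po[t] = pa[t] * s + h;
      }
    }
  }
  return O;
}

// --- forward --------------------------------------------------------------

template <typename eT>
static List feat_forward_impl(const mat& X, const List& par, const List& state,
                              const ivec& strides, int klen, double p_drop,
                              const ivec& drop_layer, bool training,
                              double bn_eps, double bn_momentum) {
  const int T = X.n_rows, N = X.n_cols;
  const int n_layers = strides.n_elem;
  List conv_par = par["conv"];
  List conv_rm = state["conv_rm"], conv_rv = state["conv_rv"];

  // input batch norm (one channel over all T*N values)
  double g0 = as<double>(par["bn0_gamma"]), b0 = as<double>(par["bn0_beta"]);
  double mu0, var0;
  if (training) {
    mu0 = accu(X) / ((double)T * N);
    var0 = accu(square(X)) / ((double)T * N) - mu0 * mu0;
    if (var0 < 0) var0 = 0;
  } else {
    mu0 = as<double>(state["bn0_rm"]);
    var0 = as<double>(state["bn0_rv"]);
  }
  mat Y0d = (X - mu0) * (g0 / std::sqrt(var0 + bn_eps)) + b0;
  Mat<eT> Y0 = to_T<eT>(Y0d);
  Cube<eT> A(Y0.memptr(), T, 1, N);

  List acts(n_layers), mus(n_layers), vars(n_layers), masks(n_layers);
  List new_rm(n_layers), new_rv(n_layers);

  for (int l = 0; l < n_layers; ++l) {
    List lp = conv_par[l];
    Mat<eT> W = to_T<eT>(as<mat>(lp["W"]));
    Col<eT> b = to_Tv<eT>(as<vec>(lp["b"]));
    vec gamma = lp["gamma"], beta = lp["beta"];
    const int C_in = A.n_cols, L_in = A.n_rows;
    const int L_out = conv_out_len(L_in, klen, strides[l]);
    if (L_out < 1) stop("convolution output length < 1");
    if ((int)W.n_rows != C_in * klen) stop("conv weight shape mismatch");
    const int C_out = W.n_cols;

    Mat<eT> M(L_out, C_in * klen);
    vec mu, var_;
    if (training) {
      // cache post-ReLU activations in an R-backed buffer (zero copy)
      eT* act_ptr;
      SEXP act_s = rbuf<eT>::alloc((std::size_t)L_out * C_out * N, act_ptr);
      acts[l] = act_s;
      Cube<eT> Z(act_ptr, L_out, C_out, N, false, true);
      conv_forward_into(A, W, b, klen, strides[l], Z, M);
      Z.transform([](eT v) { return v > 0 ? v : (eT)0; });   // ReLU
      bn_stats(Z, mu, var_);
      vec rm = conv_rm[l], rv = conv_rv[l];
      new_rm[l] = (1 - bn_momentum) * rm + bn_momentum * mu;
      new_rv[l] = (1 - bn_momentum) * rv + bn_momentum * var_;
      A = Z;            // copy; act buffer must stay pre-BN
      bn_apply(A, mu, var_, gamma, beta, bn_eps);
      if (p_drop > 0 && drop_layer[l] == 1) {
        eT* mk_ptr;
        SEXP mk_s = rbuf<eT>::alloc((std::size_t)L_out * C_out * N, mk_ptr);
        masks[l] = mk_s;
        Cube<eT> Mk(mk_ptr, L_out, C_out, N, false, true);
        const eT scale = (eT)(1.0 / (1.0 - p_drop));
        for (uword i = 0; i < Mk.n_elem; ++i)
          Mk(i) = (unif_rand() < p_drop) ? (eT)0 : scale;
        A %= Mk;
      } else {
        masks[l] = R_NilValue;
      }
      mus[l] = mu; vars[l] = var_;
    } else {
      Cube<eT> Z(L_out, C_out, N);
      conv_forward_into(A, W, b, klen, strides[l], Z, M);
      Z.transform([](eT v) { return v > 0 ? v : (eT)0; });
      mu = as<vec>(conv_rm[l]);
      var_ = as<vec>(conv_rv[l]);
      bn_apply(Z, mu, var_, gamma, beta, bn_eps);
      A = std::move(Z);
    }
  }

  // flatten: per sample, column-major (length-major within each channel)
  const int F = A.n_rows * A.n_cols;
  mat out(F, N);
  for (int n = 0; n < N; ++n) {
    const eT* p = A.slice_colptr(n, 0);
    double* q = out.colptr(n);
    for (int i = 0; i < F; ++i) q[i] = p[i];
  }

  List res = List::create(_["out"] = out);
  if (training) {
    res["new_state"] = List::create(
        _["bn0_rm"] = (1 - bn_momentum) * as<double>(state["bn0_rm"]) +
                      bn_momentum * mu0,
        _["bn0_rv"] = (1 - bn_momentum) * as<double>(state["bn0_rv"]) +
                      bn_momentum * var0,
        _["conv_rm"] = new_rm, _["conv_rv"] = new_rv);
    res["cache"] = List::create(
        _["acts"] = acts, _["mus"] = mus, _["vars"] = vars,
        _["masks"] = masks, _["bn0_mu"] = mu0, _["bn0_var"] = var0,
        _["last_dims"] = IntegerVector::create(A.n_rows, A.n_cols));
  }
  return res;
}

// --- backward -------------------------------------------------------------

template <typename eT>
static List feat_backward_impl(const mat& dOut, const mat& X, const List& par,
                               const List& cache, const ivec& strides,
                               int klen, double bn_eps) {
  const int n_layers = strides.n_elem;
  const int N = dOut.n_cols;
  List conv_par = par["conv"];
  List acts = cache["acts"], mus = cache["mus"], vars = cache["vars"],
       masks = cache["masks"];
  IntegerVector last_dims = cache["last_dims"];
  double mu0 = as<double>(cache["bn0_mu"]), var0 = as<double>(cache["bn0_var"]);
  double g0 = as<double>(par["bn0_gamma"]), b0 = as<double>(par["bn0_beta"]);

  Cube<eT> dA(last_dims[0], last_dims[1], N);
  {
    const int F = last_dims[0] * last_dims[1];
    for (int n = 0; n < N; ++n) {
      const double* q = dOut.colptr(n);
      eT* p = dA.slice_colptr(n, 0);
      for (int i = 0; i < F; ++i) p[i] = (eT)q[i];
    }
  }

  List conv_grads(n_layers);
  mat Y0d = (X - mu0) * (g0 / std::sqrt(var0 + bn_eps)) + b0;

  // per-layer lengths for locating cached activations
  for (int l = n_layers - 1; l >= 0; --l) {
    List lp = conv_par[l];
    Mat<eT> W = to_T<eT>(as<mat>(lp["W"]));
    vec gamma = lp["gamma"];
    vec mu = mus[l], var_ = vars[l];
    const int Ln = dA.n_rows, C = dA.n_cols, Nn = dA.n_slices;
    const double m = (double)Ln * Nn;
    const eT* act_ptr = rbuf<eT>::ptr_of(acts[l]);
    Cube<eT> Aact(const_cast<eT*>(act_ptr), Ln, C, Nn, false, true);

    // dropout mask, batch-norm backward and ReLU backward, fused
    // (xhat recomputed from the cached post-ReLU activations)
    const eT* pm = Rf_isNull(masks[l]) ? nullptr : rbuf<eT>::ptr_of(masks[l]);
    vec inv_sd = 1.0 / sqrt(var_ + bn_eps);
    vec sum_dy(C, fill::zeros), sum_dyx(C, fill::zeros);
    for (int n = 0; n < Nn; ++n) {
      for (int c = 0; c < C; ++c) {
        eT* pd = dA.slice_colptr(n, c);
        const eT* pa = Aact.slice_colptr(n, c);
        const double muc = mu[c], isd = inv_sd[c];
        const std::size_t off = ((std::size_t)n * C + c) * Ln;
        double sdy = 0, sdyx = 0;
        if (pm) {
          for (int t = 0; t < Ln; ++t) {
            const double d = (double)pd[t] * pm[off + t];
            pd[t] = (eT)d;
            sdy += d;
            sdyx += d * (pa[t] - muc) * isd;
          }
        } else {
          for (int t = 0; t < Ln; ++t) {
            const double d = pd[t];
            sdy += d;
            sdyx += d * (pa[t] - muc) * isd;
          }
        }
        sum_dy[c] += sdy;
        sum_dyx[c] += sdyx;
      }
    }
    vec dgamma = sum_dyx, dbeta = sum_dy;
    vec mean_dy = sum_dy / m, mean_dyx = sum_dyx / m;
    for (int n = 0; n < Nn; ++n) {
      for (int c = 0; c < C; ++c) {
        eT* pd = dA.slice_colptr(n, c);
        const eT* pa = Aact.slice_colptr(n, c);
        const double muc = mu[c], isd = inv_sd[c];
        const double gi = gamma[c] * isd, mdy = mean_dy[c], mdyx = mean_dyx[c];
        for (int t = 0; t < Ln; ++t) {
          if (pa[t] <= 0) {            // ReLU backward
            pd[t] = 0;
          } else {
            const double xh = (pa[t] - muc) * isd;
            pd[t] = (eT)((pd[t] - mdy - xh * mdyx) * gi);
          }
        }
      }
    }

    // conv backward; rebuild this layer's input from the previous cache
    Cube<eT> A_in;
    if (l == 0) {
      Mat<eT> Y0 = to_T<eT>(Y0d);
      A_in = Cube<eT>(Y0.memptr(), Y0.n_rows, 1, N);
    } else {
      List lprev = conv_par[l - 1];
      const eT* pact = rbuf<eT>::ptr_of(acts[l - 1]);
      // previous layer's dims: infer from weight/output chain
      const int pC = as<mat>(lprev["W"]).n_cols;
      const std::size_t pn = (std::size_t)Rf_xlength(acts[l - 1]);
      const std::size_t pelem =
          std::is_same<eT, float>::value ? pn / 4 : pn;
      const int pL = (int)(pelem / ((std::size_t)pC * N));
      Cube<eT> Pact(const_cast<eT*>(pact), pL, pC, N, false, true);
      A_in = block_output(Pact, as<vec>(mus[l - 1]), as<vec>(vars[l - 1]),
                          as<vec>(lprev["gamma"]), as<vec>(lprev["beta"]),
                          bn_eps, masks[l - 1]);
    }
    const int C_in = A_in.n_cols;
    Mat<eT> dW(W.n_rows, W.n_cols, fill::zeros);
    Col<eT> db(W.n_cols, fill::zeros);
    Cube<eT> dA_in(A_in.n_rows, C_in, N, fill::zeros);
    Mat<eT> M(Ln, C_in * klen);
    for (int n = 0; n < N; ++n) {
      im2col(A_in.slice(n), klen, strides[l], M);
      dW += M.t() * dA.slice(n);
      db += sum(dA.slice(n), 0).t();
      Mat<eT> dM = dA.slice(n) * W.t();
      col2im_add(dM, klen, strides[l], dA_in.slice(n));
    }
    conv_grads[l] = List::create(
        _["W"] = conv_to<mat>::from(dW), _["b"] = conv_to<vec>::from(db),
        _["gamma"] = dgamma, _["beta"] = dbeta);
    dA = std::move(dA_in);
  }

  // input batch-norm backward
  const double m0 = (double)X.n_rows * X.n_cols;
  double inv_sd0 = 1.0 / std::sqrt(var0 + bn_eps);
  mat dY0(X.n_rows, X.n_cols);
  for (int n = 0; n < (int)X.n_cols; ++n) {
    const eT* p = dA.slice_colptr(n, 0);
    double* q = dY0.colptr(n);
    for (int t = 0; t < (int)X.n_rows; ++t) q[t] = p[t];
  }
  mat xh0 = (X - mu0) * inv_sd0;
  double dgamma0 = accu(dY0 % xh0);
  double dbeta0 = accu(dY0);
  mat dX = (dY0 - dbeta0 / m0 - xh0 * (dgamma0 / m0)) * (g0 * inv_sd0);

  return List::create(_["bn0_gamma"] = dgamma0, _["bn0_beta"] = dbeta0,
                      _["conv"] = conv_grads, _["dX"] = dX);
}

// --- exports --------------------------------------------------------------

// [[Rcpp::export]]
List feat_forward(const arma::mat& X, const List& par, const List& state,
                  const arma::ivec& strides, int klen, double p_drop,
                  const arma::ivec& drop_layer, bool training,
                  double bn_eps, double bn_momentum, bool single_prec) {
  if (single_prec) {
    return feat_forward_impl<float>(X, par, state, strides, klen, p_drop,
                                    drop_layer, training, bn_eps, bn_momentum);
  }
  return feat_forward_impl<double>(X, par, state, strides, klen, p_drop,
                                   drop_layer, training, bn_eps, bn_momentum);
}

// [[Rcpp::export]]
List feat_backward(const arma::mat& dOut, const arma::mat& X, const List& par,
                   const List& cache, const arma::ivec& strides, int klen,
                   double bn_eps, bool single_prec) {
  if (single_prec) {
    return feat_backward_impl<float>(dOut, X, par, cache, strides, klen, bn_eps);
  }
  return feat_backward_impl<double>(dOut, X, par, cache, strides, klen, bn_eps);
}
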