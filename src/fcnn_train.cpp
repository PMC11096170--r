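// Mini-batch Adam training loop for the voxel-wise FCNN (linear -> layer
// normalization -> ReLU blocks, MSE loss). The R level owns initialization,
// seeding and batch shuffling so runs are reproducible from R's RNG; this
// file only does the dense numerics.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LN_EPS = 1e-5;

struct Params {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b, g, be;
  arma::vec Wo;
  double bo;
};

static Params unpack(const List& params) {
  int n_layers = (params.size() - 2) / 4;
  Params p;
  p.W.resize(n_layers);
  p.b.resize(n_layers);
  p.g.resize(n_layers);
  p.be.resize(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    p.W[l] = as<arma::mat>(params[4 * l]);
    p.b[l] = as<arma::vec>(params[4 * l + 1]);
    p.g[l] = as<arma::vec>(params[4 * l + 2]);
    p.be[l] = as<arma::vec>(params[4 * l + 3]);
  }
  p.Wo = as<arma::vec>(params[params.size() - 2]);
  p.bo = as<double>(params[params.size() - 1]);
  return p;
}

static List pack(const Params& p) {
  int n_layers = p.W.size();
  List out(4 * n_layers + 2);
  CharacterVector names(4 * n_layers + 2);
  for (int l = 0; l < n_layers; ++l) {
    std::string ix = std::to_string(l + 1);
    out[4 * l] = wrap(p.W[l]);
    out[4 * l + 1] = wrap(p.b[l]);
    out[4 * l + 2] = wrap(p.g[l]);
    out[4 * l + 3] = wrap(p.be[l]);
    names[4 * l] = "W" + ix;
    names[4 * l + 1] = "b" + ix;
    names[4 * l + 2] = "g" + ix;
    names[4 * l + 3] = "be" + ix;
  }
  arma::mat Wo(p.Wo);
  Wo.reshape(p.Wo.n_elem, 1);
  out[4 * n_layers] = wrap(Wo);
  out[4 * n_layers + 1] = p.bo;
  names[4 * n_layers] = "Wo";
  names[4 * n_layers + 1] = "bo";
  out.attr("names") = names;
  return out;
}

struct Cache {
  std::vector<arma::mat> A_in, xhat, H;
  std::vector<arma::vec> inv_sd;
  arma::mat A_last;
};

static arma::vec forward(const Params& p, const arma::mat& X, Cache* cache) {
  int n_layers = p.W.size();
  arma::mat A = X;
  if (cache) {
    cache->A_in.resize(n_layers);
    cache->xhat.resize(n_layers);
    cache->H.resize(n_layers);
    cache->inv_sd.resize(n_layers);
  }
  for (int l = 0; l < n_layers; ++l) {
    arma::mat Z = A * p.W[l];
    Z.each_row() += p.b[l].t();
    arma::vec mu = arma::mean(Z, 1);
    Z.each_col() -= mu;
    arma::vec v = arma::mean(arma::square(Z), 1);
    arma::vec inv_sd = 1.0 / arma::sqrt(v + LN_EPS);
    Z.each_col() %= inv_sd;                       // Z is now xhat
    arma::mat H = Z;
    H.each_row() %= p.g[l].t();
    H.each_row() += p.be[l].t();
    if (cache) {
      cache->A_in[l] = A;
      cache->xhat[l] = Z;
      cache->inv_sd[l] = inv_sd;
      cache->H[l] = H;
    }
    A = H;
    A.elem(arma::find(H <= 0)).zeros();           // ReLU
  }
  if (cache) cache->A_last = A;
  return A * p.Wo + p.bo;
}

static Params gradients(const Params& p, const Cache& cache,
                        const arma::vec& d_pred) {
  int n_layers = p.W.size();
  Params g;
  g.W.resize(n_layers);
  g.b.resize(n_layers);
  g.g.resize(n_layers);
  g.be.resize(n_layers);
  g.Wo = cache.A_last.t() * d_pred;
  g.bo = arma::accu(d_pred);
  arma::mat dA = d_pred * p.Wo.t();
  for (int l = n_layers - 1; l >= 0; --l) {
    arma::mat dH = dA;
    dH.elem(arma::find(cache.H[l] <= 0)).zeros();
    g.g[l] = arma::sum(dH % cache.xhat[l], 0).t();
    g.be[l] = arma::sum(dH, 0).t();
    dH.each_row() %= p.g[l].t();                  // dH is now dxhat
    arma::vec rm1 = arma::mean(dH, 1);
    arma::vec rm2 = arma::mean(dH % cache.xhat[l], 1);
    arma::mat dZ = dH;
    dZ.each_col() -= rm1;
    dZ -= cache.xhat[l].each_col() % rm2;
    dZ.each_col() %= cache.inv_sd[l];
    g.W[l] = cache.A_in[l].t() * dZ;
    g.b[l] = arma::sum(dZ, 0).t();
    if (l > 0) dA = dZ * p.W[l].t();
  }
  return g;
}

// Adam state and update, kept per-tensor.
struct Adam {
  Params m, v;
  long t = 0;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;

  explicit Adam(const Params& p, double lr_) : lr(lr_) {
    m = p; v = p;
    auto zero_mat = [](arma::mat& x) { x.zeros(); };
    auto zero_vec = [](arma::vec& x) { x.zeros(); };
    for (size_t l = 0; l < p.W.size(); ++l) {
      zero_mat(m.W[l]); zero_vec(m.b[l]); zero_vec(m.g[l]); zero_vec(m.be[l]);
      zero_mat(v.W[l]); zero_vec(v.b[l]); zero_vec(v.g[l]); zero_vec(v.be[l]);
    }
    m.Wo.zeros(); v.Wo.zeros(); m.bo = 0; v.bo = 0;
  }

  template <class T>
  void upd(T& theta, T& mm, T& vv, const T& grad, double bc1, double bc2) {
    mm = b1 * mm + (1 - b1) * grad;
    vv = b2 * vv + (1 - b2) * (grad % grad);
    theta -= lr * (mm / bc1) / (arma::sqrt(vv / bc2) + eps);
  }

  void step(Params& p, const Params& grad) {
    ++t;
    double bc1 = 1 - std::pow(b1, (double)t);
    double bc2 = 1 - std::pow(b2, (double)t);
    for (size_t l = 0; l < p.W.size(); ++l) {
      upd(p.W[l], m.W[l], v.W[l], grad.W[l], bc1, bc2);
      upd(p.b[l], m.b[l], v.b[l], grad.b[l], bc1, bc2);
      upd(p.g[l], m.g[l], v.g[l], grad.g[l], bc1, bc2);
      upd(p.be[l], m.be[l], v.be[l], grad.be[l], bc1, bc2);
    }
    upd(p.Wo, m.Wo, v.Wo, grad.Wo, bc1, bc2);
    m.bo = b1 * m.bo + (1 - b1) * grad.bo;
    v.bo = b2 * v.bo + (1 - b2) * grad.bo * grad.bo;
    p.bo -= lr * (m.bo / bc1) / (std::sqrt(v.bo / bc2) + eps);
  }
};

// [[Rcpp::export(name = ".cpp_fcnn_predict")]]
arma::vec cpp_fcnn_predict(List params, const arma::mat& X) {
  Params p = unpack(params);
  return forward(p, X, nullptr);
}

// [[Rcpp::export(name = ".cpp_fcnn_grad")]]
List cpp_fcnn_grad(List params, const arma::mat& X, const arma::vec& y) {
  Params p = unpack(params);
  Cache cache;
  arma::vec pred = forward(p, X, &cache);
  arma::vec d_pred = 2.0 * (pred - y) / (double)y.n_elem;
  return pack(gradients(p, cache, d_pred));
}

// [[Rcpp::export(name = ".cpp_fcnn_train")]]
List cpp_fcnn_train(List params0, const arma::mat& X, const arma::vec& y,
                    Nullable<NumericMatrix> Xval, Nullable<NumericVector> yval,
                    const arma::umat& perms, int batch_size, double lr,
                    int epochs_used) {
  Params p = unpack(params0);
  Adam adam(p, lr);
  int n = X.n_rows;
  int epochs = perms.n_cols;
  arma::mat Xv;
  arma::vec yv;
  bool has_val = Xval.isNotNull();
  if (has_val) {
    Xv = as<arma::mat>(Xval.get());
    yv = as<arma::vec>(yval.get());
  }
  arma::vec hist_train(epochs), hist_val(epochs);
  hist_val.fill(NA_REAL);
  List checkpoint = R_NilValue;

  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n) - 1;
      arma::uvec idx = perms.col(e).subvec(start, stop) - 1;
      arma::mat Xb = X.rows(idx);
      arma::vec yb = y.elem(idx);
      Cache cache;
      arma::vec pred = forward(p, Xb, &cache);
      arma::vec resid = pred - yb;
      double loss = arma::mean(arma::square(resid));
      if (!std::isfinite(loss)) {
        Rcpp::stop("non-finite training loss at epoch %d (lr %g): aborting",
                   e + 1, lr);
      }
      loss_sum += loss;
      ++n_batches;
      arma::vec d_pred = 2.0 * resid / (double)yb.n_elem;
      Params grad = gradients(p, cache, d_pred);
      adam.step(p, grad);
    }
    hist_train(e) = loss_sum / n_batches;
    if (has_val) {
      arma::vec pv = forward(p, Xv, nullptr);
      hist_val(e) = arma::mean(arma::square(pv - yv));
    }
    if (e + 1 == epochs_used) checkpoint = pack(p);
    Rcpp::checkUserInterrupt();
  }
  if (checkpoint.isNULL()) checkpoint = pack(p);
  return List::create(
    _["params"] = checkpoint,
    _["final_params"] = pack(p),
    _["train_loss"] = hist_train,
    _["val_loss"] = hist_val
  );
}
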