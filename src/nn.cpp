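// Training core for the compact admission classifier:
// dense(h1) -> batchnorm -> relu -> dense(h2) -> batchnorm -> relu ->
// dense(1) -> sigmoid, binary cross-entropy, Adam, early stopping on a
// held-out monitor slice of the training data. All randomness (init,
// shuffles, monitor slice) comes from one std::mt19937_64 so a seed fixes
// the fit exactly.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Adam {
  mat m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init(const mat& w) { m.zeros(size(w)); v.zeros(size(w)); }
  void step(mat& w, const mat& g, double lr, int t) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * square(g);
    mat mhat = m / (1.0 - std::pow(b1, t));
    mat vhat = v / (1.0 - std::pow(b2, t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
};

const double BN_EPS = 1e-5;
const double BN_MOMENTUM = 0.1;

// batch-norm backward; dout is gradient wrt gamma*zhat+beta
mat bn_backward(const mat& dout, const mat& zhat, const rowvec& invstd,
                const rowvec& gamma, rowvec& dgamma, rowvec& dbeta) {
  double B = (double)dout.n_rows;
  dgamma = sum(dout % zhat, 0);
  dbeta = sum(dout, 0);
  mat dzhat = dout.each_row() % gamma;
  mat dz = dzhat * B;
  dz.each_row() -= sum(dzhat, 0);
  dz -= zhat.each_row() % sum(dzhat % zhat, 0);
  dz.each_row() %= invstd / B;
  return dz;
}

double bce(const vec& p, const vec& y) {
  vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  return -mean(y % log(pc) + (1.0 - y) % log(1.0 - pc));
}

struct Net {
  mat W1, W2, W3;
  rowvec b1, g1, be1, rm1, rv1;
  rowvec b2, g2, be2, rm2, rv2;
  double b3;
  // inference-mode forward using running statistics
  vec predict(const mat& X) const {
    mat z1 = X * W1; z1.each_row() += b1;
    z1.each_row() -= rm1;
    z1.each_row() %= g1 / sqrt(rv1 + BN_EPS);
    z1.each_row() += be1;
    z1 = clamp(z1, 0.0, datum::inf);
    mat z2 = z1 * W2; z2.each_row() += b2;
    z2.each_row() -= rm2;
    z2.each_row() %= g2 / sqrt(rv2 + BN_EPS);
    z2.each_row() += be2;
    z2 = clamp(z2, 0.0, datum::inf);
    vec f = z2 * W3 + b3;
    return 1.0 / (1.0 + exp(-f));
  }
};

} // namespace

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(const arma::mat& X, const arma::vec& y,
                        int h1, int h2, double lr, int batch_size,
                        int max_epochs, int patience, double monitor_frac,
                        double seed) {
  const uword n = X.n_rows, d = X.n_cols;
  std::mt19937_64 rng((uint64_t)seed);

  // monitor slice for early stopping: seeded shuffle, last chunk held out
  std::vector<uword> perm(n);
  for (uword i = 0; i < n; ++i) perm[i] = i;
  std::shuffle(perm.begin(), perm.end(), rng);
  uword n_mon = (uword)std::floor(monitor_frac * n);
  if (max_epochs > 1 && n_mon < 2 && n >= 20) n_mon = 2;
  uword n_fit = n - n_mon;
  uvec fit_idx(n_fit), mon_idx(std::max<uword>(n_mon, 1));
  for (uword i = 0; i < n_fit; ++i) fit_idx[i] = perm[i];
  if (n_mon > 0) {
    mon_idx.set_size(n_mon);
    for (uword i = 0; i < n_mon; ++i) mon_idx[i] = perm[n_fit + i];
  }
  mat Xf = X.rows(fit_idx);
  vec yf = y.elem(fit_idx);
  mat Xm; vec ym;
  bool have_monitor = n_mon >= 2;
  if (have_monitor) { Xm = X.rows(mon_idx); ym = y.elem(mon_idx); }

  Net net;
  std::normal_distribution<double> gauss(0.0, 1.0);
  auto he_init = [&](uword rows, uword cols) {
    mat w(rows, cols);
    double s = std::sqrt(2.0 / (double)rows);
    for (uword j = 0; j < cols; ++j)
      for (uword i = 0; i < rows; ++i) w(i, j) = s * gauss(rng);
    return w;
  };
  net.W1 = he_init(d, h1); net.b1.zeros(h1);
  net.g1.ones(h1); net.be1.zeros(h1);
  net.rm1.zeros(h1); net.rv1.ones(h1);
  net.W2 = he_init(h1, h2); net.b2.zeros(h2);
  net.g2.ones(h2); net.be2.zeros(h2);
  net.rm2.zeros(h2); net.rv2.ones(h2);
  net.W3 = he_init(h2, 1); net.b3 = 0.0;

  Adam aW1, ab1, ag1, abe1, aW2, ab2, ag2, abe2, aW3, ab3;
  aW1.init(net.W1); ab1.init(mat(net.b1)); ag1.init(mat(net.g1));
  abe1.init(mat(net.be1));
  aW2.init(net.W2); ab2.init(mat(net.b2)); ag2.init(mat(net.g2));
  abe2.init(mat(net.be2));
  aW3.init(net.W3); mat b3m(1, 1, fill::zeros); ab3.init(b3m);

  std::vector<uword> order(n_fit);
  for (uword i = 0; i < n_fit; ++i) order[i] = i;

  std::vector<double> train_loss_hist, monitor_loss_hist;
  Net best = net;
  double best_loss = datum::inf;
  int best_epoch = 0, epochs_run = 0, stall = 0, t_adam = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    uword seen = 0;
    for (uword start = 0; start < n_fit; start += (uword)batch_size) {
      uword stop = std::min(n_fit, start + (uword)batch_size);
      if (stop - start < 2) continue; // batch statistics need >= 2 rows
      uvec bidx(stop - start);
      for (uword i = start; i < stop; ++i) bidx[i - start] = order[i];
      mat Xb = Xf.rows(bidx);
      vec yb = yf.elem(bidx);
      double B = (double)Xb.n_rows;

      // forward (training mode: batch statistics)
      mat z1 = Xb * net.W1; z1.each_row() += net.b1;
      rowvec mu1 = mean(z1, 0);
      rowvec var1 = mean(square(z1.each_row() - mu1), 0);
      rowvec invstd1 = 1.0 / sqrt(var1 + BN_EPS);
      mat zhat1 = (z1.each_row() - mu1).each_row() % invstd1;
      mat a1p = zhat1.each_row() % net.g1;
      a1p.each_row() += net.be1;
      mat a1 = clamp(a1p, 0.0, datum::inf);

      mat z2 = a1 * net.W2; z2.each_row() += net.b2;
      rowvec mu2 = mean(z2, 0);
      rowvec var2 = mean(square(z2.each_row() - mu2), 0);
      rowvec invstd2 = 1.0 / sqrt(var2 + BN_EPS);
      mat zhat2 = (z2.each_row() - mu2).each_row() % invstd2;
      mat a2p = zhat2.each_row() % net.g2;
      a2p.each_row() += net.be2;
      mat a2 = clamp(a2p, 0.0, datum::inf);

      vec f = a2 * net.W3 + net.b3;
      vec p = 1.0 / (1.0 + exp(-f));
      epoch_loss += bce(p, yb) * B;
      seen += Xb.n_rows;

      // running statistics (unbiased variance, as batch-norm convention)
      double unb = B > 1 ? B / (B - 1.0) : 1.0;
      net.rm1 = (1.0 - BN_MOMENTUM) * net.rm1 + BN_MOMENTUM * mu1;
      net.rv1 = (1.0 - BN_MOMENTUM) * net.rv1 + BN_MOMENTUM * (unb * var1);
      net.rm2 = (1.0 - BN_MOMENTUM) * net.rm2 + BN_MOMENTUM * mu2;
      net.rv2 = (1.0 - BN_MOMENTUM) * net.rv2 + BN_MOMENTUM * (unb * var2);

      // backward
      vec df = (p - yb) / B;
      mat dW3 = a2.t() * df;
      double db3 = accu(df);
      mat da2 = df * net.W3.t();
      da2 %= conv_to<mat>::from(a2p > 0.0);
      rowvec dg2, dbe2v;
      mat dz2 = bn_backward(da2, zhat2, invstd2, net.g2, dg2, dbe2v);
      mat dW2 = a1.t() * dz2;
      rowvec db2 = sum(dz2, 0);
      mat da1 = dz2 * net.W2.t();
      da1 %= conv_to<mat>::from(a1p > 0.0);
      rowvec dg1, dbe1v;
      mat dz1 = bn_backward(da1, zhat1, invstd1, net.g1, dg1, dbe1v);
      mat dW1 = Xb.t() * dz1;
      rowvec db1 = sum(dz1, 0);

      ++t_adam;
      aW1.step(net.W1, dW1, lr, t_adam);
      { mat w(net.b1); ab1.step(w, mat(db1), lr, t_adam); net.b1 = w.row(0); }
      { mat w(net.g1); ag1.step(w, mat(dg1), lr, t_adam); net.g1 = w.row(0); }
      { mat w(net.be1); abe1.step(w, mat(dbe1v), lr, t_adam); net.be1 = w.row(0); }
      aW2.step(net.W2, dW2, lr, t_adam);
      { mat w(net.b2); ab2.step(w, mat(db2), lr, t_adam); net.b2 = w.row(0); }
      { mat w(net.g2); ag2.step(w, mat(dg2), lr, t_adam); net.g2 = w.row(0); }
      { mat w(net.be2); abe2.step(w, mat(dbe2v), lr, t_adam); net.be2 = w.row(0); }
      aW3.step(net.W3, dW3, lr, t_adam);
      { mat g(1, 1); g(0, 0) = db3; mat w(1, 1); w(0, 0) = net.b3;
        ab3.step(w, g, lr, t_adam); net.b3 = w(0, 0); }
    }
    epochs_run = epoch;
    train_loss_hist.push_back(seen > 0 ? epoch_loss / (double)seen : NA_REAL);

    double mon = have_monitor ? bce(net.predict(Xm), ym)
                              : train_loss_hist.back();
    monitor_loss_hist.push_back(mon);
    if (mon < best_loss - 1e-6) {
      best_loss = mon;
      best = net;
      best_epoch = epoch;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }

  auto rv = [](const rowvec& r) { return Rcpp::NumericVector(r.begin(), r.end()); };
  return Rcpp::List::create(
    Rcpp::Named("W1") = best.W1, Rcpp::Named("b1") = rv(best.b1),
    Rcpp::Named("gamma1") = rv(best.g1), Rcpp::Named("beta1") = rv(best.be1),
    Rcpp::Named("running_mean1") = rv(best.rm1),
    Rcpp::Named("running_var1") = rv(best.rv1),
    Rcpp::Named("W2") = best.W2, Rcpp::Named("b2") = rv(best.b2),
    Rcpp::Named("gamma2") = rv(best.g2), Rcpp::Named("beta2") = rv(best.be2),
    Rcpp::Named("running_mean2") = rv(best.rm2),
    Rcpp::Named("running_var2") = rv(best.rv2),
    Rcpp::Named("W3") = best.W3, Rcpp::Named("b3") = best.b3,
    Rcpp::Named("epochs_run") = epochs_run,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("train_loss") = train_loss_hist,
    Rcpp::Named("monitor_loss") = monitor_loss_hist,
    Rcpp::Named("best_monitor_loss") = best_loss);
}
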