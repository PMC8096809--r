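// Stacked many-to-many LSTM sequence classifier:
//   LSTM(h1, sequence output) -> batch norm -> dropout ->
//   LSTM(h2, sequence output) -> dropout -> per-timestep softmax (C classes)
// Trained with weighted categorical cross-entropy (padded positions carry
// zero weight) and Adam with a per-epoch exponentially decaying learning
// rate. Single-threaded and deterministic given the seed. Batch-norm uses
// per-feature statistics pooled over batch x time during training and the
// running moments at inference, so inference is strictly causal in time.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.99;

struct LstmCache {
  cube Gi, Gf, Gg, Go, C, Tc, H; // each (h, B, T)
};

// forward one LSTM layer over a batch; Xin is (din, B, T)
static void lstm_layer_forward(const mat& W, const vec& b, const cube& Xin,
                               int h, LstmCache& cc) {
  const int B = Xin.n_cols, T = Xin.n_slices, din = Xin.n_rows;
  cc.Gi.set_size(h, B, T); cc.Gf.set_size(h, B, T); cc.Gg.set_size(h, B, T);
  cc.Go.set_size(h, B, T); cc.C.set_size(h, B, T); cc.Tc.set_size(h, B, T);
  cc.H.set_size(h, B, T);
  mat hs(h, B, arma::fill::zeros), cs(h, B, arma::fill::zeros);
  mat inp(din + h, B);
  for (int t = 0; t < T; ++t) {
    inp.rows(0, din - 1) = Xin.slice(t);
    inp.rows(din, din + h - 1) = hs;
    mat Z = W * inp;
    Z.each_col() += b;
    mat i = 1.0 / (1.0 + arma::exp(-Z.rows(0, h - 1)));
    mat f = 1.0 / (1.0 + arma::exp(-Z.rows(h, 2 * h - 1)));
    mat g = arma::tanh(Z.rows(2 * h, 3 * h - 1));
    mat o = 1.0 / (1.0 + arma::exp(-Z.rows(3 * h, 4 * h - 1)));
    cs = f % cs + i % g;
    mat tc = arma::tanh(cs);
    hs = o % tc;
    cc.Gi.slice(t) = i; cc.Gf.slice(t) = f; cc.Gg.slice(t) = g;
    cc.Go.slice(t) = o; cc.C.slice(t) = cs; cc.Tc.slice(t) = tc;
    cc.H.slice(t) = hs;
  }
}

// backpropagation through time for one layer; dH is gradient w.r.t. H
static void lstm_layer_backward(const mat& W, const cube& Xin,
                                const LstmCache& cc, const cube& dH,
                                mat& gW, vec& gb, cube* dXin) {
  const int B = Xin.n_cols, T = Xin.n_slices, din = Xin.n_rows;
  const int h = cc.H.n_rows;
  gW.zeros(W.n_rows, W.n_cols);
  gb.zeros(W.n_rows);
  if (dXin) dXin->set_size(din, B, T);
  mat dh_next(h, B, arma::fill::zeros), dc_next(h, B, arma::fill::zeros);
  mat inp(din + h, B), dZ(4 * h, B);
  for (int t = T - 1; t >= 0; --t) {
    const mat& i = cc.Gi.slice(t); const mat& f = cc.Gf.slice(t);
    const mat& g = cc.Gg.slice(t); const mat& o = cc.Go.slice(t);
    const mat& tc = cc.Tc.slice(t);
    mat dh = dH.slice(t) + dh_next;
    mat do_ = dh % tc;
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat cprev = (t > 0) ? cc.C.slice(t - 1)
                        : mat(h, B, arma::fill::zeros);
    mat di = dc % g, df = dc % cprev, dg = dc % i;
    dZ.rows(0, h - 1) = di % i % (1.0 - i);
    dZ.rows(h, 2 * h - 1) = df % f % (1.0 - f);
    dZ.rows(2 * h, 3 * h - 1) = dg % (1.0 - g % g);
    dZ.rows(3 * h, 4 * h - 1) = do_ % o % (1.0 - o);
    inp.rows(0, din - 1) = Xin.slice(t);
    inp.rows(din, din + h - 1) = (t > 0) ? cc.H.slice(t - 1)
                                         : mat(h, B, arma::fill::zeros);
    gW += dZ * inp.t();
    gb += arma::sum(dZ, 1);
    mat dInp = W.t() * dZ;
    if (dXin) dXin->slice(t) = dInp.rows(0, din - 1);
    dh_next = dInp.rows(din, din + h - 1);
    dc_next = dc % f;
  }
}

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long step = 0;
  void init(const std::vector<mat*>& ps) {
    for (auto* p : ps) {
      m.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void update(std::vector<mat*>& ps, const std::vector<mat*>& gs, double lr) {
    ++step;
    double c1 = 1.0 - std::pow(b1, (double)step);
    double c2 = 1.0 - std::pow(b2, (double)step);
    for (size_t k = 0; k < ps.size(); ++k) {
      m[k] = b1 * m[k] + (1.0 - b1) * (*gs[k]);
      v[k] = b2 * v[k] + (1.0 - b2) * arma::square(*gs[k]);
      *ps[k] -= lr * (m[k] / c1) / (arma::sqrt(v[k] / c2) + eps);
    }
  }
};

// [[Rcpp::export]]
List cpp_lstm_train(List params, const arma::cube& X,
                    const arma::imat& Y, const arma::mat& Wt,
                    int epochs, int batch_size, double lr0, double decay,
                    double dropout, int n_classes, int seed) {
  mat W1 = as<mat>(params["W1"]);  vec b1 = as<vec>(params["b1"]);
  vec gamma = as<vec>(params["gamma"]), beta = as<vec>(params["beta"]);
  vec rmean = as<vec>(params["run_mean"]), rvar = as<vec>(params["run_var"]);
  mat W2 = as<mat>(params["W2"]);  vec b2 = as<vec>(params["b2"]);
  mat Wout = as<mat>(params["Wout"]); vec bout = as<vec>(params["bout"]);

  const int d = X.n_rows, T = X.n_cols, N = X.n_slices;
  const int h1 = gamma.n_elem, h2 = Wout.n_cols, C = n_classes;
  if ((int)W1.n_cols != d + h1 || (int)W2.n_cols != h1 + h2)
    stop("parameter dimensions do not match the input");
  if ((int)Y.n_rows != T || (int)Y.n_cols != N) stop("label array shape mismatch");
  if (arma::accu(Wt) <= 0) stop("all positions carry zero weight (all-pad batch)");
  const double keep = 1.0 - dropout;

  // vectors live as one-column matrices for the shared Adam machinery
  mat b1m(b1), gammam(gamma), betam(beta), b2m(b2), boutm(bout);
  std::vector<mat*> ps = {&W1, &b1m, &gammam, &betam, &W2, &b2m, &Wout, &boutm};
  Adam adam; adam.init(ps);

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> order(N);
  for (int n = 0; n < N; ++n) order[n] = n;

  NumericVector loss_hist(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    double lr = lr0 * std::pow(decay, (double)ep);
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0, ep_wt = 0.0;
    for (int start = 0; start < N; start += batch_size) {
      int B = std::min(batch_size, N - start);
      cube Xb(d, B, T);
      arma::ivec Yb(B * T);
      vec wb(B * T);
      for (int b = 0; b < B; ++b) {
        int n = order[start + b];
        for (int t = 0; t < T; ++t) {
          Xb.slice(t).col(b) = X.slice(n).col(t);
          Yb[t * B + b] = Y(t, n);
          wb[t * B + b] = Wt(t, n);
        }
      }
      double sumW = arma::accu(wb);
      if (sumW <= 0) continue;

      // ---- forward ----
      LstmCache c1; lstm_layer_forward(W1, b1m.col(0), Xb, h1, c1);
      mat M1(c1.H.memptr(), h1, B * T, false, true);
      vec mu = arma::mean(M1, 1);
      vec va = arma::var(M1, 1, 1); // population variance per feature
      vec invstd = 1.0 / arma::sqrt(va + BN_EPS);
      mat Xhat = M1;
      Xhat.each_col() -= mu;
      Xhat.each_col() %= invstd;
      mat Z1 = Xhat;
      Z1.each_col() %= gammam.col(0);
      Z1.each_col() += betam.col(0);
      rmean = BN_MOMENTUM * rmean + (1.0 - BN_MOMENTUM) * mu;
      rvar = BN_MOMENTUM * rvar + (1.0 - BN_MOMENTUM) * va;

      mat mask1(h1, B * T), mask2(h2, B * T);
      if (dropout > 0) {
        for (arma::uword j = 0; j < mask1.n_elem; ++j)
          mask1[j] = (unif(rng) < keep) ? 1.0 / keep : 0.0;
        for (arma::uword j = 0; j < mask2.n_elem; ++j)
          mask2[j] = (unif(rng) < keep) ? 1.0 / keep : 0.0;
      } else { mask1.ones(); mask2.ones(); }
      mat D1 = Z1 % mask1;
      cube D1c(D1.memptr(), h1, B, T, false, true);

      LstmCache c2; lstm_layer_forward(W2, b2m.col(0), D1c, h2, c2);
      mat M2(c2.H.memptr(), h2, B * T, false, true);
      mat D2 = M2 % mask2;

      mat logits = Wout * D2;
      logits.each_col() += boutm.col(0);
      logits.each_row() -= arma::max(logits, 0);
      mat P = arma::exp(logits);
      P.each_row() /= arma::sum(P, 0);

      double loss = 0.0;
      mat dL = P;
      for (int j = 0; j < B * T; ++j) {
        double w = wb[j];
        if (w <= 0) { dL.col(j).zeros(); continue; }
        int y = Yb[j];
        loss += -w * std::log(std::max(P(y, j), 1e-12));
        dL(y, j) -= 1.0;
        dL.col(j) *= w / sumW;
      }
      loss /= sumW;
      ep_loss += loss * sumW; ep_wt += sumW;

      // ---- backward ----
      mat gWout = dL * D2.t();
      mat gbout = arma::sum(dL, 1);
      mat dD2 = Wout.t() * dL;
      mat dM2 = dD2 % mask2;
      cube dH2(dM2.memptr(), h2, B, T, false, true);
      mat gW2; vec gb2v; cube dD1c;
      lstm_layer_backward(W2, D1c, c2, dH2, gW2, gb2v, &dD1c);
      mat dD1(dD1c.memptr(), h1, B * T, false, true);
      mat dZ1 = dD1 % mask1;
      mat dgamma = arma::sum(dZ1 % Xhat, 1);
      mat dbeta = arma::sum(dZ1, 1);
      mat dXhat = dZ1;
      dXhat.each_col() %= gammam.col(0);
      const double Mn = (double)(B * T);
      vec sum_dx = arma::sum(dXhat, 1);
      vec sum_dxx = arma::sum(dXhat % Xhat, 1);
      mat dM1 = Mn * dXhat;
      dM1.each_col() -= sum_dx;
      mat xs = Xhat;
      xs.each_col() %= sum_dxx;
      dM1 -= xs;
      vec sc = invstd / Mn;
      dM1.each_col() %= sc;
      cube dH1(dM1.memptr(), h1, B, T, false, true);
      mat gW1; vec gb1v;
      lstm_layer_backward(W1, Xb, c1, dH1, gW1, gb1v, nullptr);

      mat gb1(gb1v), gb2(gb2v);
      std::vector<mat*> gs = {&gW1, &gb1, &dgamma, &dbeta,
                              &gW2, &gb2, &gWout, &gbout};
      adam.update(ps, gs, lr);
    }
    loss_hist[ep] = (ep_wt > 0) ? ep_loss / ep_wt : NA_REAL;
  }

  return List::create(
    _["params"] = List::create(
      _["W1"] = W1, _["b1"] = vec(b1m.col(0)),
      _["gamma"] = vec(gammam.col(0)), _["beta"] = vec(betam.col(0)),
      _["run_mean"] = rmean, _["run_var"] = rvar,
      _["W2"] = W2, _["b2"] = vec(b2m.col(0)),
      _["Wout"] = Wout, _["bout"] = vec(boutm.col(0))),
    _["loss"] = loss_hist);
}

// [[Rcpp::export]]
arma::cube cpp_lstm_predict(List params, const arma::cube& X, int n_classes) {
  mat W1 = as<mat>(params["W1"]);  vec b1 = as<vec>(params["b1"]);
  vec gamma = as<vec>(params["gamma"]), beta = as<vec>(params["beta"]);
  vec rmean = as<vec>(params["run_mean"]), rvar = as<vec>(params["run_var"]);
  mat W2 = as<mat>(params["W2"]);  vec b2 = as<vec>(params["b2"]);
  mat Wout = as<mat>(params["Wout"]); vec bout = as<vec>(params["bout"]);
  const int d = X.n_rows, T = X.n_cols, N = X.n_slices;
  const int h1 = gamma.n_elem, h2 = Wout.n_cols;
  if ((int)W1.n_cols != d + h1) stop("input dimension mismatch");

  vec scale = gamma / arma::sqrt(rvar + BN_EPS);
  vec shift = beta - scale % rmean;
  cube out(n_classes, T, N);
  mat h1s(h1, 1), c1s(h1, 1), h2s(h2, 1), c2s(h2, 1);
  for (int n = 0; n < N; ++n) {
    h1s.zeros(); c1s.zeros(); h2s.zeros(); c2s.zeros();
    for (int t = 0; t < T; ++t) {
      vec x = X.slice(n).col(t);
      vec z1 = W1 * arma::join_cols(x, h1s.col(0)) + b1;
      vec i = 1.0 / (1.0 + arma::exp(-z1.subvec(0, h1 - 1)));
      vec f = 1.0 / (1.0 + arma::exp(-z1.subvec(h1, 2 * h1 - 1)));
      vec g = arma::tanh(z1.subvec(2 * h1, 3 * h1 - 1));
      vec o = 1.0 / (1.0 + arma::exp(-z1.subvec(3 * h1, 4 * h1 - 1)));
      c1s.col(0) = f % c1s.col(0) + i % g;
      h1s.col(0) = o % arma::tanh(c1s.col(0));
      vec zin = scale % h1s.col(0) + shift;
      vec z2 = W2 * arma::join_cols(zin, h2s.col(0)) + b2;
      vec i2 = 1.0 / (1.0 + arma::exp(-z2.subvec(0, h2 - 1)));
      vec f2 = 1.0 / (1.0 + arma::exp(-z2.subvec(h2, 2 * h2 - 1)));
      vec g2 = arma::tanh(z2.subvec(2 * h2, 3 * h2 - 1));
      vec o2 = 1.0 / (1.0 + arma::exp(-z2.subvec(3 * h2, 4 * h2 - 1)));
      c2s.col(0) = f2 % c2s.col(0) + i2 % g2;
      h2s.col(0) = o2 % arma::tanh(c2s.col(0));
      vec logit = Wout * h2s.col(0) + bout;
      logit -= logit.max();
      vec p = arma::exp(logit);
      out.slice(n).col(t) = p / arma::accu(p);
    }
  }
  return out;
}
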