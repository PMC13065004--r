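// Multilayer perceptron for binary risk prediction: ReLU hidden layers,
// sigmoid output, cross-entropy loss, minibatch Adam with decoupled weight
// decay and reduce-on-plateau learning-rate decay. All randomness (init,
// shuffling) comes from a caller-supplied seed via a local mt19937, so a
// fixed seed reproduces training exactly.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec forward_probs(const std::vector<arma::mat>& W,
                               const std::vector<arma::vec>& b,
                               const arma::mat& Xt) {
  arma::mat A = Xt; // (features x n)
  const size_t L = W.size();
  for (size_t l = 0; l < L; ++l) {
    A = W[l] * A;
    A.each_col() += b[l];
    if (l + 1 < L) {
      A = arma::clamp(A, 0.0, arma::datum::inf); // ReLU
    } else {
      A = 1.0 / (1.0 + arma::exp(-A)); // sigmoid
    }
  }
  return A.row(0).t();
}

static double ce_loss(const arma::vec& z, const arma::vec& p) {
  const double eps = 1e-12;
  arma::vec q = arma::clamp(p, eps, 1.0 - eps);
  return -arma::mean(z % arma::log(q) + (1.0 - z) % arma::log(1.0 - q));
}

// [[Rcpp::export(name = ".mlp_train")]]
List mlp_train(const arma::mat& X, const arma::vec& z,
               const IntegerVector& hidden,
               int epochs, int batch_size, double lr, double weight_decay,
               double dropout, int seed, double lr_factor, int lr_patience,
               double min_lr) {
  const arma::uword n = X.n_rows, q = X.n_cols;
  std::vector<arma::uword> sizes;
  sizes.push_back(q);
  for (int h : hidden) sizes.push_back((arma::uword)h);
  sizes.push_back(1);
  const size_t L = sizes.size() - 1;

  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::vec> b(L), mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    // He-normal init for ReLU layers, Xavier for the sigmoid output
    double scale = (l + 1 < L) ? std::sqrt(2.0 / sizes[l])
                               : std::sqrt(1.0 / sizes[l]);
    W[l].set_size(sizes[l + 1], sizes[l]);
    for (arma::uword i = 0; i < W[l].n_elem; ++i) W[l](i) = scale * gauss(rng);
    b[l].zeros(sizes[l + 1]);
    mW[l].zeros(arma::size(W[l])); vW[l].zeros(arma::size(W[l]));
    mb[l].zeros(sizes[l + 1]);    vb[l].zeros(sizes[l + 1]);
  }

  const arma::mat Xt = X.t(); // feature-major
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  long t = 0;
  double best_loss = arma::datum::inf;
  int stall = 0;
  double cur_lr = lr;
  NumericVector trajectory(epochs);

  std::vector<arma::mat> A(L + 1), D(L);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (arma::uword start = 0; start < n; start += (arma::uword)batch_size) {
      arma::uword end = std::min(n, start + (arma::uword)batch_size);
      arma::uword m = end - start;
      arma::uvec idx(m);
      for (arma::uword i = 0; i < m; ++i) idx(i) = order[start + i];

      A[0] = Xt.cols(idx);
      arma::rowvec zb(m);
      for (arma::uword i = 0; i < m; ++i) zb(i) = z(idx(i));

      std::vector<arma::mat> mask(L);
      for (size_t l = 0; l < L; ++l) {
        arma::mat Zl = W[l] * A[l];
        Zl.each_col() += b[l];
        if (l + 1 < L) {
          A[l + 1] = arma::clamp(Zl, 0.0, arma::datum::inf);
          if (dropout > 0.0) {
            // inverted dropout: scale kept units so inference needs no change
            mask[l].set_size(arma::size(A[l + 1]));
            for (arma::uword i = 0; i < mask[l].n_elem; ++i) {
              mask[l](i) = (unif(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
            }
            A[l + 1] %= mask[l];
          }
        } else {
          A[l + 1] = 1.0 / (1.0 + arma::exp(-Zl));
        }
      }

      // output delta for sigmoid + cross-entropy
      arma::mat delta = (A[L].row(0) - zb) / (double)m;
      ++t;
      const double bc1 = 1.0 - std::pow(beta1, (double)t);
      const double bc2 = 1.0 - std::pow(beta2, (double)t);

      for (size_t l = L; l-- > 0;) {
        arma::mat gW = delta * A[l].t();
        arma::vec gb = arma::sum(delta, 1);
        if (l > 0) {
          arma::mat back = W[l].t() * delta;
          delta = back % arma::conv_to<arma::mat>::from(A[l] > 0.0);
          if (dropout > 0.0) delta %= mask[l - 1];
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * (gW % gW);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * (gb % gb);
        W[l] -= cur_lr * ((mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + adam_eps)
                          + weight_decay * W[l]);
        b[l] -= cur_lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + adam_eps);
      }
    }

    double full = ce_loss(z, forward_probs(W, b, Xt));
    trajectory[ep] = full;
    if (full < best_loss - 1e-6) {
      best_loss = full;
      stall = 0;
    } else if (++stall >= lr_patience) {
      cur_lr = std::max(min_lr, cur_lr * lr_factor);
      stall = 0;
    }
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = wrap(W[l]);
    bout[l] = wrap(b[l]);
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["loss_trajectory"] = trajectory,
                      _["final_loss"] = best_loss);
}

// [[Rcpp::export(name = ".mlp_predict")]]
arma::vec mlp_predict(const List& W, const List& b, const arma::mat& X) {
  std::vector<arma::mat> Wv(W.size());
  std::vector<arma::vec> bv(b.size());
  for (int l = 0; l < W.size(); ++l) {
    Wv[l] = as<arma::mat>(W[l]);
    bv[l] = as<arma::vec>(b[l]);
  }
  return forward_probs(Wv, bv, X.t());
}
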