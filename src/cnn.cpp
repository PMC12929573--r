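// Training/inference engine for the four-block convolutional classifier:
// [3x3 conv (same) -> batch norm -> ReLU -> 2x2 max-pool] x 4, widths
// 32/64/128/256, flatten, dense -> single logit.  Sigmoid + binary
// cross-entropy loss, RMSProp updates.  All randomness (weight init,
// example ordering) is supplied from R, so runs are reproducible.
//
// Feature maps are stored as (H*W) x C matrices with pixel index
// p = row*W + col; convolution is im2col + GEMM.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const int NBLOCK = 4;
static const double BN_EPS = 1e-5;

static mat im2col3(const mat& A, int H, int W) {
  const int C = A.n_cols;
  mat out(H * W, 9 * C, fill::zeros);
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      const int o = (dr + 1) * 3 + (dc + 1);
      for (int c = 0; c < C; ++c) {
        for (int r = 0; r < H; ++r) {
          const int rs = r + dr;
          if (rs < 0 || rs >= H) continue;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dc;
            if (ws < 0 || ws >= W) continue;
            out(r * W + w, o * C + c) = A(rs * W + ws, c);
          }
        }
      }
    }
  }
  return out;
}

static mat col2im3(const mat& dcols, int H, int W, int C) {
  mat dA(H * W, C, fill::zeros);
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      const int o = (dr + 1) * 3 + (dc + 1);
      for (int c = 0; c < C; ++c) {
        for (int r = 0; r < H; ++r) {
          const int rs = r + dr;
          if (rs < 0 || rs >= H) continue;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dc;
            if (ws < 0 || ws >= W) continue;
            dA(rs * W + ws, c) += dcols(r * W + w, o * C + c);
          }
        }
      }
    }
  }
  return dA;
}

static mat maxpool2(const mat& A, int H, int W, umat& arg) {
  const int C = A.n_cols, Ho = H / 2, Wo = W / 2;
  mat out(Ho * Wo, C);
  arg.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int pr = 0; pr < Ho; ++pr) {
      for (int pc = 0; pc < Wo; ++pc) {
        const int q = pr * Wo + pc;
        const int base = (2 * pr) * W + 2 * pc;
        const int idx[4] = { base, base + 1, base + W, base + W + 1 };
        double best = A(idx[0], c);
        int bi = idx[0];
        for (int t = 1; t < 4; ++t) {
          const double v = A(idx[t], c);
          if (v > best) { best = v; bi = idx[t]; }
        }
        out(q, c) = best;
        arg(q, c) = static_cast<uword>(bi);
      }
    }
  }
  return out;
}

struct Weights {
  std::vector<mat>    cw;   // (9*Cin) x Cout
  std::vector<rowvec> cb, gamma, beta, rmean, rvar;
  vec    dw;
  double db;
};

static Weights unpack(const Rcpp::List& w) {
  Weights W;
  Rcpp::List cw = w["conv_w"], cb = w["conv_b"], g = w["bn_gamma"],
             be = w["bn_beta"], rm = w["bn_mean"], rv = w["bn_var"];
  for (int l = 0; l < NBLOCK; ++l) {
    W.cw.push_back(Rcpp::as<mat>(cw[l]));
    W.cb.push_back(Rcpp::as<rowvec>(cb[l]));
    W.gamma.push_back(Rcpp::as<rowvec>(g[l]));
    W.beta.push_back(Rcpp::as<rowvec>(be[l]));
    W.rmean.push_back(Rcpp::as<rowvec>(rm[l]));
    W.rvar.push_back(Rcpp::as<rowvec>(rv[l]));
  }
  W.dw = Rcpp::as<vec>(w["dense_w"]);
  W.db = Rcpp::as<double>(w["dense_b"]);
  return W;
}

static Rcpp::List pack(const Weights& W) {
  Rcpp::List cw(NBLOCK), cb(NBLOCK), g(NBLOCK), be(NBLOCK), rm(NBLOCK), rv(NBLOCK);
  for (int l = 0; l < NBLOCK; ++l) {
    cw[l] = W.cw[l]; cb[l] = W.cb[l]; g[l] = W.gamma[l];
    be[l] = W.beta[l]; rm[l] = W.rmean[l]; rv[l] = W.rvar[l];
  }
  return Rcpp::List::create(
      Rcpp::Named("conv_w") = cw, Rcpp::Named("conv_b") = cb,
      Rcpp::Named("bn_gamma") = g, Rcpp::Named("bn_beta") = be,
      Rcpp::Named("bn_mean") = rm, Rcpp::Named("bn_var") = rv,
      Rcpp::Named("dense_w") = W.dw, Rcpp::Named("dense_b") = W.db);
}

// image (H x W x 3 array) -> (H*W) x 3 matrix, pixel index r*W + c
static mat image_to_mat(const Rcpp::NumericVector& img, int& H, int& W) {
  Rcpp::IntegerVector d = img.attr("dim");
  H = d[0]; W = d[1];
  const int C = d[2];
  mat A(H * W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int r = 0; r < H; ++r)
        A(r * W + w, c) = img[r + H * (w + W * c)];
  return A;
}

// forward pass in evaluation mode (running batch-norm statistics)
// [[Rcpp::export]]
Rcpp::NumericVector cnn_forward_cpp(Rcpp::List images, Rcpp::List weights) {
  Weights W = unpack(weights);
  const int N = images.size();
  Rcpp::NumericVector logits(N);
  for (int i = 0; i < N; ++i) {
    int H, Wd;
    mat A = image_to_mat(images[i], H, Wd);
    for (int l = 0; l < NBLOCK; ++l) {
      mat z = im2col3(A, H, Wd) * W.cw[l];
      z.each_row() += W.cb[l];
      rowvec sd = sqrt(W.rvar[l] + BN_EPS);
      z.each_row() -= W.rmean[l];
      z.each_row() /= sd;
      z.each_row() %= W.gamma[l];
      z.each_row() += W.beta[l];
      z.transform([](double v) { return v > 0 ? v : 0.0; });
      umat arg;
      A = maxpool2(z, H, Wd, arg);
      H /= 2; Wd /= 2;
    }
    logits[i] = dot(vectorise(A), W.dw) + W.db;
  }
  return logits;
}

struct Cache {
  int H, W;
  mat cols, xhat, relu_in;  // relu_in: post-BN pre-ReLU
  umat arg;
};

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List images, Rcpp::NumericVector labels,
                         Rcpp::List weights, Rcpp::IntegerMatrix order,
                         double lr, double alpha, double eps, int batch_size,
                         double bn_momentum) {
  Weights W = unpack(weights);
  const int N = images.size();
  const int epochs = order.nrow();

  // pre-convert images once
  std::vector<mat> data(N);
  int H0 = 0, W0 = 0;
  for (int i = 0; i < N; ++i) data[i] = image_to_mat(images[i], H0, W0);

  // RMSProp accumulators
  std::vector<mat>    v_cw;
  std::vector<rowvec> v_cb, v_g, v_b;
  for (int l = 0; l < NBLOCK; ++l) {
    v_cw.push_back(zeros<mat>(size(W.cw[l])));
    v_cb.push_back(zeros<rowvec>(W.cb[l].n_elem));
    v_g.push_back(zeros<rowvec>(W.gamma[l].n_elem));
    v_b.push_back(zeros<rowvec>(W.beta[l].n_elem));
  }
  vec v_dw = zeros<vec>(W.dw.n_elem);
  double v_db = 0.0;

  auto rms = [&](double& p, double& v, double g) {
    v = alpha * v + (1.0 - alpha) * g * g;
    p -= lr * g / (std::sqrt(v) + eps);
  };

  Rcpp::NumericVector loss_hist(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (int b0 = 0; b0 < N; b0 += batch_size) {
      const int B = std::min(batch_size, N - b0);
      std::vector<int> idx(B);
      for (int t = 0; t < B; ++t) idx[t] = order(ep, b0 + t) - 1;
      const bool batch_stats = (B >= 2);

      // ---------- forward ----------
      std::vector<std::vector<Cache>> cache(B, std::vector<Cache>(NBLOCK));
      std::vector<mat> act(B);
      std::vector<rowvec> mu(NBLOCK), sd(NBLOCK);
      for (int t = 0; t < B; ++t) act[t] = data[idx[t]];
      int H = H0, Wd = W0;
      for (int l = 0; l < NBLOCK; ++l) {
        std::vector<mat> z(B);
        for (int t = 0; t < B; ++t) {
          cache[t][l].H = H; cache[t][l].W = Wd;
          cache[t][l].cols = im2col3(act[t], H, Wd);
          z[t] = cache[t][l].cols * W.cw[l];
          z[t].each_row() += W.cb[l];
        }
        // batch statistics (population variance over batch x pixels)
        rowvec m(W.cb[l].n_elem, fill::zeros), s2(W.cb[l].n_elem, fill::zeros);
        double cnt = 0;
        for (int t = 0; t < B; ++t) { m += sum(z[t], 0); cnt += z[t].n_rows; }
        m /= cnt;
        for (int t = 0; t < B; ++t) {
          mat d = z[t]; d.each_row() -= m;
          s2 += sum(square(d), 0);
        }
        s2 /= cnt;
        W.rmean[l] = (1.0 - bn_momentum) * W.rmean[l] + bn_momentum * m;
        W.rvar[l]  = (1.0 - bn_momentum) * W.rvar[l]  + bn_momentum * s2;
        if (batch_stats) { mu[l] = m; sd[l] = sqrt(s2 + BN_EPS); }
        else             { mu[l] = W.rmean[l]; sd[l] = sqrt(W.rvar[l] + BN_EPS); }
        for (int t = 0; t < B; ++t) {
          mat xh = z[t];
          xh.each_row() -= mu[l];
          xh.each_row() /= sd[l];
          cache[t][l].xhat = xh;
          mat y = xh;
          y.each_row() %= W.gamma[l];
          y.each_row() += W.beta[l];
          cache[t][l].relu_in = y;
          y.transform([](double v) { return v > 0 ? v : 0.0; });
          act[t] = maxpool2(y, H, Wd, cache[t][l].arg);
        }
        H /= 2; Wd /= 2;
      }
      vec logit(B), dlogit(B);
      for (int t = 0; t < B; ++t) {
        const double z = dot(vectorise(act[t]), W.dw) + W.db;
        const double y = labels[idx[t]];
        logit[t] = z;
        ep_loss += (std::log1p(std::exp(-std::fabs(z))) + std::max(z, 0.0) - z * y);
        dlogit[t] = (1.0 / (1.0 + std::exp(-z)) - y) / B;
      }

      // ---------- backward ----------
      mat g_dw(W.dw.n_elem, 1, fill::zeros);
      double g_db = 0.0;
      std::vector<mat> grad(B);
      const int Hf = H, Wf = Wd;
      for (int t = 0; t < B; ++t) {
        g_dw += dlogit[t] * vectorise(act[t]);
        g_db += dlogit[t];
        vec df = dlogit[t] * W.dw;
        grad[t] = reshape(df, Hf * Wf, W.cw[NBLOCK - 1].n_cols);
      }

      std::vector<mat>    g_cw(NBLOCK);
      std::vector<rowvec> g_cb(NBLOCK), g_g(NBLOCK), g_b(NBLOCK);
      for (int l = NBLOCK - 1; l >= 0; --l) {
        const int Hl = cache[0][l].H, Wl = cache[0][l].W;
        const int C = W.cw[l].n_cols;
        g_cw[l] = zeros<mat>(size(W.cw[l]));
        g_cb[l] = zeros<rowvec>(C);
        rowvec sum_dy(C, fill::zeros), sum_dyx(C, fill::zeros);
        std::vector<mat> dy(B);
        for (int t = 0; t < B; ++t) {
          // unpool
          mat d(Hl * Wl, C, fill::zeros);
          const mat& gq = grad[t];
          const umat& arg = cache[t][l].arg;
          for (int c = 0; c < C; ++c)
            for (uword q = 0; q < gq.n_rows; ++q)
              d(arg(q, c), c) += gq(q, c);
          // ReLU
          d %= conv_to<mat>::from(cache[t][l].relu_in > 0);
          dy[t] = d;
          sum_dy  += sum(d, 0);
          sum_dyx += sum(d % cache[t][l].xhat, 0);
        }
        g_g[l] = sum_dyx;
        g_b[l] = sum_dy;
        const double Ntot = static_cast<double>(B) * Hl * Wl;
        for (int t = 0; t < B; ++t) {
          mat dz = dy[t];
          if (batch_stats) {
            dz.each_row() -= sum_dy / Ntot;
            mat corr = cache[t][l].xhat;
            corr.each_row() %= (sum_dyx / Ntot);
            dz -= corr;
          }
          dz.each_row() %= (W.gamma[l] / sd[l]);
          g_cw[l] += cache[t][l].cols.t() * dz;
          g_cb[l] += sum(dz, 0);
          if (l > 0) {
            mat dcols = dz * W.cw[l].t();
            grad[t] = col2im3(dcols, Hl, Wl, W.cw[l].n_rows / 9);
          }
        }
      }

      // ---------- RMSProp updates ----------
      for (int l = 0; l < NBLOCK; ++l) {
        v_cw[l] = alpha * v_cw[l] + (1.0 - alpha) * square(g_cw[l]);
        W.cw[l] -= lr * g_cw[l] / (sqrt(v_cw[l]) + eps);
        v_cb[l] = alpha * v_cb[l] + (1.0 - alpha) * square(g_cb[l]);
        W.cb[l] -= lr * g_cb[l] / (sqrt(v_cb[l]) + eps);
        v_g[l] = alpha * v_g[l] + (1.0 - alpha) * square(g_g[l]);
        W.gamma[l] -= lr * g_g[l] / (sqrt(v_g[l]) + eps);
        v_b[l] = alpha * v_b[l] + (1.0 - alpha) * square(g_b[l]);
        W.beta[l] -= lr * g_b[l] / (sqrt(v_b[l]) + eps);
      }
      v_dw = alpha * v_dw + (1.0 - alpha) * square(g_dw.col(0));
      W.dw -= lr * g_dw.col(0) / (sqrt(v_dw) + eps);
      rms(W.db, v_db, g_db);
      Rcpp::checkUserInterrupt();
    }
    loss_hist[ep] = ep_loss / N;
  }

  return Rcpp::List::create(Rcpp::Named("weights") = pack(W),
                            Rcpp::Named("loss_history") = loss_hist);
}
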