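// Training core for the embedding + MLP matrix-completion model.
// All randomness goes through R's RNG so results are reproducible with
// set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void leaky_inplace(arma::mat& Z, double slope) {
  Z.for_each([slope](arma::mat::elem_type& x) { if (x < 0) x *= slope; });
}

static arma::vec mlp_forward(const arma::mat& A0,
                             const std::vector<arma::mat>& Wl,
                             const std::vector<arma::vec>& bl,
                             double slope) {
  arma::mat A = A0;
  const int nl = (int)Wl.size();
  for (int l = 0; l < nl - 1; ++l) {
    arma::mat Z = A * Wl[l].t();
    Z.each_row() += bl[l].t();
    leaky_inplace(Z, slope);
    A = Z;
  }
  arma::mat out = A * Wl[nl - 1].t();
  out.each_row() += bl[nl - 1].t();
  return out.col(0);
}

static void unpack_mlp(const List& weights, const List& biases,
                       std::vector<arma::mat>& Wl, std::vector<arma::vec>& bl) {
  for (int l = 0; l < weights.size(); ++l) {
    Wl.push_back(as<arma::mat>(weights[l]));
    bl.push_back(as<arma::vec>(biases[l]));
  }
}

// Draw n_needed indices (1-based) into vals, sampling uniformly with
// replacement but accepting a candidate with value v outright only when a
// Gaussian(mu, sd) threshold draw t satisfies t >= v, and otherwise with
// probability p_bg; rejected candidates are redrawn.
// [[Rcpp::export]]
IntegerVector cpp_biased_sample(NumericVector vals, int n_needed,
                                double mu, double sd, double p_bg) {
  const int n = vals.size();
  if (n < 1) stop("no values to sample from");
  IntegerVector out(n_needed);
  for (int k = 0; k < n_needed; ++k) {
    for (;;) {
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      const double t = mu + sd * norm_rand();
      if (t >= vals[i] || unif_rand() < p_bg) { out[k] = i + 1; break; }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_predict_all(const arma::mat& W, const arma::mat& H,
                          List weights, List biases, double slope) {
  std::vector<arma::mat> Wl; std::vector<arma::vec> bl;
  unpack_mlp(weights, biases, Wl, bl);
  const int n = W.n_rows, m = H.n_cols, p = W.n_cols, q = H.n_rows;
  arma::mat out(n, m);
  arma::mat A0(n, p + q);
  A0.cols(0, p - 1) = W;
  for (int j = 0; j < m; ++j) {
    A0.cols(p, p + q - 1) = arma::repmat(H.col(j).t(), n, 1);
    out.col(j) = mlp_forward(A0, Wl, bl, slope);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_forward_pairs(const arma::mat& W, const arma::mat& H,
                                List weights, List biases, double slope,
                                IntegerVector rows, IntegerVector cols) {
  std::vector<arma::mat> Wl; std::vector<arma::vec> bl;
  unpack_mlp(weights, biases, Wl, bl);
  const int p = W.n_cols, q = H.n_rows;
  const int n_pairs = rows.size();
  NumericVector out(n_pairs);
  const int chunk = 8192;
  for (int s = 0; s < n_pairs; s += chunk) {
    const int e = std::min(s + chunk, n_pairs);
    arma::mat A0(e - s, p + q);
    for (int k = s; k < e; ++k) {
      A0.submat(k - s, 0, k - s, p - 1) = W.row(rows[k]);
      A0.submat(k - s, p, k - s, p + q - 1) = H.col(cols[k]).t();
    }
    arma::vec pred = mlp_forward(A0, Wl, bl, slope);
    for (int k = s; k < e; ++k) out[k] = pred[k - s];
  }
  return out;
}

struct Adam {
  arma::mat m, v;
  Adam(int r, int c) : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
  void step_dense(arma::mat& param, const arma::mat& g,
                  double lr, long t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    param -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
  // Sparse variant for embedding tables: only the listed rows carry gradient,
  // and only their moments are advanced (bias correction uses the global
  // step count).
  void step_rows(arma::mat& param, const arma::mat& g,
                 const std::vector<int>& rows, double lr, long t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (int r : rows) {
      m.row(r) = b1 * m.row(r) + (1 - b1) * g.row(r);
      v.row(r) = b2 * v.row(r) + (1 - b2) * (g.row(r) % g.row(r));
      param.row(r) -= lr * (m.row(r) / c1) / (arma::sqrt(v.row(r) / c2) + eps);
    }
  }
};

// Full training loop: biased batches, Adam, per-epoch validation MSE, and an
// R-side stopping decision (conv_fun receives the trace so far and returns
// list(stop=, reason=)).
// [[Rcpp::export]]
List cpp_train(arma::mat W, arma::mat H, List weights, List biases,
               NumericVector train_vals, IntegerVector train_rows,
               IntegerVector train_cols,
               NumericVector val_vals, IntegerVector val_rows,
               IntegerVector val_cols,
               double lr, int batch_size, int max_epochs, double slope,
               double thr_mu, double thr_sd, double p_bg,
               bool rollback_best, Function conv_fun) {
  std::vector<arma::mat> Wl; std::vector<arma::vec> bl;
  unpack_mlp(weights, biases, Wl, bl);
  const int nl = (int)Wl.size();
  const int p = W.n_cols, q = H.n_rows;
  const int n_train = train_vals.size();
  if (n_train < 1) stop("no training entries");
  const int n_batches = (n_train + batch_size - 1) / batch_size;

  Adam adW(W.n_rows, W.n_cols), adH(H.n_rows, H.n_cols);
  std::vector<Adam> adWl, adbl;
  for (int l = 0; l < nl; ++l) {
    adWl.emplace_back(Wl[l].n_rows, Wl[l].n_cols);
    adbl.emplace_back(bl[l].n_elem, 1);
  }

  arma::mat gW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat gHt(H.n_cols, H.n_rows, arma::fill::zeros); // transposed: rows = samples
  std::vector<char> touchedW(W.n_rows, 0), touchedH(H.n_cols, 0);

  std::vector<double> trace;
  std::string stop_reason = "max_epochs";
  long t = 0;
  double best_mse = R_PosInf;
  arma::mat bestW, bestH;
  std::vector<arma::mat> bestWl;
  std::vector<arma::vec> bestbl;

  std::vector<arma::mat> acts(nl), D(nl > 1 ? nl - 1 : 0);
  std::vector<arma::mat> gWl(nl); std::vector<arma::vec> gbl(nl);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    for (int b = 0; b < n_batches; ++b) {
      // biased batch selection (sampling with replacement)
      arma::mat A0(batch_size, p + q);
      arma::vec y(batch_size);
      std::vector<int> bi(batch_size), bj(batch_size);
      for (int k = 0; k < batch_size; ++k) {
        int idx;
        for (;;) {
          idx = (int)(unif_rand() * n_train);
          if (idx >= n_train) idx = n_train - 1;
          const double thr = thr_mu + thr_sd * norm_rand();
          if (thr >= train_vals[idx] || unif_rand() < p_bg) break;
        }
        bi[k] = train_rows[idx]; bj[k] = train_cols[idx];
        y[k] = train_vals[idx];
        A0.submat(k, 0, k, p - 1) = W.row(bi[k]);
        A0.submat(k, p, k, p + q - 1) = H.col(bj[k]).t();
      }
      // forward, keeping activations and leaky-ReLU derivative masks
      acts[0] = A0;
      for (int l = 0; l < nl - 1; ++l) {
        arma::mat Z = acts[l] * Wl[l].t();
        Z.each_row() += bl[l].t();
        D[l] = arma::conv_to<arma::mat>::from(Z >= 0);
        D[l].transform([slope](double d) { return d > 0.5 ? 1.0 : slope; });
        leaky_inplace(Z, slope);
        acts[l + 1] = Z;
      }
      arma::vec yhat = acts[nl - 1] * Wl[nl - 1].t() + bl[nl - 1][0];
      arma::vec dy = 2.0 * (yhat - y) / (double)batch_size;

      // backward
      gWl[nl - 1] = dy.t() * acts[nl - 1];
      gbl[nl - 1] = arma::vec(1);
      gbl[nl - 1][0] = arma::accu(dy);
      arma::mat dA0;
      if (nl == 1) {
        dA0 = dy * Wl[0];
      } else {
        arma::mat delta = (dy * Wl[nl - 1]) % D[nl - 2];
        for (int l = nl - 2; l >= 0; --l) {
          gWl[l] = delta.t() * acts[l];
          gbl[l] = arma::sum(delta, 0).t();
          if (l > 0) delta = (delta * Wl[l]) % D[l - 1];
          else dA0 = delta * Wl[0];
        }
      }

      // scatter entry gradients into the embedding tables
      std::vector<int> rowsW, colsH;
      for (int k = 0; k < batch_size; ++k) {
        if (!touchedW[bi[k]]) { touchedW[bi[k]] = 1; rowsW.push_back(bi[k]); }
        if (!touchedH[bj[k]]) { touchedH[bj[k]] = 1; colsH.push_back(bj[k]); }
        gW.row(bi[k]) += dA0.submat(k, 0, k, p - 1);
        gHt.row(bj[k]) += dA0.submat(k, p, k, p + q - 1);
      }

      ++t;
      for (int l = 0; l < nl; ++l) {
        adWl[l].step_dense(Wl[l], gWl[l], lr, t);
        arma::mat gb(gbl[l]);
        arma::mat blm(bl[l]);
        adbl[l].step_dense(blm, gb, lr, t);
        bl[l] = blm.col(0);
      }
      adW.step_rows(W, gW, rowsW, lr, t);
      { // H moments are stored q x m; the gradient buffer is transposed
        const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
        const double c1 = 1.0 - std::pow(b1, (double)t);
        const double c2 = 1.0 - std::pow(b2, (double)t);
        for (int j : colsH) {
          arma::rowvec g = gHt.row(j);
          adH.m.col(j) = b1 * adH.m.col(j) + (1 - b1) * g.t();
          adH.v.col(j) = b2 * adH.v.col(j) + (1 - b2) * (g.t() % g.t());
          H.col(j) -= lr * (adH.m.col(j) / c1) /
                      (arma::sqrt(adH.v.col(j) / c2) + eps);
        }
      }
      for (int r : rowsW) { gW.row(r).zeros(); touchedW[r] = 0; }
      for (int j : colsH) { gHt.row(j).zeros(); touchedH[j] = 0; }
    }

    // validation MSE
    double sse = 0.0;
    const int n_val = val_vals.size();
    const int chunk = 8192;
    for (int s = 0; s < n_val; s += chunk) {
      const int e = std::min(s + chunk, n_val);
      arma::mat A0(e - s, p + q);
      for (int k = s; k < e; ++k) {
        A0.submat(k - s, 0, k - s, p - 1) = W.row(val_rows[k]);
        A0.submat(k - s, p, k - s, p + q - 1) = H.col(val_cols[k]).t();
      }
      arma::vec pred = mlp_forward(A0, Wl, bl, slope);
      for (int k = s; k < e; ++k) {
        const double r = pred[k - s] - val_vals[k];
        sse += r * r;
      }
    }
    trace.push_back(sse / (double)n_val);
    if (rollback_best && trace.back() < best_mse) {
      best_mse = trace.back();
      bestW = W; bestH = H; bestWl = Wl; bestbl = bl;
    }

    List decision = conv_fun(wrap(trace));
    if (as<bool>(decision["stop"])) {
      stop_reason = as<std::string>(decision["reason"]);
      break;
    }
  }

  if (rollback_best && bestW.n_elem > 0) {
    W = bestW; H = bestH; Wl = bestWl; bl = bestbl;
  }
  List outW(nl), outb(nl);
  for (int l = 0; l < nl; ++l) { outW[l] = Wl[l]; outb[l] = bl[l]; }
  return List::create(_["W"] = W, _["H"] = H,
                      _["weights"] = outW, _["biases"] = outb,
                      _["trace"] = trace, _["stop_reason"] = stop_reason,
                      _["epochs"] = (int)trace.size());
}
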