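// Inference-only forward pass of the rank-encoding transformer encoder.
// Mirrors the R training implementation (pre-LN attention + ReLU
// feed-forward blocks, final LayerNorm, mean pooling over real
// positions); cells are processed independently, so results are
// batch-invariant by construction. Kept in C++ because the perturbation
// scan embeds tens of thousands of perturbed cells.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LN_EPS = 1e-5;

static arma::mat layer_norm(const arma::mat& X, const arma::rowvec& g,
                            const arma::rowvec& b) {
  arma::colvec mu = arma::mean(X, 1);
  arma::mat xc = X.each_col() - mu;
  arma::colvec invstd = 1.0 / arma::sqrt(arma::mean(arma::square(xc), 1) + LN_EPS);
  arma::mat xhat = xc.each_col() % invstd;
  xhat.each_row() %= g;
  xhat.each_row() += b;
  return xhat;
}

// [[Rcpp::export]]
arma::mat cpp_encode_pool(List params, List dims, List tokens) {
  const int nLayers = as<int>(dims["nLayers"]);
  const int nHeads = as<int>(dims["nHeads"]);
  const int d = as<int>(dims["hiddenDim"]);
  const int dh = d / nHeads;
  const double scale = 1.0 / std::sqrt((double)dh);

  arma::mat tokEmb = as<arma::mat>(params["tok"]);
  arma::mat posEmb = as<arma::mat>(params["pos"]);
  std::vector<arma::mat> Wq(nLayers), Wk(nLayers), Wv(nLayers), Wo(nLayers),
      W1(nLayers), W2(nLayers);
  std::vector<arma::rowvec> bq(nLayers), bk(nLayers), bv(nLayers),
      bo(nLayers), b1(nLayers), b2(nLayers), ln1g(nLayers), ln1b(nLayers),
      ln2g(nLayers), ln2b(nLayers);
  for (int l = 0; l < nLayers; ++l) {
    std::string pre = "l" + std::to_string(l + 1) + "_";
    Wq[l] = as<arma::mat>(params[pre + "Wq"]);
    Wk[l] = as<arma::mat>(params[pre + "Wk"]);
    Wv[l] = as<arma::mat>(params[pre + "Wv"]);
    Wo[l] = as<arma::mat>(params[pre + "Wo"]);
    W1[l] = as<arma::mat>(params[pre + "W1"]);
    W2[l] = as<arma::mat>(params[pre + "W2"]);
    bq[l] = as<arma::rowvec>(params[pre + "bq"]);
    bk[l] = as<arma::rowvec>(params[pre + "bk"]);
    bv[l] = as<arma::rowvec>(params[pre + "bv"]);
    bo[l] = as<arma::rowvec>(params[pre + "bo"]);
    b1[l] = as<arma::rowvec>(params[pre + "b1"]);
    b2[l] = as<arma::rowvec>(params[pre + "b2"]);
    ln1g[l] = as<arma::rowvec>(params[pre + "ln1g"]);
    ln1b[l] = as<arma::rowvec>(params[pre + "ln1b"]);
    ln2g[l] = as<arma::rowvec>(params[pre + "ln2g"]);
    ln2b[l] = as<arma::rowvec>(params[pre + "ln2b"]);
  }
  arma::rowvec lnfg = as<arma::rowvec>(params["lnfg"]);
  arma::rowvec lnfb = as<arma::rowvec>(params["lnfb"]);

  const int B = tokens.size();
  arma::mat pooled(B, d);

  for (int c = 0; c < B; ++c) {
    IntegerVector tk = tokens[c];
    const int len = tk.size();
    if (len == 0) stop("empty encoding cannot be embedded");
    if ((unsigned)len > posEmb.n_rows)
      stop("encoding longer than the model context length");
    arma::mat X(len, d);
    for (int t = 0; t < len; ++t)
      X.row(t) = tokEmb.row(tk[t]) + posEmb.row(t);
    for (int l = 0; l < nLayers; ++l) {
      arma::mat h1 = layer_norm(X, ln1g[l], ln1b[l]);
      arma::mat Q = h1 * Wq[l]; Q.each_row() += bq[l];
      arma::mat K = h1 * Wk[l]; K.each_row() += bk[l];
      arma::mat V = h1 * Wv[l]; V.each_row() += bv[l];
      arma::mat O(len, d);
      for (int h = 0; h < nHeads; ++h) {
        arma::span hc(h * dh, (h + 1) * dh - 1);
        arma::mat S = Q.cols(hc) * K.cols(hc).t() * scale;
        S -= S.max();
        arma::mat E = arma::exp(S);
        E.each_col() /= arma::sum(E, 1);
        O.cols(hc) = E * V.cols(hc);
      }
      arma::mat attn = O * Wo[l]; attn.each_row() += bo[l];
      X += attn;
      arma::mat h2 = layer_norm(X, ln2g[l], ln2b[l]);
      arma::mat A1 = h2 * W1[l]; A1.each_row() += b1[l];
      A1.transform([](double x) { return x > 0 ? x : 0.0; });
      arma::mat F2 = A1 * W2[l]; F2.each_row() += b2[l];
      X += F2;
    }
    arma::mat H = layer_norm(X, lnfg, lnfb);
    pooled.row(c) = arma::mean(H, 0);
  }
  return pooled;
}
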