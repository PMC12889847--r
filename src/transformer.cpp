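// Cross-attention readout: forward and backward passes.
//
// One decoder "layer" in the DETR sense: learned queries (one per ROI or per
// vertex mask), a single cross-attention over image tokens (keys = projected
// tokens + positional encodings, values = projected tokens), a feedforward
// block, pre-norm residual ordering, then a per-query linear readout whose
// output is scattered to the query's masked vertices. Gradients are exact
// analytic backprop; the Adam loop lives in R. Work is blocked per stimulus,
// which keeps every intermediate cache-resident at typical sizes.
//
// Shapes: tokens cube X is (n_tokens x d x batch); params are R matrices.
// `owner` maps each vertex (1-based) to the unique query whose mask holds it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;

struct LnCache {
  arma::mat xhat;
  arma::vec inv_sd;
};

static arma::mat ln_forward(const arma::mat& x, const arma::vec& g,
                            const arma::vec& b, LnCache& cache) {
  arma::vec mu = arma::mean(x, 1);
  arma::mat xc = x.each_col() - mu;
  arma::vec var = arma::mean(arma::square(xc), 1);
  cache.inv_sd = 1.0 / arma::sqrt(var + LN_EPS);
  cache.xhat = xc.each_col() % cache.inv_sd;
  arma::mat out = cache.xhat;
  out.each_row() %= g.t();
  out.each_row() += b.t();
  return out;
}

static arma::mat ln_backward(const arma::mat& dy, const arma::vec& g,
                             const LnCache& cache, arma::vec& dg,
                             arma::vec& db) {
  dg += arma::sum(dy % cache.xhat, 0).t();
  db += arma::sum(dy, 0).t();
  arma::mat dxhat = dy.each_row() % g.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % cache.xhat, 1);
  arma::mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= cache.xhat.each_col() % m2;
  dx.each_col() %= cache.inv_sd;
  return dx;
}

static arma::mat softmax_rows(const arma::mat& logits) {
  arma::mat z = logits.each_col() - arma::max(logits, 1);
  z = arma::exp(z);
  z.each_col() /= arma::sum(z, 1);
  return z;
}

struct Params {
  arma::mat Q, W1, W2, Wout, Win, Wq, Wk, Wv, Wo;
  arma::vec g1, b1, g2, b2, g3, b3, bh, b2f, bout, bin, bq, bk, bv, bo;
  bool use_proj;
  int n_heads;
};

static Params unpack(const List& par) {
  Params p;
  p.Q = as<arma::mat>(par["Q"]);
  p.g1 = as<arma::vec>(par["g1"]); p.b1 = as<arma::vec>(par["b1"]);
  p.g2 = as<arma::vec>(par["g2"]); p.b2 = as<arma::vec>(par["b2"]);
  p.g3 = as<arma::vec>(par["g3"]); p.b3 = as<arma::vec>(par["b3"]);
  p.W1 = as<arma::mat>(par["W1"]); p.bh = as<arma::vec>(par["bh"]);
  p.W2 = as<arma::mat>(par["W2"]); p.b2f = as<arma::vec>(par["b2f"]);
  p.Wout = as<arma::mat>(par["Wout"]); p.bout = as<arma::vec>(par["bout"]);
  p.Wq = as<arma::mat>(par["Wq"]); p.bq = as<arma::vec>(par["bq"]);
  p.Wk = as<arma::mat>(par["Wk"]); p.bk = as<arma::vec>(par["bk"]);
  p.Wv = as<arma::mat>(par["Wv"]); p.bv = as<arma::vec>(par["bv"]);
  p.Wo = as<arma::mat>(par["Wo"]); p.bo = as<arma::vec>(par["bo"]);
  p.use_proj = as<bool>(par["use_proj"]);
  if (p.use_proj) {
    p.Win = as<arma::mat>(par["Win"]);
    p.bin = as<arma::vec>(par["bin"]);
  }
  p.n_heads = as<int>(par["n_heads"]);
  return p;
}

// Per-stimulus forward intermediates needed by backward.
struct FwdCache {
  arma::mat Xp, K0, Kp, Vp, Ho;
  std::vector<arma::mat> Ah;   // per-head attention (m x n)
  arma::mat C, U, Un, Hpre, H, G, Gn;
  LnCache ln2, ln3;
};

// Qp = (LN1(Q)) Wq + bq, shared across the batch; computed by the caller.
static arma::rowvec forward_one(const Params& p, const arma::mat& Qp,
                                const arma::mat& X, const arma::mat& P,
                                const arma::ivec& owner, FwdCache& fc) {
  const int m = p.Q.n_rows, dm = p.Q.n_cols;
  fc.Xp = p.use_proj ? arma::mat(X * p.Win) : X;
  if (p.use_proj) fc.Xp.each_row() += p.bin.t();
  fc.K0 = fc.Xp + P;
  fc.Kp = fc.K0 * p.Wk;
  fc.Kp.each_row() += p.bk.t();
  fc.Vp = fc.Xp * p.Wv;
  fc.Vp.each_row() += p.bv.t();
  const int h = p.n_heads, dk = dm / h;
  const double scale = 1.0 / std::sqrt((double)dk);
  fc.Ho.set_size(m, dm);
  fc.Ah.resize(h);
  for (int i = 0; i < h; ++i) {
    arma::span cols(i * dk, (i + 1) * dk - 1);
    arma::mat logits = Qp.cols(cols) * fc.Kp.cols(cols).t() * scale;
    fc.Ah[i] = softmax_rows(logits);
    fc.Ho.cols(cols) = fc.Ah[i] * fc.Vp.cols(cols);
  }
  fc.C = fc.Ho * p.Wo;
  fc.C.each_row() += p.bo.t();
  fc.U = p.Q + fc.C;
  fc.Un = ln_forward(fc.U, p.g2, p.b2, fc.ln2);
  fc.Hpre = fc.Un * p.W1;
  fc.Hpre.each_row() += p.bh.t();
  fc.H = arma::clamp(fc.Hpre, 0.0, arma::datum::inf);  // ReLU
  fc.G = fc.U + fc.H * p.W2;
  fc.G.each_row() += p.b2f.t();
  fc.Gn = ln_forward(fc.G, p.g3, p.b3, fc.ln3);
  const int V = owner.n_elem;
  arma::rowvec pred(V);
  for (int v = 0; v < V; ++v)
    pred(v) = arma::dot(fc.Gn.row(owner(v) - 1), p.Wout.col(v)) + p.bout(v);
  return pred;
}

// [[Rcpp::export(name = ".attn_forward_cpp")]]
List attn_forward_cpp(const arma::cube& tokens, const List& params,
                      const arma::mat& P, const arma::ivec& owner,
                      bool return_attention) {
  Params p = unpack(params);
  LnCache ln1;
  arma::mat Qn = ln_forward(p.Q, p.g1, p.b1, ln1);
  arma::mat Qp = Qn * p.Wq;
  Qp.each_row() += p.bq.t();
  const int B = tokens.n_slices, V = owner.n_elem;
  const int m = p.Q.n_rows, n = tokens.n_rows;
  arma::mat pred(B, V);
  arma::cube attn;
  if (return_attention) attn.set_size(m, n, B);
  FwdCache fc;
  for (int s = 0; s < B; ++s) {
    pred.row(s) = forward_one(p, Qp, tokens.slice(s), P, owner, fc);
    if (return_attention) {
      arma::mat a(m, n, arma::fill::zeros);
      for (int i = 0; i < p.n_heads; ++i) a += fc.Ah[i];
      attn.slice(s) = a / p.n_heads;
    }
  }
  if (return_attention)
    return List::create(_["pred"] = pred, _["attention"] = attn);
  return List::create(_["pred"] = pred);
}

// [[Rcpp::export(name = ".attn_grad_cpp")]]
List attn_grad_cpp(const arma::cube& tokens, const arma::mat& targets,
                   const List& params, const arma::mat& P,
                   const arma::ivec& owner) {
  Params p = unpack(params);
  LnCache ln1;
  arma::mat Qn = ln_forward(p.Q, p.g1, p.b1, ln1);
  arma::mat Qp = Qn * p.Wq;
  Qp.each_row() += p.bq.t();
  const int B = tokens.n_slices, V = owner.n_elem;
  const int m = p.Q.n_rows, dm = p.Q.n_cols;
  const int h = p.n_heads, dk = dm / h;
  const double scale = 1.0 / std::sqrt((double)dk);

  arma::mat dQ(m, dm, arma::fill::zeros), dQp(m, dm, arma::fill::zeros);
  arma::mat dWq(dm, dm, arma::fill::zeros), dWk(dm, dm, arma::fill::zeros);
  arma::mat dWv(dm, dm, arma::fill::zeros), dWo(dm, dm, arma::fill::zeros);
  arma::vec dbq(dm, arma::fill::zeros), dbk(dm, arma::fill::zeros);
  arma::vec dbv(dm, arma::fill::zeros), dbo(dm, arma::fill::zeros);
  arma::vec dg1(dm, arma::fill::zeros), db1(dm, arma::fill::zeros);
  arma::vec dg2(dm, arma::fill::zeros), db2(dm, arma::fill::zeros);
  arma::vec dg3(dm, arma::fill::zeros), db3(dm, arma::fill::zeros);
  arma::mat dW1(arma::size(p.W1), arma::fill::zeros);
  arma::vec dbh(p.bh.n_elem, arma::fill::zeros);
  arma::mat dW2(arma::size(p.W2), arma::fill::zeros);
  arma::vec db2f(dm, arma::fill::zeros);
  arma::mat dWout(arma::size(p.Wout), arma::fill::zeros);
  arma::vec dbout(V, arma::fill::zeros);
  arma::mat dWin; arma::vec dbin;
  if (p.use_proj) {
    dWin.zeros(arma::size(p.Win));
    dbin.zeros(p.bin.n_elem);
  }

  double loss = 0.0;
  const double denom = (double)B * (double)V;
  FwdCache fc;
  for (int s = 0; s < B; ++s) {
    const arma::mat& X = tokens.slice(s);
    arma::rowvec pred = forward_one(p, Qp, X, P, owner, fc);
    arma::rowvec err = pred - targets.row(s);
    loss += arma::dot(err, err);
    arma::rowvec dpred = 2.0 * err / denom;

    // readout
    arma::mat dGn(m, dm, arma::fill::zeros);
    for (int v = 0; v < V; ++v) {
      const int q = owner(v) - 1;
      dWout.col(v) += fc.Gn.row(q).t() * dpred(v);
      dbout(v) += dpred(v);
      dGn.row(q) += dpred(v) * p.Wout.col(v).t();
    }
    arma::mat dG = ln_backward(dGn, p.g3, fc.ln3, dg3, db3);

    // feedforward block
    arma::mat dU = dG;
    arma::mat dH = dG * p.W2.t();
    dW2 += fc.H.t() * dG;
    db2f += arma::sum(dG, 0).t();
    arma::mat dHpre = dH % arma::conv_to<arma::mat>::from(fc.Hpre > 0);
    dW1 += fc.Un.t() * dHpre;
    dbh += arma::sum(dHpre, 0).t();
    arma::mat dUn = dHpre * p.W1.t();
    dU += ln_backward(dUn, p.g2, fc.ln2, dg2, db2);

    // residual: U = Q + C
    dQ += dU;
    const arma::mat& dC = dU;

    // attention output projection: C = Ho Wo + bo
    dWo += fc.Ho.t() * dC;
    dbo += arma::sum(dC, 0).t();
    arma::mat dHo = dC * p.Wo.t();

    // scaled dot-product attention per head
    arma::mat dKp(X.n_rows, dm, arma::fill::zeros);
    arma::mat dVp(X.n_rows, dm, arma::fill::zeros);
    for (int i = 0; i < h; ++i) {
      arma::span cols(i * dk, (i + 1) * dk - 1);
      const arma::mat& A = fc.Ah[i];
      arma::mat dA = dHo.cols(cols) * fc.Vp.cols(cols).t();
      dVp.cols(cols) += A.t() * dHo.cols(cols);            // value path
      arma::vec rs = arma::sum(dA % A, 1);
      arma::mat dL = (A % (dA.each_col() - rs)) * scale;
      dQp.cols(cols) += dL * fc.Kp.cols(cols);
      dKp.cols(cols) += dL.t() * Qp.cols(cols);            // key path
    }
    // key/value projections: Kp = (Xp + P) Wk + bk, Vp = Xp Wv + bv
    dWk += fc.K0.t() * dKp;
    dbk += arma::sum(dKp, 0).t();
    dWv += fc.Xp.t() * dVp;
    dbv += arma::sum(dVp, 0).t();
    if (p.use_proj) {
      arma::mat dXp = dKp * p.Wk.t() + dVp * p.Wv.t();
      dWin += X.t() * dXp;
      dbin += arma::sum(dXp, 0).t();
    }
  }
  // query projection: Qp = LN1(Q) Wq + bq (shared across the batch)
  dWq = Qn.t() * dQp;
  dbq = arma::sum(dQp, 0).t();
  dQ += ln_backward(dQp * p.Wq.t(), p.g1, ln1, dg1, db1);
  loss /= denom;

  List grads = List::create(
    _["Q"] = dQ, _["g1"] = dg1, _["b1"] = db1, _["g2"] = dg2, _["b2"] = db2,
    _["g3"] = dg3, _["b3"] = db3, _["W1"] = dW1, _["bh"] = dbh,
    _["W2"] = dW2, _["b2f"] = db2f, _["Wout"] = dWout, _["bout"] = dbout);
  grads["Wq"] = dWq; grads["bq"] = dbq;
  grads["Wk"] = dWk; grads["bk"] = dbk;
  grads["Wv"] = dWv; grads["bv"] = dbv;
  grads["Wo"] = dWo; grads["bo"] = dbo;
  if (p.use_proj) {
    grads["Win"] = dWin;
    grads["bin"] = dbin;
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// ---------------- spatial-feature factorized readout ----------------
// Stimulus-independent spatial softmax per query pools the tokens; a linear
// feature map then predicts the query's masked vertices.

// [[Rcpp::export(name = ".factorized_forward_cpp")]]
arma::mat factorized_forward_cpp(const arma::cube& tokens, const arma::mat& S,
                                 const arma::mat& Wf, const arma::vec& bout,
                                 const arma::ivec& owner) {
  arma::mat Wsp = softmax_rows(S);
  const int B = tokens.n_slices, V = owner.n_elem;
  arma::mat pred(B, V);
  for (int s = 0; s < B; ++s) {
    arma::mat pooled = Wsp * tokens.slice(s);   // m x d
    for (int v = 0; v < V; ++v)
      pred(s, v) = arma::dot(pooled.row(owner(v) - 1), Wf.col(v)) + bout(v);
  }
  return pred;
}

// [[Rcpp::export(name = ".factorized_grad_cpp")]]
List factorized_grad_cpp(const arma::cube& tokens, const arma::mat& targets,
                         const arma::mat& S, const arma::mat& Wf,
                         const arma::vec& bout, const arma::ivec& owner) {
  arma::mat Wsp = softmax_rows(S);
  const int B = tokens.n_slices, V = owner.n_elem;
  const int m = S.n_rows;
  arma::mat dWsp(arma::size(Wsp), arma::fill::zeros);
  arma::mat dWf(arma::size(Wf), arma::fill::zeros);
  arma::vec dbout(V, arma::fill::zeros);
  double loss = 0.0;
  const double denom = (double)B * (double)V;
  for (int s = 0; s < B; ++s) {
    const arma::mat& X = tokens.slice(s);
    arma::mat pooled = Wsp * X;
    arma::mat dpooled(m, X.n_cols, arma::fill::zeros);
    for (int v = 0; v < V; ++v) {
      const int q = owner(v) - 1;
      double e = arma::dot(pooled.row(q), Wf.col(v)) + bout(v) - targets(s, v);
      loss += e * e;
      double dp = 2.0 * e / denom;
      dWf.col(v) += pooled.row(q).t() * dp;
      dbout(v) += dp;
      dpooled.row(q) += dp * Wf.col(v).t();
    }
    dWsp += dpooled * X.t();
  }
  arma::vec rs = arma::sum(dWsp % Wsp, 1);
  arma::mat dS = Wsp % (dWsp.each_col() - rs);
  loss /= denom;
  return List::create(_["loss"] = loss,
                      _["grads"] = List::create(_["S"] = dS, _["Wf"] = dWf,
                                                _["bout"] = dbout));
}
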