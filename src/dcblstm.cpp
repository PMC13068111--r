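// Densely connected bidirectional LSTM core: batched forward pass and full
// backpropagation through time. Parameters travel as one flat vector so the
// R-side optimiser (Adam) can treat the model as a plain numeric vector.
//
// Flat layout, in order, for blocks j = 1..n (input width D_1 = 1,
// D_j = 2H for j >= 2), each block holding a forward and a backward
// direction:
//   W (4H x D_j), U (4H x H), b (4H)   [forward direction]
//   W (4H x D_j), U (4H x H), b (4H)   [backward direction]
// followed by the shared regression head: w (2H), b0 (1).
// Gate order inside the 4H axis: input, forget, candidate, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirCache {
  cube gates; // 4H x B x T, post-activation (i, f, g, o)
  cube C;     // H x B x T cell states
  cube Hs;    // H x B x T hidden states
};

// One LSTM direction over the whole batch. rev = true processes time
// back-to-front (the "backward" half of a BiLSTM).
static void lstm_dir_forward(const mat& W, const mat& U, const vec& b,
                             const cube& X, bool rev, DirCache& cc) {
  const uword D = X.n_rows, B = X.n_cols, T = X.n_slices, H = U.n_cols;
  cc.gates.set_size(4 * H, B, T);
  cc.C.set_size(H, B, T);
  cc.Hs.set_size(H, B, T);
  // input contribution for every time step in one GEMM
  cube Zin(4 * H, B, T);
  {
    const mat Xm(const_cast<double*>(X.memptr()), D, B * T, false, true);
    mat Zm(Zin.memptr(), 4 * H, B * T, false, true);
    Zm = W * Xm;
  }
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    const uword t = rev ? (T - 1 - s) : s;
    mat z = Zin.slice(t) + U * h;
    z.each_col() += b;
    mat gi = sigm(z.rows(0, H - 1));
    mat gf = sigm(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigm(z.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    cc.gates.slice(t) = join_cols(join_cols(gi, gf), join_cols(gg, go));
    cc.C.slice(t) = c;
    cc.Hs.slice(t) = h;
  }
}

// BPTT for one direction. dHout holds dLoss/dh_t; accumulates into the
// parameter gradients and into dX (gradient w.r.t. this block's input).
static void lstm_dir_backward(const mat& W, const mat& U, const cube& X,
                              bool rev, const DirCache& cc, const cube& dHout,
                              mat& dW, mat& dU, vec& db, cube& dX) {
  const uword D = X.n_rows, B = X.n_cols, T = X.n_slices, H = U.n_cols;
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  cube DZ(4 * H, B, T);       // pre-activation gate gradients, all steps
  cube Hprev(H, B, T);        // hidden state at the previous processed step
  for (uword s = T; s-- > 0;) { // reverse of processing order
    const uword t = rev ? (T - 1 - s) : s;
    const mat& G = cc.gates.slice(t);
    mat gi = G.rows(0, H - 1);
    mat gf = G.rows(H, 2 * H - 1);
    mat gg = G.rows(2 * H, 3 * H - 1);
    mat go = G.rows(3 * H, 4 * H - 1);
    mat tc = tanh(cc.C.slice(t));
    mat cprev(H, B, fill::zeros);
    if (s > 0) {
      const uword tprev = rev ? (t + 1) : (t - 1);
      cprev = cc.C.slice(tprev);
      Hprev.slice(t) = cc.Hs.slice(tprev);
    } else {
      Hprev.slice(t).zeros();
    }
    mat dh = dHout.slice(t) + dh_next;
    mat dgo = dh % tc;
    mat dc = dh % go % (1.0 - tc % tc) + dc_next;
    mat dgi = dc % gg;
    mat dgg = dc % gi;
    mat dgf = dc % cprev;
    dc_next = dc % gf;
    mat dz = join_cols(join_cols(dgi % gi % (1.0 - gi), dgf % gf % (1.0 - gf)),
                       join_cols(dgg % (1.0 - gg % gg), dgo % go % (1.0 - go)));
    DZ.slice(t) = dz;
    dh_next = U.t() * dz;
  }
  // parameter and input gradients as single GEMMs over all steps
  const mat DZm(DZ.memptr(), 4 * H, B * T, false, true);
  const mat Xm(const_cast<double*>(X.memptr()), D, B * T, false, true);
  const mat Hm(Hprev.memptr(), H, B * T, false, true);
  dW += DZm * Xm.t();
  dU += DZm * Hm.t();
  db += sum(DZm, 1);
  mat dXm(dX.memptr(), D, B * T, false, true);
  dXm += W.t() * DZm;
}

struct BlockView { // non-owning views into the flat parameter vector
  mat Wf, Uf, Wb, Ub;
  vec bf, bb;
};

static uword block_in_width(uword j, uword H) { return j == 0 ? 1 : 2 * H; }

static std::vector<BlockView> map_params(double* p, uword n_blocks, uword H,
                                         vec& head_w, double*& head_b) {
  std::vector<BlockView> bl(n_blocks);
  double* q = p;
  for (uword j = 0; j < n_blocks; ++j) {
    const uword D = block_in_width(j, H);
    bl[j].Wf = mat(q, 4 * H, D, false, true); q += 4 * H * D;
    bl[j].Uf = mat(q, 4 * H, H, false, true); q += 4 * H * H;
    bl[j].bf = vec(q, 4 * H, false, true);    q += 4 * H;
    bl[j].Wb = mat(q, 4 * H, D, false, true); q += 4 * H * D;
    bl[j].Ub = mat(q, 4 * H, H, false, true); q += 4 * H * H;
    bl[j].bb = vec(q, 4 * H, false, true);    q += 4 * H;
  }
  head_w = vec(q, 2 * H, false, true); q += 2 * H;
  head_b = q;
  return bl;
}

// [[Rcpp::export]]
int dcblstm_n_params(int n_blocks, int H) {
  uword n = 0;
  for (uword j = 0; j < (uword)n_blocks; ++j) {
    const uword D = block_in_width(j, (uword)H);
    n += 2 * (4 * H * D + 4 * H * H + 4 * H);
  }
  return (int)(n + 2 * H + 1);
}

struct ForwardState {
  std::vector<cube> inputs;   // per-block input, D_j x B x T
  std::vector<cube> outputs;  // per-block output, 2H x B x T
  std::vector<DirCache> cf, cb;
  cube fused;                 // head input, 2H x B x T
};

// conn: 0 = stacked (single is its 1-block case), 1 = dense summation
static void model_forward(const std::vector<BlockView>& bl, const vec& head_w,
                          double head_b, const mat& Xin, int conn,
                          ForwardState& st, mat& pred) {
  const uword T = Xin.n_rows, B = Xin.n_cols;
  const uword n = bl.size(), H = bl[0].Uf.n_cols;
  st.inputs.resize(n);
  st.outputs.resize(n);
  st.cf.resize(n);
  st.cb.resize(n);
  cube x0(1, B, T);
  for (uword t = 0; t < T; ++t) x0.slice(t) = Xin.row(t);
  cube run_sum; // dense running sum x^j
  for (uword j = 0; j < n; ++j) {
    if (j == 0) st.inputs[j] = x0;
    else if (conn == 1) st.inputs[j] = run_sum;
    else st.inputs[j] = st.outputs[j - 1];
    lstm_dir_forward(bl[j].Wf, bl[j].Uf, bl[j].bf, st.inputs[j], false, st.cf[j]);
    lstm_dir_forward(bl[j].Wb, bl[j].Ub, bl[j].bb, st.inputs[j], true, st.cb[j]);
    cube& O = st.outputs[j];
    O.set_size(2 * H, B, T);
    for (uword t = 0; t < T; ++t)
      O.slice(t) = join_cols(st.cf[j].Hs.slice(t), st.cb[j].Hs.slice(t));
    if (conn == 1) {
      if (j == 0) run_sum = O; else run_sum += O;
    }
  }
  st.fused = (conn == 1) ? run_sum : st.outputs[n - 1];
  pred.set_size(T, B);
  for (uword t = 0; t < T; ++t)
    pred.row(t) = head_w.t() * st.fused.slice(t) + head_b;
}

// [[Rcpp::export]]
List dcblstm_forward_cpp(NumericVector theta, NumericMatrix X, int n_blocks,
                         int H, int conn, bool return_features = false) {
  vec head_w;
  double* head_b;
  std::vector<BlockView> bl =
      map_params(REAL(theta), (uword)n_blocks, (uword)H, head_w, head_b);
  mat Xin(X.begin(), X.nrow(), X.ncol(), false);
  ForwardState st;
  mat pred;
  model_forward(bl, head_w, *head_b, Xin, conn, st, pred);
  List out = List::create(Named("pred") = wrap(pred));
  if (return_features) {
    NumericVector f(st.fused.begin(), st.fused.end());
    f.attr("dim") = IntegerVector::create(st.fused.n_rows, st.fused.n_cols,
                                          st.fused.n_slices);
    out["features"] = f;
  }
  return out;
}

// Batch loss: mean over segments of per-segment RMSE, plus its gradient.
// [[Rcpp::export]]
List dcblstm_grad_cpp(NumericVector theta, NumericMatrix X, NumericMatrix Y,
                      int n_blocks, int H, int conn) {
  const uword nb = (uword)n_blocks, Hh = (uword)H;
  vec head_w;
  double* head_b;
  std::vector<BlockView> bl = map_params(REAL(theta), nb, Hh, head_w, head_b);
  mat Xin(X.begin(), X.nrow(), X.ncol(), false);
  mat Yin(Y.begin(), Y.nrow(), Y.ncol(), false);
  const uword T = Xin.n_rows, B = Xin.n_cols;

  ForwardState st;
  mat pred;
  model_forward(bl, head_w, *head_b, Xin, conn, st, pred);

  mat err = pred - Yin;
  rowvec seg_rmse = sqrt(mean(square(err), 0)); // per segment
  double loss = mean(seg_rmse);
  // d loss / d pred(t,b) = err(t,b) / (B * T * rmse_b), guarded at rmse ~ 0
  mat dPred = err;
  for (uword b = 0; b < B; ++b) {
    double r = seg_rmse(b);
    dPred.col(b) *= (r > 1e-12) ? 1.0 / ((double)B * (double)T * r) : 0.0;
  }

  NumericVector gradR(theta.size());
  vec gw;
  double* gb0;
  std::vector<BlockView> gr = map_params(REAL(gradR), nb, Hh, gw, gb0);

  // head backward
  cube dFused(2 * Hh, B, T, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    dFused.slice(t) = head_w * dPred.row(t);
    gw += st.fused.slice(t) * dPred.row(t).t();
  }
  *gb0 = accu(dPred);

  // blocks, top-down. For dense: d loss/d l^j = sum_{m >= j} d loss/d x^m,
  // tracked by the running accumulator A.
  cube A = dFused;
  for (uword j = nb; j-- > 0;) {
    const uword D = st.inputs[j].n_rows;
    cube dX(D, B, T, fill::zeros);
    cube dHf(Hh, B, T), dHb(Hh, B, T);
    const cube& dO = (conn == 1) ? A : ((j == nb - 1) ? dFused : A);
    for (uword t = 0; t < T; ++t) {
      dHf.slice(t) = dO.slice(t).rows(0, Hh - 1);
      dHb.slice(t) = dO.slice(t).rows(Hh, 2 * Hh - 1);
    }
    lstm_dir_backward(bl[j].Wf, bl[j].Uf, st.inputs[j], false, st.cf[j], dHf,
                      gr[j].Wf, gr[j].Uf, gr[j].bf, dX);
    lstm_dir_backward(bl[j].Wb, bl[j].Ub, st.inputs[j], true, st.cb[j], dHb,
                      gr[j].Wb, gr[j].Ub, gr[j].bb, dX);
    if (j > 0) {
      if (conn == 1) A += dX; // dX is grad w.r.t. x^{j-1}
      else A = dX;            // stacked: input grad feeds block j-1's output
    }
  }

  return List::create(Named("loss") = loss, Named("grad") = gradR);
}

// Single bidirectional block, exposed for oracle tests: X is a D x B x T
// array, returns 2H x B x T.
// [[Rcpp::export]]
NumericVector bilstm_forward_cpp(NumericMatrix Wf, NumericMatrix Uf,
                                 NumericVector bf, NumericMatrix Wb,
                                 NumericMatrix Ub, NumericVector bb,
                                 NumericVector Xarr) {
  IntegerVector dm = Xarr.attr("dim");
  cube X(Xarr.begin(), dm[0], dm[1], dm[2], false);
  mat wf(Wf.begin(), Wf.nrow(), Wf.ncol(), false);
  mat uf(Uf.begin(), Uf.nrow(), Uf.ncol(), false);
  mat wb(Wb.begin(), Wb.nrow(), Wb.ncol(), false);
  mat ub(Ub.begin(), Ub.nrow(), Ub.ncol(), false);
  vec vbf(bf.begin(), bf.size(), false), vbb(bb.begin(), bb.size(), false);
  DirCache cf, cb;
  lstm_dir_forward(wf, uf, vbf, X, false, cf);
  lstm_dir_forward(wb, ub, vbb, X, true, cb);
  const uword H = uf.n_cols, B = X.n_cols, T = X.n_slices;
  cube O(2 * H, B, T);
  for (uword t = 0; t < T; ++t)
    O.slice(t) = join_cols(cf.Hs.slice(t), cb.Hs.slice(t));
  NumericVector out(O.begin(), O.end());
  out.attr("dim") = IntegerVector::create(2 * H, B, T);
  return out;
}
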