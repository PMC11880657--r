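// 2D U-Net dose regressor: forward pass, backpropagation and Adam
// training loop. Encoder blocks optionally use depthwise-separable
// (Xception-style) convolutions; bottleneck and decoder use full 3x3
// convolutions; 2x2 max-pooling, nearest-neighbour upsampling, skip
// concatenation, and a 1x1 convolution + ReLU head so predicted dose is
// non-negative. All tensors are (rows, cols, channels) cubes; the
// trainable parameters live in one flat vector whose layout is fixed by
// the architecture configuration. Computation is single precision (the
// usual choice for network training); the R-facing parameter vector is
// double.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef float real;
typedef arma::Mat<real> rmat;
typedef arma::Col<real> rvec;
typedef arma::Row<real> rrow;
typedef arma::Cube<real> rcube;

enum OpType { OP_INPUT = 0, OP_FULL3, OP_PW, OP_DW, OP_RELU, OP_POOL,
              OP_UP, OP_CONCAT };

struct Op {
  int type;
  int in;      // index of input op
  int skip;    // second input (concat only)
  int cin;
  int cout;
  long woff;   // offset of weights in the flat parameter vector
  long boff;   // offset of bias (-1 = no bias)
  std::string name;
};

struct Graph {
  std::vector<Op> ops;
  long nparam;
};

static int add_conv(Graph &g, int type, int in, int cin, int cout,
                    const std::string &name) {
  Op op; op.type = type; op.in = in; op.skip = -1;
  op.cin = cin; op.cout = cout; op.name = name;
  op.woff = g.nparam;
  if (type == OP_FULL3) { g.nparam += 9L * cin * cout; op.boff = g.nparam; g.nparam += cout; }
  else if (type == OP_PW) { g.nparam += (long)cin * cout; op.boff = g.nparam; g.nparam += cout; }
  else { /* OP_DW */ g.nparam += 9L * cin; op.boff = -1; op.cout = cin; }
  g.ops.push_back(op);
  return (int)g.ops.size() - 1;
}

static int add_simple(Graph &g, int type, int in, int cout,
                      const std::string &name, int skip = -1) {
  Op op; op.type = type; op.in = in; op.skip = skip;
  op.cin = cout; op.cout = cout; op.woff = -1; op.boff = -1; op.name = name;
  g.ops.push_back(op);
  return (int)g.ops.size() - 1;
}

// two conv+ReLU units; separable = depthwise 3x3 followed by pointwise 1x1
static int add_block(Graph &g, int prev, int cin, int f, bool sep,
                     const std::string &tag) {
  if (sep) {
    prev = add_conv(g, OP_DW, prev, cin, cin, tag + "_dw1");
    prev = add_conv(g, OP_PW, prev, cin, f, tag + "_pw1");
    prev = add_simple(g, OP_RELU, prev, f, tag + "_relu1");
    prev = add_conv(g, OP_DW, prev, f, f, tag + "_dw2");
    prev = add_conv(g, OP_PW, prev, f, f, tag + "_pw2");
    prev = add_simple(g, OP_RELU, prev, f, tag + "_relu2");
  } else {
    prev = add_conv(g, OP_FULL3, prev, cin, f, tag + "_conv1");
    prev = add_simple(g, OP_RELU, prev, f, tag + "_relu1");
    prev = add_conv(g, OP_FULL3, prev, f, f, tag + "_conv2");
    prev = add_simple(g, OP_RELU, prev, f, tag + "_relu2");
  }
  return prev;
}

static Graph build_graph(int in_ch, int depth, int base, bool sep) {
  Graph g; g.nparam = 0;
  Op inp; inp.type = OP_INPUT; inp.in = -1; inp.skip = -1;
  inp.cin = in_ch; inp.cout = in_ch; inp.woff = -1; inp.boff = -1;
  inp.name = "input";
  g.ops.push_back(inp);
  int prev = 0, cin = in_ch;
  std::vector<int> skips;
  for (int i = 0; i < depth - 1; ++i) {
    int f = base << i;
    char tag[32]; snprintf(tag, sizeof(tag), "enc%d", i + 1);
    prev = add_block(g, prev, cin, f, sep, tag);
    skips.push_back(prev);
    prev = add_simple(g, OP_POOL, prev, f, std::string(tag) + "_pool");
    cin = f;
  }
  int fb = base << (depth - 1);
  prev = add_block(g, prev, cin, fb, false, "bottleneck");
  cin = fb;
  for (int i = depth - 2; i >= 0; --i) {
    int f = base << i;
    char tag[32]; snprintf(tag, sizeof(tag), "dec%d", i + 1);
    prev = add_simple(g, OP_UP, prev, cin, std::string(tag) + "_up");
    prev = add_conv(g, OP_FULL3, prev, cin, f, std::string(tag) + "_upconv");
    prev = add_simple(g, OP_RELU, prev, f, std::string(tag) + "_uprelu");
    prev = add_simple(g, OP_CONCAT, prev, 2 * f, std::string(tag) + "_concat",
                      skips[i]);
    prev = add_conv(g, OP_FULL3, prev, 2 * f, f, std::string(tag) + "_conv1");
    prev = add_simple(g, OP_RELU, prev, f, std::string(tag) + "_relu1");
    prev = add_conv(g, OP_FULL3, prev, f, f, std::string(tag) + "_conv2");
    prev = add_simple(g, OP_RELU, prev, f, std::string(tag) + "_relu2");
    cin = f;
  }
  prev = add_conv(g, OP_PW, prev, cin, 1, "head");
  add_simple(g, OP_RELU, prev, 1, "head_relu");
  return g;
}

static Graph graph_from_cfg(const IntegerVector &cfg) {
  if (cfg.size() != 4) stop("cfg must be (in_channels, depth, base_filters, separable)");
  int in_ch = cfg[0], depth = cfg[1], base = cfg[2];
  bool sep = cfg[3] != 0;
  if (depth < 2) stop("depth must be >= 2");
  if (base < 1) stop("base_filters must be >= 1");
  if (in_ch < 1) stop("input channel count must be >= 1");
  return build_graph(in_ch, depth, base, sep);
}

// ---- primitive forward/backward --------------------------------------

// im2col for a 3x3 same-padding convolution; P is (H*W) x (9*Cin)
static void im2col3(const rcube &X, rmat &P) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  P.zeros(H * (long)W, 9L * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        int di = ki - 1, dj = kj - 1;
        long col = c * 9L + kj * 3L + ki;
        int r0d = std::max(0, -di), r1d = H - 1 - std::max(0, di);
        int c0d = std::max(0, -dj), c1d = W - 1 - std::max(0, dj);
        if (r1d < r0d || c1d < c0d) continue;
        rmat pm(P.colptr(col), H, W, false, true);
        pm.submat(r0d, c0d, r1d, c1d) =
          X.slice(c).submat(r0d + di, c0d + dj, r1d + di, c1d + dj);
      }
    }
  }
}

// scatter-add of dP back onto dX (transpose of im2col3)
static void col2im3(const rmat &dP, rcube &dX) {
  int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        int di = ki - 1, dj = kj - 1;
        long col = c * 9L + kj * 3L + ki;
        int r0d = std::max(0, -di), r1d = H - 1 - std::max(0, di);
        int c0d = std::max(0, -dj), c1d = W - 1 - std::max(0, dj);
        if (r1d < r0d || c1d < c0d) continue;
        rmat g(const_cast<real *>(dP.colptr(col)), H, W, false, true);
        dX.slice(c).submat(r0d + di, c0d + dj, r1d + di, c1d + dj) +=
          g.submat(r0d, c0d, r1d, c1d);
      }
    }
  }
}

static void full3_forward(const Op &op, const rcube &X, const rvec &par,
                          rcube &Y, rmat &Pcache) {
  int H = X.n_rows, W = X.n_cols;
  im2col3(X, Pcache);
  rmat Wm(const_cast<real *>(par.memptr()) + op.woff,
          9L * op.cin, op.cout, false, true);
  rmat Ym = Pcache * Wm;
  Ym.each_row() += rrow(const_cast<real *>(par.memptr()) + op.boff,
                        op.cout, false, true);
  Y = rcube(Ym.memptr(), H, W, op.cout);
}

static void full3_backward(const Op &op, const rcube &X, const rvec &par,
                           const rcube &dY, const rmat &Pcache,
                           rvec &grad, rcube &dX) {
  int H = X.n_rows, W = X.n_cols;
  rmat dYm(const_cast<real *>(dY.memptr()), H * (long)W, op.cout,
           false, true);
  rmat Wm(const_cast<real *>(par.memptr()) + op.woff,
          9L * op.cin, op.cout, false, true);
  rmat dW = Pcache.t() * dYm;
  rrow db = arma::sum(dYm, 0);
  rmat dP = dYm * Wm.t();
  dX.zeros(H, W, op.cin);
  col2im3(dP, dX);
  for (long i = 0; i < (long)dW.n_elem; ++i) grad[op.woff + i] += dW[i];
  for (int j = 0; j < op.cout; ++j) grad[op.boff + j] += db[j];
}

static void pw_forward(const Op &op, const rcube &X, const rvec &par,
                       rcube &Y) {
  int H = X.n_rows, W = X.n_cols;
  rmat Xm(const_cast<real *>(X.memptr()), H * (long)W, op.cin, false, true);
  rmat Wm(const_cast<real *>(par.memptr()) + op.woff,
          op.cin, op.cout, false, true);
  rmat Ym = Xm * Wm;
  Ym.each_row() += rrow(const_cast<real *>(par.memptr()) + op.boff,
                        op.cout, false, true);
  Y = rcube(Ym.memptr(), H, W, op.cout);
}

static void pw_backward(const Op &op, const rcube &X, const rvec &par,
                        const rcube &dY, rvec &grad, rcube &dX) {
  int H = X.n_rows, W = X.n_cols;
  rmat Xm(const_cast<real *>(X.memptr()), H * (long)W, op.cin, false, true);
  rmat dYm(const_cast<real *>(dY.memptr()), H * (long)W, op.cout,
           false, true);
  rmat Wm(const_cast<real *>(par.memptr()) + op.woff,
          op.cin, op.cout, false, true);
  rmat dW = Xm.t() * dYm;
  rrow db = arma::sum(dYm, 0);
  rmat dXm = dYm * Wm.t();
  dX = rcube(dXm.memptr(), H, W, op.cin);
  for (long i = 0; i < (long)dW.n_elem; ++i) grad[op.woff + i] += dW[i];
  for (int j = 0; j < op.cout; ++j) grad[op.boff + j] += db[j];
}

static void dw_forward(const Op &op, const rcube &X, const rvec &par,
                       rcube &Y) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  Y.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    const real *k = par.memptr() + op.woff + 9L * c;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        int di = ki - 1, dj = kj - 1;
        real w = k[kj * 3 + ki];
        int r0d = std::max(0, -di), r1d = H - 1 - std::max(0, di);
        int c0d = std::max(0, -dj), c1d = W - 1 - std::max(0, dj);
        if (r1d < r0d || c1d < c0d) continue;
        Y.slice(c).submat(r0d, c0d, r1d, c1d) +=
          w * X.slice(c).submat(r0d + di, c0d + dj, r1d + di, c1d + dj);
      }
    }
  }
}

static void dw_backward(const Op &op, const rcube &X, const rvec &par,
                        const rcube &dY, rvec &grad, rcube &dX) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  dX.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    const real *k = par.memptr() + op.woff + 9L * c;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        int di = ki - 1, dj = kj - 1;
        int r0d = std::max(0, -di), r1d = H - 1 - std::max(0, di);
        int c0d = std::max(0, -dj), c1d = W - 1 - std::max(0, dj);
        if (r1d < r0d || c1d < c0d) continue;
        grad[op.woff + 9L * c + kj * 3 + ki] += arma::accu(
          dY.slice(c).submat(r0d, c0d, r1d, c1d) %
          X.slice(c).submat(r0d + di, c0d + dj, r1d + di, c1d + dj));
        dX.slice(c).submat(r0d + di, c0d + dj, r1d + di, c1d + dj) +=
          k[kj * 3 + ki] * dY.slice(c).submat(r0d, c0d, r1d, c1d);
      }
    }
  }
}

static void pool_forward(const rcube &X, rcube &Y, arma::ucube &idx) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  if (H % 2 || W % 2) stop("spatial size must be divisible by 2^(depth-1)");
  int h = H / 2, w = W / 2;
  Y.set_size(h, w, C); idx.set_size(h, w, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        real best = X(2 * i, 2 * j, c); unsigned b = 0;
        real v;
        v = X(2 * i + 1, 2 * j, c); if (v > best) { best = v; b = 1; }
        v = X(2 * i, 2 * j + 1, c); if (v > best) { best = v; b = 2; }
        v = X(2 * i + 1, 2 * j + 1, c); if (v > best) { best = v; b = 3; }
        Y(i, j, c) = best; idx(i, j, c) = b;
      }
    }
  }
}

static void pool_backward(const rcube &dY, const arma::ucube &idx,
                          rcube &dX, int H, int W) {
  int h = dY.n_rows, w = dY.n_cols, C = dY.n_slices;
  dX.zeros(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        unsigned b = idx(i, j, c);
        dX(2 * i + (b & 1u), 2 * j + (b >> 1), c) = dY(i, j, c);
      }
}

static void up_forward(const rcube &X, rcube &Y) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  Y.set_size(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        real v = X(i, j, c);
        Y(2 * i, 2 * j, c) = v; Y(2 * i + 1, 2 * j, c) = v;
        Y(2 * i, 2 * j + 1, c) = v; Y(2 * i + 1, 2 * j + 1, c) = v;
      }
}

static void up_backward(const rcube &dY, rcube &dX) {
  int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  dX.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dX(i, j, c) = dY(2 * i, 2 * j, c) + dY(2 * i + 1, 2 * j, c) +
          dY(2 * i, 2 * j + 1, c) + dY(2 * i + 1, 2 * j + 1, c);
}

// ---- whole-network forward/backward ----------------------------------

struct Workspace {
  std::vector<rcube> act;        // output of each op
  std::vector<arma::ucube> pool_idx;
  std::vector<rmat> im2col;      // cached patch matrices for FULL3 ops
};

static void forward_pass(const Graph &g, const rvec &par, const rcube &X,
                         Workspace &ws) {
  size_t n = g.ops.size();
  ws.act.resize(n); ws.pool_idx.resize(n); ws.im2col.resize(n);
  ws.act[0] = X;
  for (size_t i = 1; i < n; ++i) {
    const Op &op = g.ops[i];
    const rcube &in = ws.act[op.in];
    switch (op.type) {
    case OP_FULL3: full3_forward(op, in, par, ws.act[i], ws.im2col[i]); break;
    case OP_PW: pw_forward(op, in, par, ws.act[i]); break;
    case OP_DW: dw_forward(op, in, par, ws.act[i]); break;
    case OP_RELU:
      ws.act[i] = in;
      ws.act[i].transform([](real v) { return v > 0 ? v : (real)0; });
      break;
    case OP_POOL: pool_forward(in, ws.act[i], ws.pool_idx[i]); break;
    case OP_UP: up_forward(in, ws.act[i]); break;
    case OP_CONCAT: {
      const rcube &sk = ws.act[op.skip];
      ws.act[i].set_size(in.n_rows, in.n_cols, sk.n_slices + in.n_slices);
      ws.act[i].slices(0, sk.n_slices - 1) = sk;
      ws.act[i].slices(sk.n_slices, sk.n_slices + in.n_slices - 1) = in;
      break;
    }
    default: stop("bad op in forward pass");
    }
  }
}

static void backward_pass(const Graph &g, const rvec &par,
                          const Workspace &ws, const rcube &dOut,
                          rvec &grad) {
  size_t n = g.ops.size();
  std::vector<rcube> dact(n);
  dact[n - 1] = dOut;
  rcube dX;
  for (size_t i = n - 1; i >= 1; --i) {
    if (dact[i].n_elem == 0) continue;
    const Op &op = g.ops[i];
    const rcube &in = ws.act[op.in];
    const rcube &dY = dact[i];
    switch (op.type) {
    case OP_FULL3:
      full3_backward(op, in, par, dY, ws.im2col[i], grad, dX); break;
    case OP_PW: pw_backward(op, in, par, dY, grad, dX); break;
    case OP_DW: dw_backward(op, in, par, dY, grad, dX); break;
    case OP_RELU: {
      dX = dY;
      const rcube &out = ws.act[i];
      for (long e = 0; e < (long)dX.n_elem; ++e)
        if (out[e] <= 0) dX[e] = 0;
      break;
    }
    case OP_POOL:
      pool_backward(dY, ws.pool_idx[i], dX, in.n_rows, in.n_cols); break;
    case OP_UP: up_backward(dY, dX); break;
    case OP_CONCAT: {
      const rcube &sk = ws.act[op.skip];
      rcube dSk = dY.slices(0, sk.n_slices - 1);
      if (dact[op.skip].n_elem == 0) dact[op.skip] = dSk;
      else dact[op.skip] += dSk;
      dX = dY.slices(sk.n_slices, dY.n_slices - 1);
      break;
    }
    default: stop("bad op in backward pass");
    }
    if (dact[op.in].n_elem == 0) dact[op.in] = dX;
    else dact[op.in] += dX;
    dact[i].reset();
  }
}

// ---- exported API -----------------------------------------------------

// [[Rcpp::export]]
List unet_param_info_cpp(IntegerVector cfg) {
  Graph g = graph_from_cfg(cfg);
  std::vector<std::string> name;
  std::vector<double> offset, len, fan_in;
  for (const Op &op : g.ops) {
    if (op.woff < 0) continue;
    long wlen = (op.type == OP_FULL3) ? 9L * op.cin * op.cout :
      (op.type == OP_PW) ? (long)op.cin * op.cout : 9L * op.cin;
    double fi = (op.type == OP_FULL3) ? 9.0 * op.cin :
      (op.type == OP_PW) ? (double)op.cin : 9.0;
    name.push_back(op.name + "_w"); offset.push_back(op.woff + 1);
    len.push_back(wlen); fan_in.push_back(fi);
    if (op.boff >= 0) {
      name.push_back(op.name + "_b"); offset.push_back(op.boff + 1);
      len.push_back(op.cout); fan_in.push_back(0);
    }
  }
  return List::create(
    _["n_params"] = (double)g.nparam,
    _["tensors"] = DataFrame::create(
      _["name"] = name, _["offset"] = offset, _["length"] = len,
      _["fan_in"] = fan_in, _["stringsAsFactors"] = false));
}

// copy sample n of the (H,W,C,N) double array into a float cube
static void load_sample(const double *p, int H, int W, int C, int n,
                        rcube &out) {
  out.set_size(H, W, C);
  long per = (long)H * W * C;
  const double *src = p + (long)n * per;
  real *dst = out.memptr();
  for (long i = 0; i < per; ++i) dst[i] = (real)src[i];
}

// [[Rcpp::export]]
NumericVector unet_forward_cpp(NumericVector par, NumericVector X,
                               IntegerVector cfg) {
  Graph g = graph_from_cfg(cfg);
  IntegerVector dims = X.attr("dim");
  if (dims.size() != 4) stop("X must be a 4D array (H, W, C, N)");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  if (C != cfg[0]) stop("channel count does not match the model configuration");
  if ((long)par.size() != g.nparam) stop("parameter vector has wrong length");
  rvec pv(par.size());
  for (long i = 0; i < (long)par.size(); ++i) pv[i] = (real)par[i];
  NumericVector out((long)H * W * N);
  out.attr("dim") = IntegerVector::create(H, W, N);
  Workspace ws;
  rcube x;
  for (int s = 0; s < N; ++s) {
    load_sample(X.begin(), H, W, C, s, x);
    forward_pass(g, pv, x, ws);
    const rcube &y = ws.act.back();
    double *dst = out.begin() + (long)s * H * W;
    for (long i = 0; i < (long)y.n_elem; ++i) dst[i] = (double)y[i];
  }
  return out;
}

// [[Rcpp::export]]
List unet_train_cpp(NumericVector par0, NumericVector X, NumericVector Y,
                    IntegerVector cfg, List opts, IntegerMatrix order) {
  Graph g = graph_from_cfg(cfg);
  IntegerVector dims = X.attr("dim");
  if (dims.size() != 4) stop("X must be a 4D array (H, W, C, N)");
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  if (C != cfg[0]) stop("channel count does not match the model configuration");
  if ((long)par0.size() != g.nparam) stop("parameter vector has wrong length");
  IntegerVector ydims = Y.attr("dim");
  if (ydims.size() != 3 || ydims[0] != H || ydims[1] != W || ydims[2] != N)
    stop("Y must be an (H, W, N) array matching X");

  int epochs = as<int>(opts["epochs"]);
  double lr = as<double>(opts["learning_rate"]);
  double b1 = as<double>(opts["beta1"]);
  double b2 = as<double>(opts["beta2"]);
  int batch = as<int>(opts["batch_size"]);
  if (epochs < 1) stop("epochs must be >= 1");
  if (lr <= 0) stop("learning rate must be positive");
  if (batch < 1) stop("batch size must be >= 1");
  if (order.nrow() != epochs || order.ncol() != N)
    stop("shuffle order must be an epochs x N matrix");

  rvec theta(par0.size());
  for (long i = 0; i < (long)par0.size(); ++i) theta[i] = (real)par0[i];
  rvec grad(g.nparam, arma::fill::zeros);
  // Adam state kept in double for accumulation accuracy
  arma::vec m(g.nparam, arma::fill::zeros), v(g.nparam, arma::fill::zeros);
  double eps = 1e-8;
  long t = 0;
  NumericVector losses(epochs);
  Workspace ws;
  rcube x;
  double npix = (double)H * W;

  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    for (int start = 0; start < N; start += batch) {
      int bn = std::min(batch, N - start);
      grad.zeros();
      for (int k = 0; k < bn; ++k) {
        int s = order(e, start + k);
        if (s < 0 || s >= N) stop("shuffle order index out of range");
        load_sample(X.begin(), H, W, C, s, x);
        forward_pass(g, theta, x, ws);
        const rcube &yhat = ws.act.back();
        rcube dOut(H, W, 1);
        double mse = 0.0;
        const double *yref = Y.begin() + (long)s * H * W;
        real scale = (real)(2.0 / (npix * bn));
        for (long i = 0; i < (long)H * W; ++i) {
          double d = (double)yhat[i] - yref[i];
          mse += d * d;
          dOut[i] = (real)d * scale;
        }
        epoch_loss += mse / npix;
        backward_pass(g, theta, ws, dOut, grad);
      }
      if (!grad.is_finite()) stop("non-finite gradient encountered; aborting");
      ++t;
      double bc1 = 1 - std::pow(b1, (double)t);
      double bc2 = 1 - std::pow(b2, (double)t);
      for (long i = 0; i < g.nparam; ++i) {
        double gi = (double)grad[i];
        m[i] = b1 * m[i] + (1 - b1) * gi;
        v[i] = b2 * v[i] + (1 - b2) * gi * gi;
        theta[i] -= (real)(lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps));
      }
    }
    losses[e] = epoch_loss / N;
    if (!std::isfinite(losses[e]))
      stop("non-finite training loss encountered; aborting");
    Rcpp::checkUserInterrupt();
  }
  NumericVector parOut(theta.n_elem);
  for (long i = 0; i < (long)theta.n_elem; ++i) parOut[i] = (double)theta[i];
  return List::create(_["par"] = parOut, _["loss"] = losses);
}
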