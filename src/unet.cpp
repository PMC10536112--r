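// Encoder-decoder segmentation network: four contracting blocks (two 3x3
// convolutions + ReLU each, 2x2 max pooling between levels), mirrored
// expanding path with 2x2 up-convolutions and skip concatenations, and a
// final 1x1 convolution to two per-pixel class scores. Forward, softmax
// cross-entropy with per-class weights, and full backpropagation are
// implemented here; the optimizer lives on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvSpec { int k; int cin; int cout; };  // k = 3 (same pad), 2 (tconv), 1

// Topology for encoder filters f1..f4, 1 input channel, 2 classes.
// Order defines the parameter packing.
std::vector<ConvSpec> topology(const arma::ivec& f) {
  const int f1 = f[0], f2 = f[1], f3 = f[2], f4 = f[3];
  return {
    {3, 1, f1},  {3, f1, f1},              // enc1 @ H
    {3, f1, f2}, {3, f2, f2},              // enc2 @ H/2
    {3, f2, f3}, {3, f3, f3},              // enc3 @ H/4
    {3, f3, f4}, {3, f4, f4},              // enc4 (bottleneck) @ H/8
    {2, f4, f3}, {3, 2 * f3, f3}, {3, f3, f3},  // up + dec3 @ H/4
    {2, f3, f2}, {3, 2 * f2, f2}, {3, f2, f2},  // up + dec2 @ H/2
    {2, f2, f1}, {3, 2 * f1, f1}, {3, f1, f1},  // up + dec1 @ H
    {1, f1, 2}                                   // output scores
  };
}

struct Layer {
  ConvSpec spec;
  arma::mat W;   // cout x (k*k*cin), view into the parameter vector
  arma::vec b;   // cout
};

// Map a flat parameter vector onto layer weight views (no copy).
std::vector<Layer> unpack(double* p, const std::vector<ConvSpec>& tp) {
  std::vector<Layer> ls;
  size_t off = 0;
  for (const auto& s : tp) {
    Layer L;
    L.spec = s;
    const size_t wsz = (size_t)s.cout * s.k * s.k * s.cin;
    L.W = arma::mat(p + off, s.cout, s.k * s.k * s.cin, false, true);
    off += wsz;
    L.b = arma::vec(p + off, s.cout, false, true);
    off += s.cout;
    ls.push_back(std::move(L));
  }
  return ls;
}

size_t nparams(const std::vector<ConvSpec>& tp) {
  size_t n = 0;
  for (const auto& s : tp) n += (size_t)s.cout * (s.k * s.k * s.cin + 1);
  return n;
}

// im2col for 3x3 same-padded convolution; row c*9 + (dy+1)*3 + (dx+1).
arma::mat im2col3(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  arma::mat out(9 * C, (size_t)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& S = X.slice(c);
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int r = c * 9 + (dy + 1) * 3 + (dx + 1);
        const int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            out(r, i + (size_t)j * H) = S(i + dy, j + dx);
      }
  }
  return out;
}

void col2im3_add(const arma::mat& cols, arma::cube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  for (int c = 0; c < C; ++c) {
    arma::mat& S = dX.slice(c);
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int r = c * 9 + (dy + 1) * 3 + (dx + 1);
        const int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            S(i + dy, j + dx) += cols(r, i + (size_t)j * H);
      }
  }
}

arma::cube conv3(const Layer& L, const arma::cube& X) {
  arma::mat Z = L.W * im2col3(X);
  Z.each_col() += L.b;
  arma::cube out(X.n_rows, X.n_cols, L.spec.cout);
  for (int c = 0; c < L.spec.cout; ++c)
    out.slice(c) = arma::reshape(Z.row(c).t(), X.n_rows, X.n_cols);
  return out;
}

// dZ (cout x HW) from dOut cube
arma::mat flatten_grad(const arma::cube& dOut) {
  arma::mat dZ(dOut.n_slices, dOut.n_rows * dOut.n_cols);
  for (arma::uword c = 0; c < dOut.n_slices; ++c)
    dZ.row(c) = arma::vectorise(dOut.slice(c)).t();
  return dZ;
}

arma::cube conv3_backward(const Layer& L, const arma::cube& X,
                          const arma::cube& dOut, arma::mat& dW,
                          arma::vec& db) {
  arma::mat dZ = flatten_grad(dOut);
  dW += dZ * im2col3(X).t();
  db += arma::sum(dZ, 1);
  arma::mat dcols = L.W.t() * dZ;
  arma::cube dX(X.n_rows, X.n_cols, X.n_slices, arma::fill::zeros);
  col2im3_add(dcols, dX);
  return dX;
}

arma::cube conv1(const Layer& L, const arma::cube& X) {
  arma::mat Xm(X.n_slices, X.n_rows * X.n_cols);
  for (arma::uword c = 0; c < X.n_slices; ++c)
    Xm.row(c) = arma::vectorise(X.slice(c)).t();
  arma::mat Z = L.W * Xm;
  Z.each_col() += L.b;
  arma::cube out(X.n_rows, X.n_cols, L.spec.cout);
  for (int c = 0; c < L.spec.cout; ++c)
    out.slice(c) = arma::reshape(Z.row(c).t(), X.n_rows, X.n_cols);
  return out;
}

arma::cube conv1_backward(const Layer& L, const arma::cube& X,
                          const arma::cube& dOut, arma::mat& dW,
                          arma::vec& db) {
  arma::mat dZ = flatten_grad(dOut);
  arma::mat Xm(X.n_slices, X.n_rows * X.n_cols);
  for (arma::uword c = 0; c < X.n_slices; ++c)
    Xm.row(c) = arma::vectorise(X.slice(c)).t();
  dW += dZ * Xm.t();
  db += arma::sum(dZ, 1);
  arma::mat dXm = L.W.t() * dZ;
  arma::cube dX(X.n_rows, X.n_cols, X.n_slices);
  for (arma::uword c = 0; c < X.n_slices; ++c)
    dX.slice(c) = arma::reshape(dXm.row(c).t(), X.n_rows, X.n_cols);
  return dX;
}

arma::cube relu(const arma::cube& X) { return arma::clamp(X, 0.0, arma::datum::inf); }

arma::cube relu_backward(const arma::cube& act, const arma::cube& dOut) {
  arma::cube dX = dOut;
  dX.elem(arma::find(act <= 0)).zeros();
  return dX;
}

arma::cube maxpool2(const arma::cube& X, arma::ucube& idx) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  arma::cube out(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            double v = X(2 * i + a, 2 * j + b, c);
            if (v > best) { best = v; bi = (2 * i + a) + (2 * j + b) * X.n_rows; }
          }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return out;
}

arma::cube maxpool2_backward(const arma::cube& dOut, const arma::ucube& idx,
                             int Hin, int Win) {
  arma::cube dX(Hin, Win, dOut.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < dOut.n_slices; ++c)
    for (arma::uword j = 0; j < dOut.n_cols; ++j)
      for (arma::uword i = 0; i < dOut.n_rows; ++i) {
        arma::uword p = idx(i, j, c);
        dX(p % Hin, p / Hin, c) += dOut(i, j, c);
      }
  return dX;
}

// 2x2 stride-2 up-convolution; W column index ci*4 + a*2 + b.
arma::cube tconv2(const Layer& L, const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols;
  arma::cube out(2 * H, 2 * W, L.spec.cout, arma::fill::zeros);
  for (int co = 0; co < L.spec.cout; ++co) {
    out.slice(co).fill(L.b[co]);
    for (int ci = 0; ci < L.spec.cin; ++ci) {
      const arma::mat& S = X.slice(ci);
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b) {
          const double w = L.W(co, ci * 4 + a * 2 + b);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              out(2 * i + a, 2 * j + b, co) += w * S(i, j);
        }
    }
  }
  return out;
}

arma::cube tconv2_backward(const Layer& L, const arma::cube& X,
                           const arma::cube& dOut, arma::mat& dW,
                           arma::vec& db) {
  const int H = X.n_rows, W = X.n_cols;
  arma::cube dX(H, W, L.spec.cin, arma::fill::zeros);
  for (int co = 0; co < L.spec.cout; ++co) {
    db[co] += arma::accu(dOut.slice(co));
    for (int ci = 0; ci < L.spec.cin; ++ci) {
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b) {
          double g = 0.0;
          const double w = L.W(co, ci * 4 + a * 2 + b);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              const double d = dOut(2 * i + a, 2 * j + b, co);
              g += d * X(i, j, ci);
              dX(i, j, ci) += w * d;
            }
          dW(co, ci * 4 + a * 2 + b) += g;
        }
    }
  }
  return dX;
}

arma::cube concat(const arma::cube& A, const arma::cube& B) {
  return arma::join_slices(A, B);
}

struct Cache {
  std::vector<arma::cube> conv_in;   // input to each conv/tconv layer (topology order)
  std::vector<arma::cube> act;       // post-ReLU activations per conv layer
  std::vector<arma::ucube> pool_idx; // 3 pools
  std::vector<arma::cube> pool_in_dims;
  arma::cube scores;                 // pre-softmax
};

// Full forward pass; fills the cache when train = true.
arma::cube forward(std::vector<Layer>& L, const arma::cube& x0, Cache* C) {
  auto keep = [&](const arma::cube& in, int li) { if (C) C->conv_in[li] = in; };
  auto keepa = [&](const arma::cube& a, int li) { if (C) C->act[li] = a; };

  arma::cube a = x0;
  std::vector<arma::cube> skips;
  int li = 0;
  // encoder: blocks 0..3, pool after blocks 0..2
  for (int blk = 0; blk < 4; ++blk) {
    for (int c = 0; c < 2; ++c, ++li) {
      keep(a, li);
      a = relu(conv3(L[li], a));
      keepa(a, li);
    }
    if (blk < 3) {
      skips.push_back(a);
      arma::ucube idx;
      arma::cube pooled = maxpool2(a, idx);
      if (C) { C->pool_idx.push_back(idx); C->pool_in_dims.push_back(arma::cube(a.n_rows, a.n_cols, 0)); }
      a = pooled;
    }
  }
  // decoder
  for (int lvl = 2; lvl >= 0; --lvl) {
    keep(a, li);
    a = tconv2(L[li], a);
    ++li;
    a = concat(a, skips[lvl]);
    for (int c = 0; c < 2; ++c, ++li) {
      keep(a, li);
      a = relu(conv3(L[li], a));
      keepa(a, li);
    }
  }
  keep(a, li);
  arma::cube scores = conv1(L[li], a);
  if (C) C->scores = scores;
  return scores;
}

arma::mat softmax_fg(const arma::cube& scores) {
  arma::mat m = arma::max(scores.slice(0), scores.slice(1));
  arma::mat e0 = arma::exp(scores.slice(0) - m);
  arma::mat e1 = arma::exp(scores.slice(1) - m);
  return e1 / (e0 + e1);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_unet_layout")]]
DataFrame cpp_unet_layout(IntegerVector filters) {
  arma::ivec f = {filters[0], filters[1], filters[2], filters[3]};
  auto tp = topology(f);
  IntegerVector k, cin, cout, wsize, bsize;
  for (const auto& s : tp) {
    k.push_back(s.k); cin.push_back(s.cin); cout.push_back(s.cout);
    wsize.push_back(s.cout * s.k * s.k * s.cin);
    bsize.push_back(s.cout);
  }
  return DataFrame::create(_["k"] = k, _["cin"] = cin, _["cout"] = cout,
                           _["wsize"] = wsize, _["bsize"] = bsize);
}

// [[Rcpp::export(name = ".cpp_unet_forward")]]
NumericMatrix cpp_unet_forward(NumericVector params, NumericMatrix x,
                               IntegerVector filters) {
  arma::ivec f = {filters[0], filters[1], filters[2], filters[3]};
  auto tp = topology(f);
  if ((size_t)params.size() != nparams(tp))
    stop("parameter vector has wrong length");
  auto L = unpack(params.begin(), tp);
  arma::cube x0(x.nrow(), x.ncol(), 1);
  x0.slice(0) = arma::mat(x.begin(), x.nrow(), x.ncol());
  arma::cube scores = forward(L, x0, nullptr);
  arma::mat p = softmax_fg(scores);
  return wrap(p);
}

// Weighted softmax cross-entropy loss (mean over pixels) and, when
// want_grad, the gradient with respect to every parameter.
// [[Rcpp::export(name = ".cpp_unet_loss_grad")]]
List cpp_unet_loss_grad(NumericVector params, NumericMatrix x,
                        IntegerMatrix y, NumericVector clsw,
                        IntegerVector filters, bool want_grad) {
  arma::ivec f = {filters[0], filters[1], filters[2], filters[3]};
  auto tp = topology(f);
  if ((size_t)params.size() != nparams(tp))
    stop("parameter vector has wrong length");
  auto L = unpack(params.begin(), tp);

  const int H = x.nrow(), W = x.ncol();
  arma::cube x0(H, W, 1);
  x0.slice(0) = arma::mat(x.begin(), H, W);

  Cache C;
  C.conv_in.resize(tp.size());
  C.act.resize(tp.size());
  arma::cube scores = forward(L, x0, want_grad ? &C : nullptr);
  if (!want_grad) {
    // recompute scores without cache? forward already returned them
  }

  // softmax + weighted CE
  arma::mat m = arma::max(scores.slice(0), scores.slice(1));
  arma::mat e0 = arma::exp(scores.slice(0) - m);
  arma::mat e1 = arma::exp(scores.slice(1) - m);
  arma::mat Z = e0 + e1;
  arma::mat p1 = e1 / Z, p0 = e0 / Z;

  const double w0 = clsw[0], w1 = clsw[1];
  const double npix = (double)H * W;
  double loss = 0.0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (y(i, j) == 1)
        loss -= w1 * std::log(std::max(p1(i, j), 1e-12));
      else
        loss -= w0 * std::log(std::max(p0(i, j), 1e-12));
    }
  loss /= npix;

  if (!want_grad)
    return List::create(_["loss"] = loss);

  // gradient accumulators (owned memory; serialized into `grad` at the end)
  struct GradSlot { arma::mat W; arma::vec b; };
  std::vector<GradSlot> G;
  for (const auto& s : tp) {
    GradSlot g;
    g.W = arma::mat(s.cout, s.k * s.k * s.cin, arma::fill::zeros);
    g.b = arma::vec(s.cout, arma::fill::zeros);
    G.push_back(std::move(g));
  }

  arma::cube dscores(H, W, 2);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double w = (y(i, j) == 1) ? w1 : w0;
      const double t1 = (y(i, j) == 1) ? 1.0 : 0.0;
      dscores(i, j, 0) = w * (p0(i, j) - (1.0 - t1)) / npix;
      dscores(i, j, 1) = w * (p1(i, j) - t1) / npix;
    }

  // backward pass mirrors forward
  int li = (int)tp.size() - 1;
  arma::cube d = conv1_backward(L[li], C.conv_in[li], dscores, G[li].W, G[li].b);
  --li;

  // decoder levels in reverse: lvl 0 (last executed) .. lvl 2
  // forward decoder order was lvl=2,1,0 with layers (t, c, c) each.
  // We walk back: for lvl = 0, 1, 2 in reverse execution order.
  std::vector<int> skip_channels = {f[0], f[1], f[2]};
  std::vector<arma::cube> dskips(3);
  for (int lvl = 0; lvl <= 2; ++lvl) {
    for (int c = 1; c >= 0; --c) {
      d = relu_backward(C.act[li], d);
      d = conv3_backward(L[li], C.conv_in[li], d, G[li].W, G[li].b);
      --li;
    }
    // split concat: first cout slices from tconv, rest from the skip
    const int upc = tp[li].cout;
    arma::cube dup = d.slices(0, upc - 1);
    dskips[lvl] = d.slices(upc, d.n_slices - 1);
    d = tconv2_backward(L[li], C.conv_in[li], dup, G[li].W, G[li].b);
    --li;
  }

  // encoder blocks in reverse; pools after blocks 0..2
  for (int blk = 3; blk >= 0; --blk) {
    if (blk < 3) {
      // d currently is gradient at pooled output of this block
      const arma::cube& a = C.act[blk * 2 + 1];
      d = maxpool2_backward(d, C.pool_idx[blk], a.n_rows, a.n_cols);
      d += dskips[blk];
    }
    for (int c = 1; c >= 0; --c) {
      li = blk * 2 + c;
      d = relu_backward(C.act[li], d);
      d = conv3_backward(L[li], C.conv_in[li], d, G[li].W, G[li].b);
    }
  }

  NumericVector grad((R_xlen_t)nparams(tp));
  size_t off = 0;
  for (size_t l = 0; l < tp.size(); ++l) {
    std::copy(G[l].W.memptr(), G[l].W.memptr() + G[l].W.n_elem,
              grad.begin() + off);
    off += G[l].W.n_elem;
    std::copy(G[l].b.memptr(), G[l].b.memptr() + G[l].b.n_elem,
              grad.begin() + off);
    off += G[l].b.n_elem;
  }
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
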