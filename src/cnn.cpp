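// Compact CNN engine for fixed-size RGB tile classification.
//
// Architecture family: [conv 3x3 same-pad + ReLU + maxpool 2x2]* -> flatten
// -> dense ReLU -> (inverted) dropout -> dense 1 + sigmoid.  Forward and
// backward passes are im2col/gemm based; all randomness (weight init,
// dropout masks, shuffling) is injected from R so results are reproducible
// under R's RNG alone.
//
// Data layout conventions (column-major, matching R arrays):
//  - a batch enters as an (H*W*C) x N matrix, each column one tile
//    flattened as y + H*x + H*W*c;
//  - conv weights for a block are an F x (9*C) matrix, column index
//    (c*3 + (kx+1))*3 + (ky+1) for kernel offset (ky,kx) in {-1,0,1}^2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for 3x3 kernels with zero padding 1, stride 1.
static arma::mat im2col3(const arma::mat& A, int H, int W, int C, int N) {
  arma::mat cols(9 * C, (arma::uword)H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; n++) {
    const double* a = A.colptr(n);
    arma::uword jbase = (arma::uword)n * H * W;
    for (int x = 0; x < W; x++) {
      for (int y = 0; y < H; y++) {
        double* cj = cols.colptr(jbase + (arma::uword)x * H + y);
        for (int c = 0; c < C; c++) {
          const double* ac = a + (arma::uword)c * H * W;
          for (int kx = -1; kx <= 1; kx++) {
            int xx = x + kx;
            if (xx < 0 || xx >= W) continue;
            const double* acx = ac + (arma::uword)xx * H;
            for (int ky = -1; ky <= 1; ky++) {
              int yy = y + ky;
              if (yy < 0 || yy >= H) continue;
              cj[(c * 3 + (kx + 1)) * 3 + (ky + 1)] = acx[yy];
            }
          }
        }
      }
    }
  }
  return cols;
}

// transpose of im2col3: scatter-add patch gradients back onto the image grid
static arma::mat col2im3(const arma::mat& dcols, int H, int W, int C, int N) {
  arma::mat dA((arma::uword)H * W * C, N, arma::fill::zeros);
  for (int n = 0; n < N; n++) {
    double* a = dA.colptr(n);
    arma::uword jbase = (arma::uword)n * H * W;
    for (int x = 0; x < W; x++) {
      for (int y = 0; y < H; y++) {
        const double* cj = dcols.colptr(jbase + (arma::uword)x * H + y);
        for (int c = 0; c < C; c++) {
          double* ac = a + (arma::uword)c * H * W;
          for (int kx = -1; kx <= 1; kx++) {
            int xx = x + kx;
            if (xx < 0 || xx >= W) continue;
            double* acx = ac + (arma::uword)xx * H;
            for (int ky = -1; ky <= 1; ky++) {
              int yy = y + ky;
              if (yy < 0 || yy >= H) continue;
              acx[yy] += cj[(c * 3 + (kx + 1)) * 3 + (ky + 1)];
            }
          }
        }
      }
    }
  }
  return dA;
}

// 2x2 stride-2 max pooling; odd trailing row/col dropped.
// Y is F x (H*W*N); returns pooled (Hp*Wp*F) x N and the winning column
// index of Y for each pooled element (row in Y is the filter index).
static void maxpool2(const arma::mat& Y, int H, int W, int F, int N,
                     arma::mat& P, arma::umat& arg) {
  int Hp = H / 2, Wp = W / 2;
  P.set_size((arma::uword)Hp * Wp * F, N);
  arg.set_size((arma::uword)Hp * Wp * F, N);
  for (int n = 0; n < N; n++) {
    arma::uword jbase = (arma::uword)n * H * W;
    for (int f = 0; f < F; f++) {
      for (int xp = 0; xp < Wp; xp++) {
        for (int yp = 0; yp < Hp; yp++) {
          double best = -1e300;
          arma::uword bestj = 0;
          for (int dx = 0; dx < 2; dx++) {
            for (int dy = 0; dy < 2; dy++) {
              arma::uword j = jbase + (arma::uword)(2 * xp + dx) * H + (2 * yp + dy);
              double v = Y(f, j);
              if (v > best) { best = v; bestj = j; }
            }
          }
          arma::uword o = (arma::uword)f * Hp * Wp + (arma::uword)xp * Hp + yp;
          P(o, n) = best;
          arg(o, n) = bestj;
        }
      }
    }
  }
}

struct Shapes {
  std::vector<int> H, W, C;  // per conv-block input dims
  int n_blocks, flat;
};

static Shapes infer_shapes(int tile, const List& conv_W) {
  Shapes s;
  s.n_blocks = conv_W.size();
  int H = tile, W = tile, C = 3;
  for (int b = 0; b < s.n_blocks; b++) {
    s.H.push_back(H); s.W.push_back(W); s.C.push_back(C);
    arma::mat Wb = as<arma::mat>(conv_W[b]);
    if ((int)Wb.n_cols != 9 * C)
      stop("conv weight block %d has %d columns, expected %d", b + 1, (int)Wb.n_cols, 9 * C);
    C = Wb.n_rows;
    H /= 2; W /= 2;
    if (H < 1 || W < 1) stop("tile size too small for the pooling depth");
  }
  s.flat = H * W * C;
  return s;
}

// Shared forward pass; caches are filled only when training.
static arma::rowvec forward_pass(const arma::mat& X0, int tile, int N,
                                 const List& conv_W, const List& conv_b,
                                 const arma::mat& W1, const arma::vec& b1,
                                 const arma::rowvec& w2, double b2,
                                 const arma::mat* dropout_mask, double dropout_rate,
                                 bool cache,
                                 std::vector<arma::mat>* A, std::vector<arma::mat>* cols,
                                 std::vector<arma::mat>* Y, std::vector<arma::umat>* arg,
                                 arma::mat* h_pre_out, arma::mat* h_drop_out) {
  Shapes s = infer_shapes(tile, conv_W);
  arma::mat cur = X0;
  for (int b = 0; b < s.n_blocks; b++) {
    if (cache) A->push_back(cur);
    arma::mat cb = im2col3(cur, s.H[b], s.W[b], s.C[b], N);
    arma::mat Wb = as<arma::mat>(conv_W[b]);
    arma::vec bb = as<arma::vec>(conv_b[b]);
    arma::mat Zb = Wb * cb;
    Zb.each_col() += bb;
    Zb.transform([](double v) { return v > 0.0 ? v : 0.0; });
    arma::mat P; arma::umat ab;
    maxpool2(Zb, s.H[b], s.W[b], Wb.n_rows, N, P, ab);
    if (cache) { cols->push_back(std::move(cb)); Y->push_back(std::move(Zb)); arg->push_back(std::move(ab)); }
    cur = std::move(P);
  }
  if (cache) A->push_back(cur);
  arma::mat hp = W1 * cur;
  hp.each_col() += b1;
  arma::mat h = hp;
  h.transform([](double v) { return v > 0.0 ? v : 0.0; });
  if (dropout_mask != nullptr && dropout_rate > 0.0)
    h = (h % (*dropout_mask)) / (1.0 - dropout_rate);
  arma::rowvec z = w2 * h + b2;
  if (cache) { *h_pre_out = std::move(hp); *h_drop_out = std::move(h); }
  return 1.0 / (1.0 + arma::exp(-z));
}

// [[Rcpp::export]]
arma::vec cnn_forward_cpp(const arma::mat& X0, int tile,
                          List conv_W, List conv_b,
                          const arma::mat& W1, const arma::vec& b1,
                          const arma::rowvec& w2, double b2) {
  int N = X0.n_cols;
  arma::rowvec p = forward_pass(X0, tile, N, conv_W, conv_b, W1, b1, w2, b2,
                                nullptr, 0.0, false,
                                nullptr, nullptr, nullptr, nullptr, nullptr, nullptr);
  return p.t();
}

// [[Rcpp::export]]
List cnn_grad_cpp(const arma::mat& X0, const arma::rowvec& y, int tile,
                  List conv_W, List conv_b,
                  const arma::mat& W1, const arma::vec& b1,
                  const arma::rowvec& w2, double b2,
                  const arma::mat& dropout_mask, double dropout_rate) {
  int N = X0.n_cols;
  Shapes s = infer_shapes(tile, conv_W);
  std::vector<arma::mat> A, cols, Y;
  std::vector<arma::umat> arg;
  arma::mat h_pre, h_drop;
  arma::rowvec p = forward_pass(X0, tile, N, conv_W, conv_b, W1, b1, w2, b2,
                                &dropout_mask, dropout_rate, true,
                                &A, &cols, &Y, &arg, &h_pre, &h_drop);

  arma::rowvec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  double loss = -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));

  // output layer: d(loss)/dz for sigmoid + BCE averaged over the batch
  arma::rowvec dz = (p - y) / (double)N;
  arma::rowvec dw2 = dz * h_drop.t();
  double db2 = arma::accu(dz);
  arma::mat dh = w2.t() * dz;
  if (dropout_rate > 0.0) dh = (dh % dropout_mask) / (1.0 - dropout_rate);
  dh.elem(arma::find(h_pre <= 0.0)).zeros();
  arma::mat dW1 = dh * A[s.n_blocks].t();
  arma::vec db1 = arma::sum(dh, 1);
  arma::mat dcur = W1.t() * dh;

  List dconv_W(s.n_blocks), dconv_b(s.n_blocks);
  for (int b = s.n_blocks - 1; b >= 0; b--) {
    arma::mat Wb = as<arma::mat>(conv_W[b]);
    int F = Wb.n_rows;
    arma::mat dY(F, (arma::uword)s.H[b] * s.W[b] * N, arma::fill::zeros);
    const arma::umat& ab = arg[b];
    int Hp = s.H[b] / 2, Wp = s.W[b] / 2;
    for (int n = 0; n < N; n++) {
      const double* d = dcur.colptr(n);
      for (int f = 0; f < F; f++) {
        const arma::uword* aj = ab.colptr(n) + (arma::uword)f * Hp * Wp;
        const double* df = d + (arma::uword)f * Hp * Wp;
        for (int k = 0; k < Hp * Wp; k++) dY(f, aj[k]) += df[k];
      }
    }
    dY.elem(arma::find(Y[b] <= 0.0)).zeros();
    dconv_W[b] = dY * cols[b].t();
    dconv_b[b] = arma::vec(arma::sum(dY, 1));
    if (b > 0) {
      arma::mat dcols = Wb.t() * dY;
      dcur = col2im3(dcols, s.H[b], s.W[b], s.C[b], N);
    }
  }

  return List::create(_["loss"] = loss, _["prob"] = p.t(),
                      _["dconv_W"] = dconv_W, _["dconv_b"] = dconv_b,
                      _["dW1"] = dW1, _["db1"] = db1,
                      _["dw2"] = dw2, _["db2"] = db2);
}
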