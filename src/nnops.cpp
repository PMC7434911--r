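// Low-level numerical kernels: im2col convolution (forward/backward),
// 2x2 max pooling, 2x2 stride-2 transposed convolution, 8-connected
// labelling and variable-density Poisson-disk thinning.
//
// Feature maps are arma::cube (H, W, C) == R array dim c(H, W, C).
// Conv weights: mat (kh*kw*Cin) x Cout, column index k = c*(kh*kw) + di*kw + dj.
// Transposed-conv weights: mat Cin x (4*Cout), column index = co*4 + di*2 + dj.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride, int pad,
                        int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M(Hout * (size_t)Wout, (size_t)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        const size_t col = (size_t)c * kh * kw + (size_t)di * kw + dj;
        for (int j = 0; j < Wout; ++j) {
          const int sj = j * stride - pad + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Hout; ++i) {
            const int si = i * stride - pad + di;
            if (si < 0 || si >= H) continue;
            M((size_t)i + (size_t)Hout * j, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return M;
}

static void col2im_add(arma::cube& dx, const arma::mat& dM, int kh, int kw,
                       int stride, int pad, int Hout, int Wout) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        const size_t col = (size_t)c * kh * kw + (size_t)di * kw + dj;
        for (int j = 0; j < Wout; ++j) {
          const int sj = j * stride - pad + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < Hout; ++i) {
            const int si = i * stride - pad + di;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += dM((size_t)i + (size_t)Hout * j, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List nn_conv_fwd(List xs, const arma::mat& W, const arma::vec& b,
                 int kh, int kw, int stride, int pad) {
  const int N = xs.size();
  List out(N);
  const int Cout = W.n_cols;
  for (int n = 0; n < N; ++n) {
    arma::cube x = as<arma::cube>(xs[n]);
    const int Hout = (x.n_rows + 2 * pad - kh) / stride + 1;
    const int Wout = (x.n_cols + 2 * pad - kw) / stride + 1;
    arma::mat M = im2col(x, kh, kw, stride, pad, Hout, Wout);
    arma::mat Y = M * W;
    Y.each_row() += b.t();
    arma::cube y(Hout, Wout, Cout);
    for (int c = 0; c < Cout; ++c)
      y.slice(c) = arma::reshape(Y.col(c), Hout, Wout);
    out[n] = y;
  }
  return out;
}

// [[Rcpp::export]]
List nn_conv_bwd(List xs, List dys, const arma::mat& W,
                 int kh, int kw, int stride, int pad) {
  const int N = xs.size();
  List dxs(N);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(W.n_cols, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::cube x = as<arma::cube>(xs[n]);
    arma::cube dy = as<arma::cube>(dys[n]);
    const int Hout = dy.n_rows, Wout = dy.n_cols, Cout = dy.n_slices;
    arma::mat dY(Hout * (size_t)Wout, Cout);
    for (int c = 0; c < Cout; ++c)
      dY.col(c) = arma::vectorise(dy.slice(c));
    arma::mat M = im2col(x, kh, kw, stride, pad, Hout, Wout);
    dW += M.t() * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dM = dY * W.t();
    arma::cube dx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
    col2im_add(dx, dM, kh, kw, stride, pad, Hout, Wout);
    dxs[n] = dx;
  }
  return List::create(_["dx"] = dxs, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List nn_pool_fwd(List xs) {
  const int N = xs.size();
  List out(N), idx(N);
  for (int n = 0; n < N; ++n) {
    arma::cube x = as<arma::cube>(xs[n]);
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    const int Ho = H / 2, Wo = W / 2;
    arma::cube y(Ho, Wo, C);
    arma::icube id(Ho, Wo, C);
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = x(2 * i, 2 * j, c);
          long long bi = 2 * i + (long long)H * (2 * j) + (long long)H * W * c;
          for (int dj = 0; dj < 2; ++dj) for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) {
              best = v;
              bi = (2 * i + di) + (long long)H * (2 * j + dj) + (long long)H * W * c;
            }
          }
          y(i, j, c) = best;
          id(i, j, c) = bi;
        }
      }
    }
    out[n] = y;
    idx[n] = id;
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
List nn_pool_bwd(List idxs, List dys, int H, int W) {
  const int N = idxs.size();
  List dxs(N);
  for (int n = 0; n < N; ++n) {
    arma::icube id = as<arma::icube>(idxs[n]);
    arma::cube dy = as<arma::cube>(dys[n]);
    arma::cube dx(H, W, dy.n_slices, arma::fill::zeros);
    double* px = dx.memptr();
    const long long m = id.n_elem;
    const double* pdy = dy.memptr();
    const arma::sword* pid = id.memptr();
    for (long long k = 0; k < m; ++k) px[pid[k]] += pdy[k];
    dxs[n] = dx;
  }
  return dxs;
}

// [[Rcpp::export]]
List nn_upconv_fwd(List xs, const arma::mat& W, const arma::vec& b) {
  const int N = xs.size();
  const int Cout = W.n_cols / 4;
  List out(N);
  for (int n = 0; n < N; ++n) {
    arma::cube x = as<arma::cube>(xs[n]);
    const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
    arma::mat X(H * (size_t)Wd, Cin);
    for (int c = 0; c < Cin; ++c) X.col(c) = arma::vectorise(x.slice(c));
    arma::mat G = X * W;  // HW x 4Cout
    arma::cube y(2 * H, 2 * Wd, Cout);
    for (int co = 0; co < Cout; ++co) {
      for (int di = 0; di < 2; ++di) for (int dj = 0; dj < 2; ++dj) {
        const arma::mat g = arma::reshape(G.col((size_t)co * 4 + di * 2 + dj), H, Wd);
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            y(2 * i + di, 2 * j + dj, co) = g(i, j) + b(co);
      }
    }
    out[n] = y;
  }
  return out;
}

// [[Rcpp::export]]
List nn_upconv_bwd(List xs, List dys, const arma::mat& W) {
  const int N = xs.size();
  const int Cout = W.n_cols / 4;
  List dxs(N);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::cube x = as<arma::cube>(xs[n]);
    arma::cube dy = as<arma::cube>(dys[n]);
    const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
    arma::mat X(H * (size_t)Wd, Cin);
    for (int c = 0; c < Cin; ++c) X.col(c) = arma::vectorise(x.slice(c));
    arma::mat G(H * (size_t)Wd, 4 * (size_t)Cout);
    for (int co = 0; co < Cout; ++co) {
      for (int di = 0; di < 2; ++di) for (int dj = 0; dj < 2; ++dj) {
        arma::mat g(H, Wd);
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            g(i, j) = dy(2 * i + di, 2 * j + dj, co);
        G.col((size_t)co * 4 + di * 2 + dj) = arma::vectorise(g);
        db(co) += arma::accu(g);
      }
    }
    dW += X.t() * G;
    arma::mat dX = G * W.t();
    arma::cube dx(H, Wd, Cin);
    for (int c = 0; c < Cin; ++c) dx.slice(c) = arma::reshape(dX.col(c), H, Wd);
    dxs[n] = dx;
  }
  return List::create(_["dx"] = dxs, _["dW"] = dW, _["db"] = db);
}

// 8-connected components of equal positive values.
// [[Rcpp::export]]
IntegerMatrix label8(const IntegerMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (m(i, j) <= 0 || lab(i, j) != 0) continue;
      const int v = m(i, j);
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        const std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (m(ni, nj) == v && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Variable-density Poisson-disk thinning: visit pixels in `order`
// (0-based column-major linear indices); keep a pixel when no previously
// kept pixel lies within its local radius r[p].
// [[Rcpp::export]]
LogicalMatrix pdisk_thin(int nr, int nc, const IntegerVector& order,
                         const NumericVector& r) {
  LogicalMatrix keep(nr, nc);
  for (int k = 0; k < order.size(); ++k) {
    const int p = order[k];
    const int i = p % nr, j = p / nr;
    const double rp = r[p];
    const int R = (int)std::ceil(rp);
    bool ok = true;
    for (int dj = -R; dj <= R && ok; ++dj) {
      const int nj = j + dj;
      if (nj < 0 || nj >= nc) continue;
      for (int di = -R; di <= R; ++di) {
        const int ni = i + di;
        if (ni < 0 || ni >= nr) continue;
        if (keep(ni, nj) && di * di + dj * dj < rp * rp) { ok = false; break; }
      }
    }
    if (ok) keep(i, j) = true;
  }
  return keep;
}

// Batch normalisation over a batch of cubes: statistics per channel across
// batch and space.
// [[Rcpp::export]]
List nn_bn_fwd(List xs, const arma::vec& gamma, const arma::vec& beta,
               const arma::vec& rm, const arma::vec& rv, bool training,
               double momentum, double eps) {
  const int N = xs.size();
  std::vector<arma::cube> x(N);
  for (int n = 0; n < N; ++n) x[n] = as<arma::cube>(xs[n]);
  const int C = x[0].n_slices;
  arma::vec mu(C), v(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0; long long m = 0;
      for (int n = 0; n < N; ++n) {
        s += arma::accu(x[n].slice(c));
        s2 += arma::accu(arma::square(x[n].slice(c)));
        m += x[n].slice(c).n_elem;
      }
      mu(c) = s / m;
      v(c) = s2 / m - mu(c) * mu(c);
    }
  } else {
    mu = rm; v = rv;
  }
  arma::vec invstd = 1.0 / arma::sqrt(v + eps);
  List ys(N), xhats(N);
  for (int n = 0; n < N; ++n) {
    arma::cube xh = x[n];
    arma::cube y = x[n];
    for (int c = 0; c < C; ++c) {
      xh.slice(c) = (x[n].slice(c) - mu(c)) * invstd(c);
      y.slice(c) = xh.slice(c) * gamma(c) + beta(c);
    }
    xhats[n] = xh;
    ys[n] = y;
  }
  arma::vec nrm = rm, nrv = rv;
  if (training) {
    nrm = (1 - momentum) * rm + momentum * mu;
    nrv = (1 - momentum) * rv + momentum * v;
  }
  return List::create(_["y"] = ys, _["xhat"] = xhats, _["invstd"] = invstd,
                      _["rm"] = nrm, _["rv"] = nrv);
}

// [[Rcpp::export]]
List nn_bn_bwd(List dys, List xhats, const arma::vec& invstd,
               const arma::vec& gamma) {
  const int N = dys.size();
  std::vector<arma::cube> dy(N), xh(N);
  for (int n = 0; n < N; ++n) {
    dy[n] = as<arma::cube>(dys[n]);
    xh[n] = as<arma::cube>(xhats[n]);
  }
  const int C = dy[0].n_slices;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  arma::vec m(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      dgamma(c) += arma::accu(dy[n].slice(c) % xh[n].slice(c));
      dbeta(c) += arma::accu(dy[n].slice(c));
      m(c) += dy[n].slice(c).n_elem;
    }
  }
  List dxs(N);
  for (int n = 0; n < N; ++n) {
    arma::cube dx = dy[n];
    for (int c = 0; c < C; ++c) {
      dx.slice(c) = (dy[n].slice(c) - dbeta(c) / m(c) -
                     xh[n].slice(c) * (dgamma(c) / m(c))) *
        (gamma(c) * invstd(c));
    }
    dxs[n] = dx;
  }
  return List::create(_["dx"] = dxs, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List nn_relu_fwd(List xs) {
  const int N = xs.size();
  List ys(N);
  for (int n = 0; n < N; ++n) {
    arma::cube x = as<arma::cube>(xs[n]);
    x.transform([](double v) { return v > 0 ? v : 0.0; });
    ys[n] = x;
  }
  return ys;
}

// [[Rcpp::export]]
List nn_relu_bwd(List dys, List ys) {
  const int N = dys.size();
  List dxs(N);
  for (int n = 0; n < N; ++n) {
    arma::cube dy = as<arma::cube>(dys[n]);
    arma::cube y = as<arma::cube>(ys[n]);
    dxs[n] = dy % arma::conv_to<arma::cube>::from(y > 0);
  }
  return dxs;
}
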