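#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- 8-connected component labelling (two-pass, union-find) ----

static int uf_find(std::vector<int> &par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// binary: matrix with nonzero = foreground. Returns integer label matrix
// (0 = background, components numbered 1..n in raster order of first pixel).
// [[Rcpp::export]]
IntegerMatrix label8_cpp(NumericMatrix binary) {
  int H = binary.nrow(), W = binary.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> par(1, 0);
  int nextLab = 1;
  // raster scan column-major consistent with R storage; neighbourhood is
  // symmetric so scan order only affects provisional labels
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (binary(i, j) == 0) continue;
      int best = 0;
      int cand[4][2] = {{i - 1, j - 1}, {i - 1, j}, {i - 1, j + 1}, {i, j - 1}};
      std::vector<int> neigh;
      for (int c = 0; c < 4; ++c) {
        int ii = cand[c][0], jj = cand[c][1];
        if (ii < 0 || jj < 0 || ii >= H || jj >= W) continue;
        int l = lab(ii, jj);
        if (l > 0) neigh.push_back(uf_find(par, l));
      }
      if (neigh.empty()) {
        par.push_back(nextLab);
        best = nextLab++;
      } else {
        best = *std::min_element(neigh.begin(), neigh.end());
        for (size_t c = 0; c < neigh.size(); ++c) par[neigh[c]] = best;
      }
      lab(i, j) = best;
    }
  }
  // second pass: resolve + renumber in raster order (row-major reading order)
  std::vector<int> renum(nextLab, 0);
  int k = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (lab(i, j) == 0) continue;
      int r = uf_find(par, lab(i, j));
      if (renum[r] == 0) renum[r] = ++k;
    }
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > 0) lab(i, j) = renum[uf_find(par, lab(i, j))];
  return lab;
}

// ---- non-local means ----
// Patch distance D(p,q) = mean squared intensity difference over the
// (2*pr+1)^2 patch (edge-replicated padding); weight w = exp(-D / h^2);
// output = sum_q w * I(q) / sum_q w over the (2*sr+1)^2 search window.
// Offset + summed-area-table formulation: O(#offsets * N).
// [[Rcpp::export]]
NumericMatrix nlm_cpp(NumericMatrix img, int pr, int sr, double h) {
  int H = img.nrow(), W = img.ncol();
  int M = pr + sr;
  int Hp = H + 2 * M, Wp = W + 2 * M;
  std::vector<double> pad((size_t)Hp * Wp);
  for (int j = 0; j < Wp; ++j) {
    int js = std::min(std::max(j - M, 0), W - 1);
    for (int i = 0; i < Hp; ++i) {
      int is = std::min(std::max(i - M, 0), H - 1);
      pad[(size_t)j * Hp + i] = img(is, js);
    }
  }
  int np = (2 * pr + 1) * (2 * pr + 1);
  double invh2 = 1.0 / (h * h * np);
  std::vector<double> num((size_t)H * W, 0.0), den((size_t)H * W, 0.0);
  // integral image of squared differences for each offset
  std::vector<double> sat((size_t)(Hp + 1) * (Wp + 1));
  int satH = Hp + 1;
  for (int dy = -sr; dy <= sr; ++dy) {
    for (int dx = -sr; dx <= sr; ++dx) {
      // sat(i+1, j+1) = sum of sq diff over pad[0..i, 0..j]
      for (int j = 0; j <= Wp; ++j) sat[(size_t)j * satH] = 0.0;
      for (int i = 0; i <= Hp; ++i) sat[i] = 0.0;
      for (int j = 1; j <= Wp; ++j) {
        double colsum = 0.0;
        for (int i = 1; i <= Hp; ++i) {
          int qi = (i - 1) + dy, qj = (j - 1) + dx;
          double d = 0.0;
          if (qi >= 0 && qi < Hp && qj >= 0 && qj < Wp) {
            d = pad[(size_t)(j - 1) * Hp + (i - 1)] - pad[(size_t)qj * Hp + qi];
            d *= d;
          } else {
            // q-patch pixels outside the padded frame cannot occur for
            // valid search offsets (|dy|,|dx| <= sr and margin = pr+sr)
            d = 0.0;
          }
          colsum += d;
          sat[(size_t)j * satH + i] = sat[(size_t)(j - 1) * satH + i] + colsum;
        }
      }
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          // patch centred at padded coord (i+M, j+M)
          int r0 = i + M - pr, c0 = j + M - pr;
          int r1 = i + M + pr + 1, c1 = j + M + pr + 1;
          double ssd = sat[(size_t)c1 * satH + r1] - sat[(size_t)c0 * satH + r1]
                     - sat[(size_t)c1 * satH + r0] + sat[(size_t)c0 * satH + r0];
          double w = std::exp(-ssd * invh2);
          double q = pad[(size_t)(j + M + dx) * Hp + (i + M + dy)];
          num[(size_t)j * H + i] += w * q;
          den[(size_t)j * H + i] += w;
        }
      }
    }
  }
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = num[(size_t)j * H + i] / den[(size_t)j * H + i];
  return out;
}

// ---- CNN tensor primitives ----
// x: array (H, W, C, N) in R's column-major layout.
// im2col output: matrix with N*oH*oW rows, k*k*C cols. Row index runs
// fastest over oH (rows), then oW, then image n.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int pad, int stride) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out((R_xlen_t)N * oH * oW, k * k * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = c * k * k + kj * k + ki;
        double *pout = &out(0, col);
        for (int n = 0; n < N; ++n) {
          const double *pim = px + ((size_t)n * C + c) * H * W;
          for (int oj = 0; oj < oW; ++oj) {
            int jj = oj * stride - pad + kj;
            bool jin = (jj >= 0 && jj < W);
            size_t base = (size_t)n * oH * oW + (size_t)oj * oH;
            for (int oi = 0; oi < oH; ++oi) {
              int ii = oi * stride - pad + ki;
              double v = 0.0;
              if (jin && ii >= 0 && ii < H) v = pim[(size_t)jj * H + ii];
              pout[base + oi] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int pad, int stride) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C * N);
  double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = c * k * k + kj * k + ki;
        const double *pcol = &cols(0, col);
        for (int n = 0; n < N; ++n) {
          double *pim = px + ((size_t)n * C + c) * H * W;
          for (int oj = 0; oj < oW; ++oj) {
            int jj = oj * stride - pad + kj;
            if (jj < 0 || jj >= W) continue;
            size_t base = (size_t)n * oH * oW + (size_t)oj * oH;
            for (int oi = 0; oi < oH; ++oi) {
              int ii = oi * stride - pad + ki;
              if (ii < 0 || ii >= H) continue;
              pim[(size_t)jj * H + ii] += pcol[base + oi];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Pooling. type 0 = max, 1 = average. Padding uses -Inf (max) / zero-count
// exclusion (average) so padded cells never contribute.
// [[Rcpp::export]]
List pool_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                  int size, int stride, int pad, int type) {
  int oH = (H + 2 * pad - size) / stride + 1;
  int oW = (W + 2 * pad - size) / stride + 1;
  NumericVector y((R_xlen_t)oH * oW * C * N);
  IntegerVector arg((R_xlen_t)oH * oW * C * N);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = arg.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *pim = px + ((size_t)n * C + c) * H * W;
      double *pout = py + ((size_t)n * C + c) * oH * oW;
      int *paout = pa + ((size_t)n * C + c) * oH * oW;
      for (int oj = 0; oj < oW; ++oj) {
        for (int oi = 0; oi < oH; ++oi) {
          double best = R_NegInf, sum = 0.0;
          int cnt = 0, bi = -1;
          for (int kj = 0; kj < size; ++kj) {
            int jj = oj * stride - pad + kj;
            if (jj < 0 || jj >= W) continue;
            for (int ki = 0; ki < size; ++ki) {
              int ii = oi * stride - pad + ki;
              if (ii < 0 || ii >= H) continue;
              double v = pim[(size_t)jj * H + ii];
              sum += v; ++cnt;
              if (v > best) { best = v; bi = jj * H + ii; }
            }
          }
          size_t o = (size_t)oj * oH + oi;
          if (type == 0) { pout[o] = best; paout[o] = bi; }
          else { pout[o] = sum / cnt; paout[o] = cnt; }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oH, oW, C, N);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector pool_bwd_cpp(NumericVector dy, IntegerVector arg,
                           int H, int W, int C, int N,
                           int size, int stride, int pad, int type) {
  int oH = (H + 2 * pad - size) / stride + 1;
  int oW = (W + 2 * pad - size) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double *pdy = dy.begin();
  const int *pa = arg.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *pim = pdx + ((size_t)n * C + c) * H * W;
      const double *pout = pdy + ((size_t)n * C + c) * oH * oW;
      const int *paout = pa + ((size_t)n * C + c) * oH * oW;
      for (int oj = 0; oj < oW; ++oj) {
        for (int oi = 0; oi < oH; ++oi) {
          size_t o = (size_t)oj * oH + oi;
          if (type == 0) {
            pim[paout[o]] += pout[o];
          } else {
            double g = pout[o] / paout[o];
            for (int kj = 0; kj < size; ++kj) {
              int jj = oj * stride - pad + kj;
              if (jj < 0 || jj >= W) continue;
              for (int ki = 0; ki < size; ++ki) {
                int ii = oi * stride - pad + ki;
                if (ii < 0 || ii >= H) continue;
                pim[(size_t)jj * H + ii] += g;
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
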