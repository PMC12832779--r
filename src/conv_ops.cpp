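#include <Rcpp.h>
using namespace Rcpp;

// Volumes are stored as [C, V] matrices, V = d1*d2*d3 voxels in R's
// column-major order (axis 1 fastest). im2col rows are channel-major:
// row = c*k^3 + t1 + k*t2 + k^2*t3, so each channel's k^3 taps are
// contiguous and grouped convolutions can slice row blocks.

static inline int out_dim(int d, int k, int stride, int pad, int dilation) {
  return (d + 2 * pad - ((k - 1) * dilation + 1)) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col3d_cpp(const NumericMatrix& x, const IntegerVector& dims,
                           int k, int stride, int pad, int dilation) {
  const int C = x.nrow();
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = out_dim(d1, k, stride, pad, dilation);
  const int o2 = out_dim(d2, k, stride, pad, dilation);
  const int o3 = out_dim(d3, k, stride, pad, dilation);
  const int k3 = k * k * k;
  NumericMatrix cols(C * k3, o1 * o2 * o3);
  const double* xp = x.begin();
  double* cp = cols.begin();
  const int nrow = C * k3;
  for (int z = 0; z < o3; ++z) {
    for (int y = 0; y < o2; ++y) {
      for (int xo = 0; xo < o1; ++xo) {
        const int col = xo + o1 * (y + o2 * z);
        double* colp = cp + (size_t)col * nrow;
        for (int c = 0; c < C; ++c) {
          for (int t3 = 0; t3 < k; ++t3) {
            const int i3 = z * stride - pad + t3 * dilation;
            for (int t2 = 0; t2 < k; ++t2) {
              const int i2 = y * stride - pad + t2 * dilation;
              for (int t1 = 0; t1 < k; ++t1) {
                const int i1 = xo * stride - pad + t1 * dilation;
                const int row = c * k3 + t1 + k * (t2 + k * t3);
                if (i1 >= 0 && i1 < d1 && i2 >= 0 && i2 < d2 &&
                    i3 >= 0 && i3 < d3) {
                  const int v = i1 + d1 * (i2 + d2 * i3);
                  colp[row] = xp[c + (size_t)v * C];
                } else {
                  colp[row] = 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix col2im3d_cpp(const NumericMatrix& cols, int C,
                           const IntegerVector& dims, int k, int stride,
                           int pad, int dilation) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = out_dim(d1, k, stride, pad, dilation);
  const int o2 = out_dim(d2, k, stride, pad, dilation);
  const int o3 = out_dim(d3, k, stride, pad, dilation);
  const int k3 = k * k * k;
  NumericMatrix x(C, d1 * d2 * d3);
  const double* cp = cols.begin();
  double* xp = x.begin();
  const int nrow = C * k3;
  for (int z = 0; z < o3; ++z) {
    for (int y = 0; y < o2; ++y) {
      for (int xo = 0; xo < o1; ++xo) {
        const int col = xo + o1 * (y + o2 * z);
        const double* colp = cp + (size_t)col * nrow;
        for (int c = 0; c < C; ++c) {
          for (int t3 = 0; t3 < k; ++t3) {
            const int i3 = z * stride - pad + t3 * dilation;
            if (i3 < 0 || i3 >= d3) continue;
            for (int t2 = 0; t2 < k; ++t2) {
              const int i2 = y * stride - pad + t2 * dilation;
              if (i2 < 0 || i2 >= d2) continue;
              for (int t1 = 0; t1 < k; ++t1) {
                const int i1 = xo * stride - pad + t1 * dilation;
                if (i1 < 0 || i1 >= d1) continue;
                const int row = c * k3 + t1 + k * (t2 + k * t3);
                const int v = i1 + d1 * (i2 + d2 * i3);
                xp[c + (size_t)v * C] += colp[row];
              }
            }
          }
        }
      }
    }
  }
  return x;
}

// ---- direct convolution kernels ---------------------------------------------
// im2col materialization is far too expensive for large-kernel 3D convs
// (k=7 on 16^3 builds ~90 MB of columns per call); these kernels loop taps
// directly over channel-planar copies so every inner loop is contiguous.

struct ConvGeom {
  int d1, d2, d3, o1, o2, o3, k, stride, pad, dil;
};

static inline void tap_range(int t, const ConvGeom& g, int d, int omax,
                             int& lo, int& hi) {
  // output positions o with 0 <= o*stride - pad + t*dil < d
  const int off = g.pad - t * g.dil;
  lo = off > 0 ? (off + g.stride - 1) / g.stride : 0;
  int hi_excl = (d + off + g.stride - 1) / g.stride; // ceil((d+off)/stride)
  hi = hi_excl < omax ? hi_excl : omax;
  if (lo > hi) lo = hi;
}

static ConvGeom make_geom(const Rcpp::IntegerVector& dims, int k, int stride,
                          int pad, int dil) {
  ConvGeom g{dims[0], dims[1], dims[2], 0, 0, 0, k, stride, pad, dil};
  g.o1 = out_dim(g.d1, k, stride, pad, dil);
  g.o2 = out_dim(g.d2, k, stride, pad, dil);
  g.o3 = out_dim(g.d3, k, stride, pad, dil);
  return g;
}

// [[Rcpp::export]]
NumericMatrix conv3d_fwd_cpp(const NumericMatrix& x, const NumericMatrix& W,
                             const IntegerVector& dims, int k, int stride,
                             int pad, int dil, int groups) {
  const int C = x.nrow();
  const int Cout = W.nrow();
  const ConvGeom g = make_geom(dims, k, stride, pad, dil);
  const size_t V = (size_t)g.d1 * g.d2 * g.d3;
  const size_t Vo = (size_t)g.o1 * g.o2 * g.o3;
  const int cg = C / groups, og = Cout / groups, k3 = k * k * k;
  std::vector<double> xp(V * C), yp(Vo * Cout, 0.0);
  for (size_t v = 0; v < V; ++v)
    for (int c = 0; c < C; ++c) xp[(size_t)c * V + v] = x[v * C + c];
  for (int grp = 0; grp < groups; ++grp) {
    for (int co = grp * og; co < (grp + 1) * og; ++co) {
      double* yc = yp.data() + (size_t)co * Vo;
      for (int cil = 0; cil < cg; ++cil) {
        const int ci = grp * cg + cil;
        const double* xc = xp.data() + (size_t)ci * V;
        for (int t3 = 0; t3 < k; ++t3) {
          int lo3, hi3; tap_range(t3, g, g.d3, g.o3, lo3, hi3);
          for (int t2 = 0; t2 < k; ++t2) {
            int lo2, hi2; tap_range(t2, g, g.d2, g.o2, lo2, hi2);
            for (int t1 = 0; t1 < k; ++t1) {
              int lo1, hi1; tap_range(t1, g, g.d1, g.o1, lo1, hi1);
              const double w = W[(size_t)(cil * k3 + t1 + k * (t2 + k * t3)) *
                                 Cout + co];
              if (w == 0.0 || lo1 >= hi1) continue;
              for (int o3 = lo3; o3 < hi3; ++o3) {
                const int i3 = o3 * stride - pad + t3 * dil;
                for (int o2 = lo2; o2 < hi2; ++o2) {
                  const int i2 = o2 * stride - pad + t2 * dil;
                  const double* __restrict__ xrow = xc + (size_t)g.d1 * (i2 + (size_t)g.d2 * i3)
                                     - pad + t1 * dil;
                  double* __restrict__ yrow = yc + (size_t)g.o1 * (o2 + (size_t)g.o2 * o3);
                  if (stride == 1) {
                    for (int o1 = lo1; o1 < hi1; ++o1)
                      yrow[o1] += w * xrow[o1];
                  } else {
                    for (int o1 = lo1; o1 < hi1; ++o1)
                      yrow[o1] += w * xrow[(size_t)o1 * stride];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  NumericMatrix y(Cout, (int)Vo);
  for (size_t v = 0; v < Vo; ++v)
    for (int c = 0; c < Cout; ++c) y[v * Cout + c] = yp[(size_t)c * Vo + v];
  return y;
}

// gradient with respect to the input
// [[Rcpp::export]]
NumericMatrix conv3d_bwd_x_cpp(const NumericMatrix& dy, const NumericMatrix& W,
                               int Cin, const IntegerVector& dims, int k,
                               int stride, int pad, int dil, int groups) {
  const int Cout = dy.nrow();
  const ConvGeom g = make_geom(dims, k, stride, pad, dil);
  const size_t V = (size_t)g.d1 * g.d2 * g.d3;
  const size_t Vo = (size_t)g.o1 * g.o2 * g.o3;
  const int cg = Cin / groups, og = Cout / groups, k3 = k * k * k;
  std::vector<double> dyp(Vo * Cout), dxp(V * Cin, 0.0);
  for (size_t v = 0; v < Vo; ++v)
    for (int c = 0; c < Cout; ++c) dyp[(size_t)c * Vo + v] = dy[v * Cout + c];
  for (int grp = 0; grp < groups; ++grp) {
    for (int co = grp * og; co < (grp + 1) * og; ++co) {
      const double* dyc = dyp.data() + (size_t)co * Vo;
      for (int cil = 0; cil < cg; ++cil) {
        const int ci = grp * cg + cil;
        double* dxc = dxp.data() + (size_t)ci * V;
        for (int t3 = 0; t3 < k; ++t3) {
          int lo3, hi3; tap_range(t3, g, g.d3, g.o3, lo3, hi3);
          for (int t2 = 0; t2 < k; ++t2) {
            int lo2, hi2; tap_range(t2, g, g.d2, g.o2, lo2, hi2);
            for (int t1 = 0; t1 < k; ++t1) {
              int lo1, hi1; tap_range(t1, g, g.d1, g.o1, lo1, hi1);
              const double w = W[(size_t)(cil * k3 + t1 + k * (t2 + k * t3)) *
                                 Cout + co];
              if (w == 0.0 || lo1 >= hi1) continue;
              for (int o3 = lo3; o3 < hi3; ++o3) {
                const int i3 = o3 * stride - pad + t3 * dil;
                for (int o2 = lo2; o2 < hi2; ++o2) {
                  const int i2 = o2 * stride - pad + t2 * dil;
                  double* __restrict__ dxrow = dxc + (size_t)g.d1 * (i2 + (size_t)g.d2 * i3)
                                 - pad + t1 * dil;
                  const double* __restrict__ dyrow = dyc + (size_t)g.o1 *
                                        (o2 + (size_t)g.o2 * o3);
                  if (stride == 1) {
                    for (int o1 = lo1; o1 < hi1; ++o1)
                      dxrow[o1] += w * dyrow[o1];
                  } else {
                    for (int o1 = lo1; o1 < hi1; ++o1)
                      dxrow[(size_t)o1 * stride] += w * dyrow[o1];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  NumericMatrix dx(Cin, (int)V);
  for (size_t v = 0; v < V; ++v)
    for (int c = 0; c < Cin; ++c) dx[v * Cin + c] = dxp[(size_t)c * V + v];
  return dx;
}

// gradient with respect to the weights
// [[Rcpp::export]]
NumericMatrix conv3d_bwd_w_cpp(const NumericMatrix& x, const NumericMatrix& dy,
                               const IntegerVector& dims, int k, int stride,
                               int pad, int dil, int groups) {
  const int Cin = x.nrow();
  const int Cout = dy.nrow();
  const ConvGeom g = make_geom(dims, k, stride, pad, dil);
  const size_t V = (size_t)g.d1 * g.d2 * g.d3;
  const size_t Vo = (size_t)g.o1 * g.o2 * g.o3;
  const int cg = Cin / groups, og = Cout / groups, k3 = k * k * k;
  std::vector<double> xp(V * Cin), dyp(Vo * Cout);
  for (size_t v = 0; v < V; ++v)
    for (int c = 0; c < Cin; ++c) xp[(size_t)c * V + v] = x[v * Cin + c];
  for (size_t v = 0; v < Vo; ++v)
    for (int c = 0; c < Cout; ++c) dyp[(size_t)c * Vo + v] = dy[v * Cout + c];
  NumericMatrix dW(Cout, cg * k3);
  for (int grp = 0; grp < groups; ++grp) {
    for (int co = grp * og; co < (grp + 1) * og; ++co) {
      const double* dyc = dyp.data() + (size_t)co * Vo;
      for (int cil = 0; cil < cg; ++cil) {
        const int ci = grp * cg + cil;
        const double* xc = xp.data() + (size_t)ci * V;
        for (int t3 = 0; t3 < k; ++t3) {
          int lo3, hi3; tap_range(t3, g, g.d3, g.o3, lo3, hi3);
          for (int t2 = 0; t2 < k; ++t2) {
            int lo2, hi2; tap_range(t2, g, g.d2, g.o2, lo2, hi2);
            for (int t1 = 0; t1 < k; ++t1) {
              int lo1, hi1; tap_range(t1, g, g.d1, g.o1, lo1, hi1);
              double acc = 0.0;
              for (int o3 = lo3; o3 < hi3; ++o3) {
                const int i3 = o3 * stride - pad + t3 * dil;
                for (int o2 = lo2; o2 < hi2; ++o2) {
                  const int i2 = o2 * stride - pad + t2 * dil;
                  const double* __restrict__ xrow = xc + (size_t)g.d1 *
                                       (i2 + (size_t)g.d2 * i3) - pad + t1 * dil;
                  const double* __restrict__ dyrow = dyc + (size_t)g.o1 *
                                        (o2 + (size_t)g.o2 * o3);
                  if (stride == 1) {
                    for (int o1 = lo1; o1 < hi1; ++o1)
                      acc += dyrow[o1] * xrow[o1];
                  } else {
                    for (int o1 = lo1; o1 < hi1; ++o1)
                      acc += dyrow[o1] * xrow[(size_t)o1 * stride];
                  }
                }
              }
              dW[(size_t)(cil * k3 + t1 + k * (t2 + k * t3)) * Cout + co] = acc;
            }
          }
        }
      }
    }
  }
  return dW;
}
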