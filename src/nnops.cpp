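#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Fused numeric kernels for the network's hot paths. Shapes follow the R
// side: attention groups one query with T context slots, rows of Ks/Vs
// grouped per query with the slot index fastest; heads split the feature
// axis contiguously.

// [[Rcpp::export(name = ".att_fwd_cpp")]]
List att_fwd_cpp(NumericMatrix Q, NumericMatrix Ks, NumericMatrix Vs,
                 int T, int H) {
  int B = Q.nrow(), M = Q.ncol();
  int dh = M / H;
  double scale = 1.0 / std::sqrt((double)dh);
  NumericMatrix O(B, M);
  NumericMatrix w(B * T, H);
  std::vector<double> s(T);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      double mx = R_NegInf;
      for (int t = 0; t < T; ++t) {
        double acc = 0.0;
        int row = b * T + t;
        for (int d = h * dh; d < (h + 1) * dh; ++d) acc += Q(b, d) * Ks(row, d);
        s[t] = acc * scale;
        if (s[t] > mx) mx = s[t];
      }
      double z = 0.0;
      for (int t = 0; t < T; ++t) { s[t] = std::exp(s[t] - mx); z += s[t]; }
      for (int t = 0; t < T; ++t) {
        double wt = s[t] / z;
        int row = b * T + t;
        w(row, h) = wt;
        for (int d = h * dh; d < (h + 1) * dh; ++d) O(b, d) += wt * Vs(row, d);
      }
    }
  }
  return List::create(Named("O") = O, Named("w") = w);
}

// [[Rcpp::export(name = ".att_bwd_cpp")]]
List att_bwd_cpp(NumericMatrix g, NumericMatrix Q, NumericMatrix Ks,
                 NumericMatrix Vs, NumericMatrix w, int T, int H) {
  int B = Q.nrow(), M = Q.ncol();
  int dh = M / H;
  double scale = 1.0 / std::sqrt((double)dh);
  NumericMatrix dQ(B, M), dK(B * T, M), dV(B * T, M);
  std::vector<double> dw(T), ds(T);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      double wdSum = 0.0;
      for (int t = 0; t < T; ++t) {
        int row = b * T + t;
        double acc = 0.0;
        for (int d = h * dh; d < (h + 1) * dh; ++d) {
          dV(row, d) += w(row, h) * g(b, d);
          acc += Vs(row, d) * g(b, d);
        }
        dw[t] = acc;
        wdSum += w(row, h) * acc;
      }
      for (int t = 0; t < T; ++t) {
        int row = b * T + t;
        double d_s = w(row, h) * (dw[t] - wdSum) * scale;
        for (int d = h * dh; d < (h + 1) * dh; ++d) {
          dQ(b, d) += d_s * Ks(row, d);
          dK(row, d) += d_s * Q(b, d);
        }
      }
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}

// scatter-add rows of g into an n-row accumulator by 1-based index
// [[Rcpp::export(name = ".scatter_add_cpp")]]
NumericMatrix scatter_add_cpp(NumericMatrix g, IntegerVector idx, int n) {
  int R = g.nrow(), D = g.ncol();
  NumericMatrix out(n, D);
  for (int d = 0; d < D; ++d)
    for (int r = 0; r < R; ++r)
      out(idx[r] - 1, d) += g(r, d);
  return out;
}

// m + v recycled over rows (no intermediate allocation)
// [[Rcpp::export(name = ".add_rowvec_cpp")]]
NumericMatrix add_rowvec_cpp(NumericMatrix m, NumericVector v) {
  int n = m.nrow(), D = m.ncol();
  NumericMatrix out(n, D);
  for (int d = 0; d < D; ++d) {
    double vd = v[d];
    for (int r = 0; r < n; ++r) out(r, d) = m(r, d) + vd;
  }
  return out;
}

// channel-wise max over index groups with argmax tracking; idx is S x m of
// 1-based rows into x (0 = padding)
// [[Rcpp::export(name = ".group_max_cpp")]]
List group_max_cpp(NumericMatrix x, IntegerMatrix idx) {
  int S = idx.nrow(), m = idx.ncol(), D = x.ncol();
  NumericMatrix out(S, D);
  IntegerMatrix arg(S, D);
  for (int s = 0; s < S; ++s) {
    for (int d = 0; d < D; ++d) { out(s, d) = R_NegInf; arg(s, d) = 0; }
    for (int j = 0; j < m; ++j) {
      int row = idx(s, j);
      if (row <= 0) continue;
      for (int d = 0; d < D; ++d) {
        double v = x(row - 1, d);
        if (v > out(s, d)) { out(s, d) = v; arg(s, d) = row; }
      }
    }
  }
  return List::create(Named("max") = out, Named("arg") = arg);
}

// LeakyReLU forward; backward recovers the sign mask from the output
// [[Rcpp::export(name = ".lrelu_fwd_cpp")]]
NumericMatrix lrelu_fwd_cpp(NumericMatrix x, double slope) {
  int n = x.nrow() * x.ncol();
  NumericMatrix out(x.nrow(), x.ncol());
  for (int i = 0; i < n; ++i) out[i] = x[i] > 0 ? x[i] : slope * x[i];
  return out;
}

// [[Rcpp::export(name = ".lrelu_bwd_cpp")]]
NumericMatrix lrelu_bwd_cpp(NumericMatrix g, NumericMatrix y, double slope) {
  int n = g.nrow() * g.ncol();
  NumericMatrix out(g.nrow(), g.ncol());
  for (int i = 0; i < n; ++i) out[i] = y[i] < 0 ? slope * g[i] : g[i];
  return out;
}

// adaptive kernel responses: h[r, m] = lrelu(<dx[r, ], G[r, 6(m-1)+1..6m]>)
// [[Rcpp::export(name = ".kernel_response_fwd_cpp")]]
NumericMatrix kernel_response_fwd_cpp(NumericMatrix dx, NumericMatrix G,
                                      int M, double slope) {
  int R = dx.nrow();
  NumericMatrix h(R, M);
  for (int m = 0; m < M; ++m)
    for (int r = 0; r < R; ++r) {
      double acc = 0.0;
      for (int d = 0; d < 6; ++d) acc += dx(r, d) * G(r, 6 * m + d);
      h(r, m) = acc > 0 ? acc : slope * acc;
    }
  return h;
}

// [[Rcpp::export(name = ".kernel_response_bwd_cpp")]]
NumericMatrix kernel_response_bwd_cpp(NumericMatrix g, NumericMatrix h,
                                      NumericMatrix dx, int M, double slope) {
  int R = dx.nrow();
  NumericMatrix dG(R, 6 * M);
  for (int m = 0; m < M; ++m)
    for (int r = 0; r < R; ++r) {
      double d_pre = h(r, m) < 0 ? slope * g(r, m) : g(r, m);
      for (int d = 0; d < 6; ++d) dG(r, 6 * m + d) = dx(r, d) * d_pre;
    }
  return dG;
}

// channel-wise softmax pooling over K-neighbour blocks (rows grouped per
// point, neighbour index fastest)
// [[Rcpp::export(name = ".softmax_pool_fwd_cpp")]]
List softmax_pool_fwd_cpp(NumericMatrix h, int K) {
  int N = h.nrow() / K, M = h.ncol();
  NumericMatrix pooled(N, M), w(h.nrow(), M);
  for (int m = 0; m < M; ++m)
    for (int i = 0; i < N; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double v = h(i * K + k, m);
        if (v > mx) mx = v;
      }
      double z = 0.0;
      for (int k = 0; k < K; ++k) z += std::exp(h(i * K + k, m) - mx);
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        double wt = std::exp(h(i * K + k, m) - mx) / z;
        w(i * K + k, m) = wt;
        acc += wt * h(i * K + k, m);
      }
      pooled(i, m) = acc;
    }
  return List::create(Named("pooled") = pooled, Named("weights") = w);
}

// [[Rcpp::export(name = ".softmax_pool_bwd_cpp")]]
NumericMatrix softmax_pool_bwd_cpp(NumericMatrix g, NumericMatrix w,
                                   NumericMatrix h, NumericMatrix pooled,
                                   int K) {
  int N = pooled.nrow(), M = pooled.ncol();
  NumericMatrix dh(h.nrow(), M);
  for (int m = 0; m < M; ++m)
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < K; ++k) {
        int r = i * K + k;
        dh(r, m) = g(i, m) * w(r, m) * (1.0 + h(r, m) - pooled(i, m));
      }
  return dh;
}

// gather rows from the virtual row-concatenation [a; b] (1-based idx)
// [[Rcpp::export(name = ".gather2_cpp")]]
NumericMatrix gather2_cpp(NumericMatrix a, NumericMatrix b,
                          IntegerVector idx) {
  int na = a.nrow(), D = a.ncol(), R = idx.size();
  NumericMatrix out(R, D);
  for (int d = 0; d < D; ++d)
    for (int r = 0; r < R; ++r) {
      int i = idx[r] - 1;
      out(r, d) = i < na ? a(i, d) : b(i - na, d);
    }
  return out;
}

// [[Rcpp::export(name = ".scatter2_cpp")]]
List scatter2_cpp(NumericMatrix g, IntegerVector idx, int na, int nb) {
  int D = g.ncol(), R = idx.size();
  NumericMatrix da(na, D), db(nb, D);
  for (int d = 0; d < D; ++d)
    for (int r = 0; r < R; ++r) {
      int i = idx[r] - 1;
      if (i < na) da(i, d) += g(r, d);
      else db(i - na, d) += g(r, d);
    }
  return List::create(Named("da") = da, Named("db") = db);
}

// in-place row-vector add onto a freshly allocated matrix
// [[Rcpp::export(name = ".add_rowvec_ip_cpp")]]
NumericMatrix add_rowvec_ip_cpp(NumericMatrix m, NumericVector v) {
  int n = m.nrow(), D = m.ncol();
  for (int d = 0; d < D; ++d) {
    double vd = v[d];
    for (int r = 0; r < n; ++r) m(r, d) += vd;
  }
  return m;
}

// backward of group_max: route each output gradient to its argmax row
// [[Rcpp::export(name = ".group_max_bwd_cpp")]]
NumericMatrix group_max_bwd_cpp(NumericMatrix g, IntegerMatrix arg, int n) {
  int S = g.nrow(), D = g.ncol();
  NumericMatrix out(n, D);
  for (int d = 0; d < D; ++d)
    for (int s = 0; s < S; ++s) {
      int row = arg(s, d);
      if (row > 0) out(row - 1, d) += g(s, d);
    }
  return out;
}
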