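// Fused gather/scatter kernels for arc-based multi-head attention.
// Dense projections stay in R/BLAS; these loops avoid materialising
// arcs x (C*d) intermediates. All node-feature matrices arrive
// TRANSPOSED ((C*d) x n) so per-node feature vectors are contiguous.
#include <Rcpp.h>
using namespace Rcpp;

// Per-arc scaled dot-product scores, one column per head.
// [[Rcpp::export(name = ".arc_attention_scores_t")]]
NumericMatrix arc_attention_scores_t(const NumericMatrix& Qt,
                                     const NumericMatrix& Kt,
                                     const IntegerVector& src,
                                     const IntegerVector& dst,
                                     int C, int d) {
  const int A = src.size();
  const int D = Qt.nrow();
  NumericMatrix S(A, C);
  const double scale = 1.0 / std::sqrt((double)d);
  const double* q = Qt.begin();
  const double* k = Kt.begin();
  for (int a = 0; a < A; ++a) {
    const double* qi = q + (size_t)(dst[a] - 1) * D;
    const double* kj = k + (size_t)(src[a] - 1) * D;
    for (int c = 0; c < C; ++c) {
      const int off = c * d;
      double s = 0.0;
      for (int t = 0; t < d; ++t) s += qi[off + t] * kj[off + t];
      S(a, c) = s * scale;
    }
  }
  return S;
}

// Numerically stable softmax over arcs sharing a destination, per column.
// [[Rcpp::export(name = ".group_softmax")]]
NumericMatrix group_softmax_cpp(const NumericMatrix& S,
                                const IntegerVector& dst, int n) {
  const int A = S.nrow(), C = S.ncol();
  NumericMatrix out(A, C);
  std::vector<double> mx(n), sum(n);
  for (int c = 0; c < C; ++c) {
    std::fill(mx.begin(), mx.end(), R_NegInf);
    for (int a = 0; a < A; ++a) {
      const int i = dst[a] - 1;
      if (S(a, c) > mx[i]) mx[i] = S(a, c);
    }
    std::fill(sum.begin(), sum.end(), 0.0);
    for (int a = 0; a < A; ++a) {
      const int i = dst[a] - 1;
      const double e = std::exp(S(a, c) - mx[i]);
      out(a, c) = e;
      sum[i] += e;
    }
    for (int a = 0; a < A; ++a) out(a, c) /= sum[dst[a] - 1];
  }
  return out;
}

// Attention-weighted sum of neighbor values per destination (heads kept
// in concatenated blocks). Returns the transposed (C*d) x n message.
// [[Rcpp::export(name = ".attn_aggregate_t")]]
NumericMatrix attn_aggregate_t(const NumericMatrix& alpha,
                               const NumericMatrix& Vt,
                               const IntegerVector& src,
                               const IntegerVector& dst,
                               int n, int C, int d) {
  const int A = src.size();
  const int D = Vt.nrow();
  NumericMatrix Mt(D, n);
  const double* v = Vt.begin();
  double* m = Mt.begin();
  for (int a = 0; a < A; ++a) {
    const double* vj = v + (size_t)(src[a] - 1) * D;
    double* mi = m + (size_t)(dst[a] - 1) * D;
    for (int c = 0; c < C; ++c) {
      const double w = alpha(a, c);
      const int off = c * d;
      for (int t = 0; t < d; ++t) mi[off + t] += w * vj[off + t];
    }
  }
  return Mt;
}

// Reverse-mode pass through attention + aggregation: given the (already
// head-expanded, transposed) message gradient dMt, returns transposed
// gradients w.r.t. Q, K, V.
// [[Rcpp::export(name = ".attn_backward_t")]]
List attn_backward_t(const NumericMatrix& alpha,
                     const NumericMatrix& Qt,
                     const NumericMatrix& Kt,
                     const NumericMatrix& Vt,
                     const NumericMatrix& dMt,
                     const IntegerVector& src,
                     const IntegerVector& dst,
                     int C, int d) {
  const int A = src.size();
  const int D = Qt.nrow();
  const int n = Qt.ncol();
  const double scale = 1.0 / std::sqrt((double)d);
  NumericMatrix dQt(D, n), dKt(D, n), dVt(D, n);
  NumericMatrix dalpha(A, C), gs(n, C);
  const double* q = Qt.begin();
  const double* k = Kt.begin();
  const double* v = Vt.begin();
  const double* dm = dMt.begin();
  double* dq = dQt.begin();
  double* dk = dKt.begin();
  double* dv = dVt.begin();
  for (int a = 0; a < A; ++a) {
    const int i = dst[a] - 1, j = src[a] - 1;
    const double* dmi = dm + (size_t)i * D;
    const double* vj = v + (size_t)j * D;
    double* dvj = dv + (size_t)j * D;
    for (int c = 0; c < C; ++c) {
      const int off = c * d;
      const double w = alpha(a, c);
      double da = 0.0;
      for (int t = 0; t < d; ++t) {
        da += dmi[off + t] * vj[off + t];
        dvj[off + t] += w * dmi[off + t];
      }
      dalpha(a, c) = da;
      gs(i, c) += w * da;
    }
  }
  for (int a = 0; a < A; ++a) {
    const int i = dst[a] - 1, j = src[a] - 1;
    const double* qi = q + (size_t)i * D;
    const double* kj = k + (size_t)j * D;
    double* dqi = dq + (size_t)i * D;
    double* dkj = dk + (size_t)j * D;
    for (int c = 0; c < C; ++c) {
      const int off = c * d;
      const double ds = alpha(a, c) * (dalpha(a, c) - gs(i, c)) * scale;
      for (int t = 0; t < d; ++t) {
        dqi[off + t] += ds * kj[off + t];
        dkj[off + t] += ds * qi[off + t];
      }
    }
  }
  return List::create(_["dQt"] = dQt, _["dKt"] = dKt, _["dVt"] = dVt);
}
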