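// Partitioned multi-head scaled-dot-product attention, forward and backward.
// The per-(item, head, chunk) loop is the innermost hot path of the network;
// everything around it (projections, feedforwards, convolutions) runs as
// BLAS matrix products in R. Scores are held keys-by-queries
// (St[k, t] = <K_k, Q_t>) so the softmax over keys walks down contiguous
// columns; during training the softmax matrices are cached (as floats,
// behind an external pointer) for the backward pass.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;
// Attention arithmetic runs in single precision (the network's working
// precision); inputs and outputs cross the R boundary as doubles. The
// softmax exponential is a 4-wide SSE2 polynomial (degree-6 on the reduced
// argument, power-of-two factor assembled in the exponent field):
// |rel err| ~ 2e-7 and the arithmetic is platform-deterministic.
#include <emmintrin.h>

#define RESTRICT __restrict__

static inline __m128 exp_ps_neg(__m128 x) {
  x = _mm_max_ps(x, _mm_set1_ps(-80.0f)); // exp(-80) ~ 0 within float
  const __m128 log2e = _mm_set1_ps(1.44269504f);
  const __m128 ln2 = _mm_set1_ps(0.69314718f);
  __m128 t = _mm_add_ps(_mm_mul_ps(x, log2e), _mm_set1_ps(0.5f));
  __m128i k = _mm_cvttps_epi32(t);
  __m128 kf = _mm_cvtepi32_ps(k);
  // floor for negative t: trunc rounds toward zero
  __m128 adj = _mm_and_ps(_mm_cmplt_ps(t, kf), _mm_set1_ps(1.0f));
  kf = _mm_sub_ps(kf, adj);
  k = _mm_cvttps_epi32(kf);
  __m128 r = _mm_sub_ps(x, _mm_mul_ps(kf, ln2));
  __m128 p = _mm_set1_ps(1.0f / 720);
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(1.0f / 120));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(1.0f / 24));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(1.0f / 6));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(0.5f));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(1.0f));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(1.0f));
  __m128i ebits = _mm_slli_epi32(_mm_add_epi32(k, _mm_set1_epi32(127)), 23);
  return _mm_mul_ps(p, _mm_castsi128_ps(ebits));
}

// training-time cache of the softmax matrices; kept outside R's heap and
// reused across calls of the same layer, so steady-state training allocates
// nothing here
struct AttnCache {
  float* p;
  size_t n;
  explicit AttnCache(size_t n_) : p(new float[n_]), n(n_) {}
  ~AttnCache() { delete[] p; }
};

// in-place softmax of one column whose maximum is already known
static inline void softmax_col(float* c, const int n, const float mx) {
  const __m128 vmx = _mm_set1_ps(mx);
  __m128 vs = _mm_setzero_ps();
  int i = 0;
  for (; i + 4 <= n; i += 4) {
    __m128 v = exp_ps_neg(_mm_sub_ps(_mm_loadu_ps(c + i), vmx));
    _mm_storeu_ps(c + i, v);
    vs = _mm_add_ps(vs, v);
  }
  float buf[4];
  _mm_storeu_ps(buf, vs);
  float s = buf[0] + buf[1] + buf[2] + buf[3];
  for (; i < n; ++i) { c[i] = std::exp(c[i] - mx); s += c[i]; }
  const float inv = 1.0f / s;
  const __m128 vinv = _mm_set1_ps(inv);
  for (i = 0; i + 4 <= n; i += 4) {
    _mm_storeu_ps(c + i, _mm_mul_ps(_mm_loadu_ps(c + i), vinv));
  }
  for (; i < n; ++i) c[i] *= inv;
}

static inline void axpy_f(float* RESTRICT y, const float* RESTRICT x,
                          const float a, const int n) {
  for (int i = 0; i < n; ++i) y[i] += a * x[i];
}

static inline float dot_f(const float* RESTRICT a, const float* RESTRICT b,
                          const int n) {
  float s = 0.0f;
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// gather one (dh x Tp) head-chunk of a (C, T, B) double cube into a
// row-major float buffer: dst[i * Tp + t] = x[off + i + t * C]
static inline void gather_rows(const double* x0, float* dst, const size_t off,
                               const int dh, const int Tp, const int C) {
  for (int t = 0; t < Tp; ++t) {
    const double* s = x0 + off + (size_t)t * C;
    for (int i = 0; i < dh; ++i) dst[(size_t)i * Tp + t] = (float)s[i];
  }
}

static inline void scatter_rows(double* x0, const float* src, const size_t off,
                                const int dh, const int Tp, const int C) {
  for (int t = 0; t < Tp; ++t) {
    double* d = x0 + off + (size_t)t * C;
    for (int i = 0; i < dh; ++i) d[i] = (double)src[(size_t)i * Tp + t];
  }
}

// softmax_k(scl * <K_k, Q_t>) written into St columns (keys contiguous)
static inline void chunk_scores_softmax(const float* Qr, const float* Kr,
                                        float* St, const int dh, const int Tp,
                                        const float scl) {
  for (int t = 0; t < Tp; ++t) {
    float* col = St + (size_t)t * Tp;
    std::fill(col, col + Tp, 0.0f);
    for (int i = 0; i < dh; ++i) {
      axpy_f(col, Kr + (size_t)i * Tp, scl * Qr[(size_t)i * Tp + t], Tp);
    }
    float mx = col[0];
    for (int k = 1; k < Tp; ++k) if (col[k] > mx) mx = col[k];
    softmax_col(col, Tp, mx);
  }
}

// Q, K, V: (channels, tokens, batch) cubes; partitions chunks the token axis
// for local attention (1 = global). Returns the concatenated head outputs
// and, when keep_cache, the softmax matrices for the backward pass (the
// supplied pool buffer is reused when it fits).
// [[Rcpp::export]]
Rcpp::List attn_fwd_cpp(const arma::cube& Q, const arma::cube& K,
                        const arma::cube& V, const int heads,
                        const int partitions, const bool keep_cache = false,
                        SEXP pool = R_NilValue) {
  const int C = Q.n_rows, T = Q.n_cols, B = Q.n_slices;
  const int dh = C / heads, Tp = T / partitions;
  const float scl = 1.0f / std::sqrt((float)dh);
  cube O(C, T, B);
  const double *q0 = Q.memptr(), *k0 = K.memptr(), *v0 = V.memptr();
  double* o0 = O.memptr();
  const size_t chunk_elems = (size_t)Tp * Tp;
  const size_t n_chunks = (size_t)B * heads * partitions;
  AttnCache* Pc = nullptr;
  SEXP cache_sexp = R_NilValue;
  if (keep_cache) {
    const size_t need = chunk_elems * n_chunks;
    if (pool != R_NilValue) {
      Rcpp::XPtr<AttnCache> xp(pool);
      if (xp.get() != nullptr && xp->n >= need) {
        Pc = xp.get();
        cache_sexp = pool;
      }
    }
    if (Pc == nullptr) {
      Pc = new AttnCache(need);
      cache_sexp = Rcpp::XPtr<AttnCache>(Pc, true);
    }
  }
  Rcpp::Shield<SEXP> cache_keep(cache_sexp);
  std::vector<float> Sbuf(Pc ? 0 : chunk_elems),
      Qf((size_t)dh * Tp), Kf((size_t)dh * Tp), Vf((size_t)dh * Tp),
      Of((size_t)dh * Tp);
  size_t ci = 0;
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      for (int p = 0; p < partitions; ++p, ++ci) {
        const size_t off = (size_t)h * dh + (size_t)p * Tp * C + (size_t)b * C * T;
        float* St = Pc ? Pc->p + ci * chunk_elems : Sbuf.data();
        gather_rows(q0, Qf.data(), off, dh, Tp, C);
        gather_rows(k0, Kf.data(), off, dh, Tp, C);
        gather_rows(v0, Vf.data(), off, dh, Tp, C);
        chunk_scores_softmax(Qf.data(), Kf.data(), St, dh, Tp, scl);
        // O row i at t = <St column t, V row i>
        for (int t = 0; t < Tp; ++t) {
          const float* col = St + (size_t)t * Tp;
          for (int i = 0; i < dh; ++i) {
            Of[(size_t)i * Tp + t] = dot_f(col, Vf.data() + (size_t)i * Tp, Tp);
          }
        }
        scatter_rows(o0, Of.data(), off, dh, Tp, C);
      }
    }
  }
  // wrap the outputs only now: wrapping copies, so it must happen after
  // the cube is filled
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("O") = O);
  if (keep_cache) out["cache"] = (SEXP)cache_keep;
  return out;
}

// [[Rcpp::export]]
Rcpp::List attn_bwd_cpp(const arma::cube& Q, const arma::cube& K,
                        const arma::cube& V, const arma::cube& dO,
                        const int heads, const int partitions,
                        SEXP cache = R_NilValue) {
  const int C = Q.n_rows, T = Q.n_cols, B = Q.n_slices;
  const int dh = C / heads, Tp = T / partitions;
  const float scl = 1.0f / std::sqrt((float)dh);
  cube dQ(C, T, B), dK(C, T, B), dV(C, T, B);
  const double *q0 = Q.memptr(), *k0 = K.memptr(), *v0 = V.memptr(),
               *g0 = dO.memptr();
  double *dq0 = dQ.memptr(), *dk0 = dK.memptr(), *dv0 = dV.memptr();
  const size_t chunk_elems = (size_t)Tp * Tp;
  AttnCache* Pc = nullptr;
  if (cache != R_NilValue) {
    Rcpp::XPtr<AttnCache> xp(cache);
    if (xp.get() != nullptr && xp->p != nullptr) Pc = xp.get();
  }
  std::vector<float> Sbuf(Pc ? 0 : chunk_elems), dSt(chunk_elems),
      Qf((size_t)dh * Tp), Kf((size_t)dh * Tp), Vf((size_t)dh * Tp),
      Gf((size_t)dh * Tp), Tmp((size_t)dh * Tp);
  size_t ci = 0;
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      for (int p = 0; p < partitions; ++p, ++ci) {
        const size_t off = (size_t)h * dh + (size_t)p * Tp * C + (size_t)b * C * T;
        gather_rows(q0, Qf.data(), off, dh, Tp, C);
        gather_rows(k0, Kf.data(), off, dh, Tp, C);
        gather_rows(v0, Vf.data(), off, dh, Tp, C);
        gather_rows(g0, Gf.data(), off, dh, Tp, C);
        const float* St;
        if (Pc) {
          St = Pc->p + ci * chunk_elems;
        } else {
          chunk_scores_softmax(Qf.data(), Kf.data(), Sbuf.data(), dh, Tp, scl);
          St = Sbuf.data();
        }
        // dV row i += g[i, t] * P column t
        std::fill(Tmp.begin(), Tmp.end(), 0.0f);
        for (int t = 0; t < Tp; ++t) {
          const float* col = St + (size_t)t * Tp;
          for (int i = 0; i < dh; ++i) {
            axpy_f(Tmp.data() + (size_t)i * Tp, col, Gf[(size_t)i * Tp + t], Tp);
          }
        }
        scatter_rows(dv0, Tmp.data(), off, dh, Tp, C);
        // dP column t = sum_i g[i, t] * V row i; then fused softmax backward
        for (int t = 0; t < Tp; ++t) {
          float* dcol = dSt.data() + (size_t)t * Tp;
          std::fill(dcol, dcol + Tp, 0.0f);
          for (int i = 0; i < dh; ++i) {
            axpy_f(dcol, Vf.data() + (size_t)i * Tp, Gf[(size_t)i * Tp + t], Tp);
          }
          const float* pcol = St + (size_t)t * Tp;
          const float cd = dot_f(dcol, pcol, Tp);
          for (int k = 0; k < Tp; ++k) dcol[k] = pcol[k] * (dcol[k] - cd) * scl;
        }
        // dQ[i, t] = <dS column t, K row i>; dK row i += dS[t, .] * q[i, t]
        for (int t = 0; t < Tp; ++t) {
          const float* dcol = dSt.data() + (size_t)t * Tp;
          for (int i = 0; i < dh; ++i) {
            Tmp[(size_t)i * Tp + t] = dot_f(dcol, Kf.data() + (size_t)i * Tp, Tp);
          }
        }
        scatter_rows(dq0, Tmp.data(), off, dh, Tp, C);
        std::fill(Tmp.begin(), Tmp.end(), 0.0f);
        for (int t = 0; t < Tp; ++t) {
          const float* dcol = dSt.data() + (size_t)t * Tp;
          for (int i = 0; i < dh; ++i) {
            axpy_f(Tmp.data() + (size_t)i * Tp, dcol, Qf[(size_t)i * Tp + t], Tp);
          }
        }
        scatter_rows(dk0, Tmp.data(), off, dh, Tp, C);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// im2col for 1-D convolution: x (C, T, B) already zero-padded; returns the
// (C*k, To*B) patch matrix for a single GEMM against the kernel matrix.
// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& xp, const int k, const int stride,
                     const int To) {
  const uword C = xp.n_rows, B = xp.n_slices;
  mat Xc(C * k, (uword)To * B);
  for (uword b = 0; b < B; ++b) {
    const mat& xb = xp.slice(b);
    for (uword t = 0; t < (uword)To; ++t) {
      const uword t0 = t * stride;
      double* col = Xc.colptr(b * To + t);
      for (uword j = 0; j < (uword)k; ++j) {
        const double* src = xb.colptr(t0 + j);
        std::copy(src, src + C, col + j * C);
      }
    }
  }
  return Xc;
}

// scatter-add adjoint of im2col: dXc (C*k, To*B) back to padded (C, Tp, B)
// [[Rcpp::export]]
arma::cube col2im_cpp(const arma::mat& dXc, const int C, const int Tp,
                      const int B, const int k, const int stride, const int To) {
  cube dxp(C, Tp, B, fill::zeros);
  for (uword b = 0; b < (uword)B; ++b) {
    mat& xb = dxp.slice(b);
    for (uword t = 0; t < (uword)To; ++t) {
      const uword t0 = t * stride;
      const double* col = dXc.colptr(b * To + t);
      for (uword j = 0; j < (uword)k; ++j) {
        double* dst = xb.colptr(t0 + j);
        for (int c = 0; c < C; ++c) dst[c] += col[j * C + c];
      }
    }
  }
  return dxp;
}

// fused elementwise helpers: leaky ReLU forward/backward (the mask is
// recovered from the sign of the cached output) and batch-norm statistics
// [[Rcpp::export]]
arma::vec lrelu_fwd_flat(arma::vec x, const double slope) {
  for (uword i = 0; i < x.n_elem; ++i) if (x[i] < 0) x[i] *= slope;
  return x;
}

// [[Rcpp::export]]
arma::vec lrelu_bwd_flat(const arma::vec& out, arma::vec dy, const double slope) {
  for (uword i = 0; i < out.n_elem; ++i) if (out[i] < 0) dy[i] *= slope;
  return dy;
}

// per-row mean and biased variance of a (C, m) matrix in one pass
// [[Rcpp::export]]
Rcpp::List bn_stats_cpp(const arma::mat& M) {
  const uword C = M.n_rows, m = M.n_cols;
  vec s(C, fill::zeros), ss(C, fill::zeros);
  for (uword j = 0; j < m; ++j) {
    const double* c = M.colptr(j);
    for (uword i = 0; i < C; ++i) { s[i] += c[i]; ss[i] += c[i] * c[i]; }
  }
  s /= (double)m;
  ss = ss / (double)m - s % s;
  return Rcpp::List::create(Rcpp::Named("mu") = s, Rcpp::Named("v") = ss);
}

// xhat = (M - mu) * inv_std, y = gamma * xhat + beta, both in one pass
// [[Rcpp::export]]
Rcpp::List bn_apply_cpp(const arma::mat& M, const arma::vec& mu,
                        const arma::vec& inv_std, const arma::vec& gamma,
                        const arma::vec& beta) {
  const uword C = M.n_rows, m = M.n_cols;
  mat xhat(C, m), y(C, m);
  for (uword j = 0; j < m; ++j) {
    const double* c = M.colptr(j);
    double* xh = xhat.colptr(j);
    double* yy = y.colptr(j);
    for (uword i = 0; i < C; ++i) {
      xh[i] = (c[i] - mu[i]) * inv_std[i];
      yy[i] = gamma[i] * xh[i] + beta[i];
    }
  }
  return Rcpp::List::create(Rcpp::Named("xhat") = xhat, Rcpp::Named("y") = y);
}

// batch-norm backward (training mode): returns dx and the per-channel
// gradient sums for gamma and beta
// [[Rcpp::export]]
Rcpp::List bn_bwd_cpp(const arma::mat& dY, const arma::mat& xhat,
                      const arma::vec& inv_std, const arma::vec& gamma) {
  const uword C = dY.n_rows, m = dY.n_cols;
  vec sum_dy(C, fill::zeros), sum_dy_xhat(C, fill::zeros);
  for (uword j = 0; j < m; ++j) {
    const double* dyc = dY.colptr(j);
    const double* xhc = xhat.colptr(j);
    for (uword i = 0; i < C; ++i) {
      sum_dy[i] += dyc[i];
      sum_dy_xhat[i] += dyc[i] * xhc[i];
    }
  }
  mat dx(C, m);
  const double invm = 1.0 / (double)m;
  for (uword j = 0; j < m; ++j) {
    const double* dyc = dY.colptr(j);
    const double* xhc = xhat.colptr(j);
    double* dxc = dx.colptr(j);
    for (uword i = 0; i < C; ++i) {
      dxc[i] = inv_std[i] * gamma[i] *
        (dyc[i] - invm * sum_dy[i] - xhc[i] * invm * sum_dy_xhat[i]);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = sum_dy_xhat,
                            Rcpp::Named("dbeta") = sum_dy);
}

// average pooling (kernel 2, stride 2) over the token axis of (C, T, B)
// [[Rcpp::export]]
arma::cube pool2_fwd_cpp(const arma::cube& x) {
  const uword C = x.n_rows, T = x.n_cols, B = x.n_slices;
  cube y(C, T / 2, B);
  for (uword b = 0; b < B; ++b) {
    const mat& xb = x.slice(b);
    mat& yb = y.slice(b);
    for (uword t = 0; t < T / 2; ++t) {
      const double* a = xb.colptr(2 * t);
      const double* c = xb.colptr(2 * t + 1);
      double* o = yb.colptr(t);
      for (uword i = 0; i < C; ++i) o[i] = 0.5 * (a[i] + c[i]);
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube pool2_bwd_cpp(const arma::cube& dy) {
  const uword C = dy.n_rows, To = dy.n_cols, B = dy.n_slices;
  cube dx(C, 2 * To, B);
  for (uword b = 0; b < B; ++b) {
    const mat& db = dy.slice(b);
    mat& xb = dx.slice(b);
    for (uword t = 0; t < To; ++t) {
      const double* d = db.colptr(t);
      double* a = xb.colptr(2 * t);
      double* c = xb.colptr(2 * t + 1);
      for (uword i = 0; i < C; ++i) { a[i] = 0.5 * d[i]; c[i] = 0.5 * d[i]; }
    }
  }
  return dx;
}
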