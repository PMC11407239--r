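/* 3D convolution as shifted BLAS gemm on zero-padded flattened volumes.
 *
 * Volumes are stored flattened (x fastest) with a one-voxel zero pad on
 * every side, stacked as row blocks for batching. A 3x3x3 convolution is
 * then a sum over 27 constant row shifts, each a dense gemm on a
 * contiguous row range: no im2col materialization, all flops in gemm.
 * Row ranges are processed in cache-sized blocks with the 27 offsets inner,
 * so each operand block is read from memory once per layer rather than 27
 * times. Pad rows receive garbage contributions and are re-zeroed by the
 * fused epilogue, which also applies bias and ReLU (forward) or the ReLU
 * mask and bias gradient (backward).
 *
 * Arithmetic is single precision (the conventional choice for network
 * training); all R-facing interfaces stay double.
 */
#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

/* R's BLAS headers only declare the double-precision routines; the linked
 * BLAS provides the single-precision ones. */
extern void F77_NAME(sgemm)(const char *transa, const char *transb,
    const int *m, const int *n, const int *k, const float *alpha,
    const float *a, const int *lda, const float *b, const int *ldb,
    const float *beta, float *c, const int *ldc FCLEN FCLEN);

#define BLOCK 8192

static float *to_float(const double *x, size_t n)
{
    float *f = (float *) R_alloc(n, sizeof(float));
    for (size_t i = 0; i < n; i++) f[i] = (float) x[i];
    return f;
}

/* Y = relu( sum_o X[.+s_o,] %*% W[,,o] + b ), computed on rows lo..hi and
 * zeroed on pad (non-core) rows. X: N x Cin, W: Cin x Cout x K, b: Cout,
 * iscore: logical length N. relu == 0 skips the nonlinearity. */
SEXP C_conv_fwd(SEXP X, SEXP W, SEXP b, SEXP shifts, SEXP lo_, SEXP hi_,
                SEXP iscore, SEXP relu_)
{
    int N = Rf_nrows(X), Cin = Rf_ncols(X);
    SEXP wdim = Rf_getAttrib(W, R_DimSymbol);
    int wCin = INTEGER(wdim)[0], Cout = INTEGER(wdim)[1], K = INTEGER(wdim)[2];
    if (wCin != Cin) Rf_error("weight/input channel mismatch");
    int lo = Rf_asInteger(lo_), hi = Rf_asInteger(hi_);
    int relu = Rf_asInteger(relu_);
    int *core = LOGICAL(iscore);
    double *bias = REAL(b);
    SEXP Y = PROTECT(Rf_allocMatrix(REALSXP, N, Cout));
    double *y = REAL(Y);
    int *s = INTEGER(shifts);
    void *vmax = vmaxget();
    float *xf = to_float(REAL(X), (size_t) N * Cin);
    float *wf = to_float(REAL(W), (size_t) Cin * Cout * K);
    float *yf = (float *) R_alloc((size_t) N * Cout, sizeof(float));
    memset(yf, 0, (size_t) N * Cout * sizeof(float));
    float one = 1.0f;
    for (int r0 = lo - 1; r0 < hi; r0 += BLOCK) {
        int m = hi - r0 < BLOCK ? hi - r0 : BLOCK;
        for (int o = 0; o < K; o++) {
            const float *A = xf + r0 + s[o];
            const float *B = wf + (size_t) o * Cin * Cout;
            float *C = yf + r0;
            F77_CALL(sgemm)("N", "N", &m, &Cout, &Cin, &one,
                            A, &N, B, &Cin, &one, C, &N FCONE FCONE);
        }
    }
    for (int c = 0; c < Cout; c++) {
        const float *colf = yf + (size_t) c * N;
        double *col = y + (size_t) c * N;
        double bc = bias[c];
        if (relu)
            for (int i = 0; i < N; i++) {
                double v = (double) colf[i] + bc;
                col[i] = (core[i] && v > 0) ? v : 0.0;
            }
        else
            for (int i = 0; i < N; i++)
                col[i] = core[i] ? (double) colf[i] + bc : 0.0;
    }
    vmaxset(vmax);
    UNPROTECT(1);
    return Y;
}

/* Backward through one conv(+ReLU) layer.
 * Inputs: layer input Xin (N x Cin), upstream gradient dY (N x Cout), layer
 * output Yout (for the ReLU mask; ignored when relu == 0), weights W.
 * Returns list(dX = N x Cin or NULL, gW = Cin x Cout x K, gb = Cout). */
SEXP C_conv_bwd(SEXP Xin, SEXP dY, SEXP Yout, SEXP W, SEXP shifts,
                SEXP lo_, SEXP hi_, SEXP iscore, SEXP relu_, SEXP want_dx_)
{
    int N = Rf_nrows(Xin), Cin = Rf_ncols(Xin), Cout = Rf_ncols(dY);
    int K = Rf_length(shifts);
    int lo = Rf_asInteger(lo_), hi = Rf_asInteger(hi_);
    int relu = Rf_asInteger(relu_), want_dx = Rf_asInteger(want_dx_);
    int *core = LOGICAL(iscore);
    int *s = INTEGER(shifts);
    float one = 1.0f;
    void *vmax = vmaxget();

    /* masked upstream gradient dZ (float) and bias gradient in one pass */
    SEXP gb = PROTECT(Rf_allocVector(REALSXP, Cout));
    float *dz = (float *) R_alloc((size_t) N * Cout, sizeof(float));
    double *dy = REAL(dY), *yo = relu ? REAL(Yout) : NULL;
    for (int c = 0; c < Cout; c++) {
        double acc = 0.0;
        const double *dyc = dy + (size_t) c * N;
        float *dzc = dz + (size_t) c * N;
        if (relu) {
            const double *yc = yo + (size_t) c * N;
            for (int i = 0; i < N; i++) {
                double v = (core[i] && yc[i] > 0) ? dyc[i] : 0.0;
                dzc[i] = (float) v; acc += v;
            }
        } else {
            for (int i = 0; i < N; i++) {
                double v = core[i] ? dyc[i] : 0.0;
                dzc[i] = (float) v; acc += v;
            }
        }
        REAL(gb)[c] = acc;
    }

    /* weight gradient: dW[,,o] = t(Xin[.+s_o,]) %*% dZ, blocked over rows */
    SEXP gW = PROTECT(Rf_alloc3DArray(REALSXP, Cin, Cout, K));
    float *xif = to_float(REAL(Xin), (size_t) N * Cin);
    float *gwf = (float *) R_alloc((size_t) Cin * Cout * K, sizeof(float));
    memset(gwf, 0, (size_t) Cin * Cout * K * sizeof(float));
    for (int r0 = lo - 1; r0 < hi; r0 += BLOCK) {
        int m = hi - r0 < BLOCK ? hi - r0 : BLOCK;
        for (int o = 0; o < K; o++) {
            const float *A = xif + r0 + s[o];
            const float *B = dz + r0;
            float *C = gwf + (size_t) o * Cin * Cout;
            F77_CALL(sgemm)("T", "N", &Cin, &Cout, &m, &one,
                            A, &N, B, &N, &one, C, &Cin FCONE FCONE);
        }
    }
    for (size_t i = 0; i < (size_t) Cin * Cout * K; i++)
        REAL(gW)[i] = (double) gwf[i];

    /* input gradient: dX[.+s_o,] += dZ %*% t(W[,,o]) */
    SEXP dX;
    if (want_dx) {
        dX = PROTECT(Rf_allocMatrix(REALSXP, N, Cin));
        float *wf = to_float(REAL(W), (size_t) Cin * Cout * K);
        float *dxf = (float *) R_alloc((size_t) N * Cin, sizeof(float));
        memset(dxf, 0, (size_t) N * Cin * sizeof(float));
        for (int r0 = lo - 1; r0 < hi; r0 += BLOCK) {
            int m = hi - r0 < BLOCK ? hi - r0 : BLOCK;
            for (int o = 0; o < K; o++) {
                const float *A = dz + r0;
                const float *B = wf + (size_t) o * Cin * Cout;
                float *C = dxf + r0 + s[o];
                F77_CALL(sgemm)("N", "T", &m, &Cin, &Cout, &one,
                                A, &N, B, &Cin, &one, C, &N FCONE FCONE);
            }
        }
        double *dx = REAL(dX);
        for (int c = 0; c < Cin; c++) {
            const float *colf = dxf + (size_t) c * N;
            double *col = dx + (size_t) c * N;
            for (int i = 0; i < N; i++)
                col[i] = core[i] ? (double) colf[i] : 0.0;
        }
    } else {
        dX = PROTECT(R_NilValue);
    }

    const char *nm[] = {"dX", "gW", "gb", ""};
    SEXP out = PROTECT(Rf_mkNamed(VECSXP, nm));
    SET_VECTOR_ELT(out, 0, dX);
    SET_VECTOR_ELT(out, 1, gW);
    SET_VECTOR_ELT(out, 2, gb);
    vmaxset(vmax);
    UNPROTECT(4);
    return out;
}
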