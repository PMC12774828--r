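// Hot numeric kernels for the encoder training loop: a fused in-place Adam
// update over the list of weight tensors, and single-pass SiLU forward /
// derivative. Everything else in the package is vectorized R on BLAS.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// In-place Adam update. params/grads/m/v must be parallel lists of numeric
// vectors (matrices included); params, m and v are modified in place, so the
// caller must own these buffers exclusively.
// [[Rcpp::export(name = ".adamStepInplace")]]
void adamStepInplace(List params, List grads, List m, List v,
                     double lr, double b1, double b2,
                     double bc1, double bc2, double eps) {
    int k = params.size();
    for (int i = 0; i < k; ++i) {
        NumericVector p = params[i], g = grads[i], mi = m[i], vi = v[i];
        R_xlen_t n = p.size();
        if (g.size() != n || mi.size() != n || vi.size() != n)
            stop("parameter/gradient shape mismatch");
        double *pp = REAL(p), *pg = REAL(g), *pm = REAL(mi), *pv = REAL(vi);
        for (R_xlen_t j = 0; j < n; ++j) {
            double gj = pg[j];
            pm[j] = b1 * pm[j] + (1.0 - b1) * gj;
            pv[j] = b2 * pv[j] + (1.0 - b2) * gj * gj;
            pp[j] -= lr * (pm[j] / bc1) / (std::sqrt(pv[j] / bc2) + eps);
        }
    }
}

// Fused augmentation: allele flip, missingness mask and one-hot encoding in
// one pass over a samples x markers integer matrix. Consumes R's RNG stream
// in exactly the same order as the composed R functions flipMarkers ->
// maskMarkers (full uniform vector for the flip decisions, then one draw per
// flipped heterozygote in index order, then a full vector for the mask), so
// fused and composed paths agree for the same seed.
// [[Rcpp::export(name = ".augmentOneHotCpp")]]
NumericVector augmentOneHotCpp(IntegerMatrix calls, NumericVector pflip,
                               NumericVector pmask) {
    int B = calls.nrow(), D = calls.ncol();
    if (pflip.size() != B || pmask.size() != B)
        stop("one rate per sample required");
    R_xlen_t n = (R_xlen_t)B * D;
    std::vector<int> v(n);
    std::vector<char> flip(n);
    const int *pc = INTEGER(calls);
    GetRNGstate();
    for (R_xlen_t j = 0; j < n; ++j) {
        double u = unif_rand();
        v[j] = pc[j];
        flip[j] = (u < pflip[j % B]) && v[j] != -1;
    }
    for (R_xlen_t j = 0; j < n; ++j) {
        if (!flip[j]) continue;
        if (v[j] == 1)
            v[j] = (unif_rand() < 0.5) ? 2 : 0;
        else
            v[j] = 1;
    }
    NumericVector out((R_xlen_t)B * D * 4);
    double *po = REAL(out);
    for (R_xlen_t j = 0; j < n; ++j) {
        int val = (unif_rand() < pmask[j % B]) ? -1 : v[j];
        int ch = (val == -1) ? 3 : val;
        po[j + n * ch] = 1.0;
    }
    PutRNGstate();
    out.attr("dim") = IntegerVector::create(B, D, 4);
    return out;
}

// Build the kernel-size-3 im2col matrix for a (B, D, C) array laid out in
// R's column-major order: output is (B*D) x (3C), column blocks holding the
// input shifted by marker offsets -1, 0, +1 (zero padded).
// [[Rcpp::export(name = ".im2colCpp")]]
NumericMatrix im2colCpp(NumericVector x, int B, int D, int C) {
    R_xlen_t BD = (R_xlen_t)B * D;
    NumericMatrix out = no_init(BD, 3 * C);
    const double *px = REAL(x);
    double *po = REAL(out);
    for (int blk = 0; blk < 3; ++blk) {
        int off = blk - 1;
        for (int c = 0; c < C; ++c) {
            double *col = po + BD * (blk * C + c);
            // zero-pad the boundary marker, bulk-copy the rest in one go
            if (off == -1) {
                std::fill(col, col + B, 0.0);
                std::copy(px + (R_xlen_t)B * (R_xlen_t)D * c,
                          px + (R_xlen_t)B * ((R_xlen_t)D * c + D - 1),
                          col + B);
            } else if (off == 1) {
                std::copy(px + (R_xlen_t)B * ((R_xlen_t)D * c + 1),
                          px + (R_xlen_t)B * ((R_xlen_t)D * c + D),
                          col);
                std::fill(col + BD - B, col + BD, 0.0);
            } else {
                std::copy(px + (R_xlen_t)B * (R_xlen_t)D * c,
                          px + (R_xlen_t)B * ((R_xlen_t)D * c + D), col);
            }
        }
    }
    return out;
}

// Fold the (B*D) x (3C) gradient of the im2col matrix back onto the input
// array: dX[d] = block0[d+1] + block1[d] + block2[d-1].
// [[Rcpp::export(name = ".col2imCpp")]]
NumericVector col2imCpp(NumericMatrix dXc, int B, int D, int C) {
    NumericVector out((R_xlen_t)B * D * C);
    const double *pd = REAL(dXc);
    double *po = REAL(out);
    R_xlen_t BD = (R_xlen_t)B * D;
    for (int blk = 0; blk < 3; ++blk) {
        int off = blk - 1;
        for (int c = 0; c < C; ++c) {
            const double *col = pd + BD * (blk * C + c);
            for (int d = 0; d < D; ++d) {
                int dt = d + off;               // position that fed this row
                if (dt < 0 || dt >= D) continue;
                double *dst = po + (R_xlen_t)B * (dt + (R_xlen_t)D * c);
                const double *src = col + (R_xlen_t)B * d;
                for (int b = 0; b < B; ++b) dst[b] += src[b];
            }
        }
    }
    out.attr("dim") = IntegerVector::create(B, D, C);
    return out;
}

// [[Rcpp::export(name = ".siluCpp")]]
NumericVector siluCpp(NumericVector x) {
    R_xlen_t n = x.size();
    NumericVector out = no_init(n);
    const double *px = REAL(x);
    double *po = REAL(out);
    for (R_xlen_t j = 0; j < n; ++j) {
        double s = 1.0 / (1.0 + std::exp(-px[j]));
        po[j] = px[j] * s;
    }
    out.attr("dim") = x.attr("dim");
    return out;
}

// d/dx [x * sigmoid(x)] = sigmoid(x) * (1 + x * (1 - sigmoid(x)))
// [[Rcpp::export(name = ".siluGradCpp")]]
NumericVector siluGradCpp(NumericVector x) {
    R_xlen_t n = x.size();
    NumericVector out = no_init(n);
    const double *px = REAL(x);
    double *po = REAL(out);
    for (R_xlen_t j = 0; j < n; ++j) {
        double s = 1.0 / (1.0 + std::exp(-px[j]));
        po[j] = s * (1.0 + px[j] * (1.0 - s));
    }
    out.attr("dim") = x.attr("dim");
    return out;
}
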