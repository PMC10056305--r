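#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* Fused in-place Adam update: one pass over the tensor instead of a chain
 * of vectorized temporaries. Mutates w, m and v by reference; the caller
 * owns these buffers exclusively (optimizer state and model weights are
 * created once and never aliased).
 *
 * m <- beta1 * m + (1 - beta1) * g
 * v <- beta2 * v + (1 - beta2) * g^2
 * w <- w - a * m / (sqrt(v) + b)
 *
 * with a = lr * sqrt(1 - beta2^t) / (1 - beta1^t) and
 * b = eps * sqrt(1 - beta2^t), the algebraic refactoring of the usual
 * bias-corrected step. */
SEXP C_adam_fused(SEXP w, SEXP m, SEXP v, SEXP g,
                  SEXP beta1_, SEXP beta2_, SEXP a_, SEXP b_)
{
    R_xlen_t n = XLENGTH(w);
    if (XLENGTH(m) != n || XLENGTH(v) != n || XLENGTH(g) != n)
        error("adam update: tensor length mismatch");
    double *pw = REAL(w), *pm = REAL(m), *pv = REAL(v), *pg = REAL(g);
    const double b1 = asReal(beta1_), b2 = asReal(beta2_);
    const double a = asReal(a_), b = asReal(b_);
    for (R_xlen_t i = 0; i < n; i++) {
        const double gi = pg[i];
        pm[i] = b1 * pm[i] + (1.0 - b1) * gi;
        pv[i] = b2 * pv[i] + (1.0 - b2) * gi * gi;
        pw[i] -= a * pm[i] / (sqrt(pv[i]) + b);
    }
    return R_NilValue;
}
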