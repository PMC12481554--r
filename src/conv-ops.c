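/* Hot inner loops of the im2col convolution engine: the patch gather and
 * the gradient scatter. Index matrices are 1-based with 0 marking a
 * zero-padded position. */

#include <R.h>
#include <Rinternals.h>

/* Xcol[r, j] = xv[idx[r, j]] with idx == 0 -> 0.0 */
SEXP C_im2col_gather(SEXP xv, SEXP idx)
{
    const double *x = REAL(xv);
    const int *id = INTEGER(idx);
    const R_xlen_t n = XLENGTH(idx);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    double *o = REAL(out);
    for (R_xlen_t k = 0; k < n; k++) {
        const int j = id[k];
        o[k] = (j > 0) ? x[j - 1] : 0.0;
    }
    SEXP dim = PROTECT(allocVector(INTSXP, 2));
    INTEGER(dim)[0] = INTEGER(getAttrib(idx, R_DimSymbol))[0];
    INTEGER(dim)[1] = INTEGER(getAttrib(idx, R_DimSymbol))[1];
    setAttrib(out, R_DimSymbol, dim);
    UNPROTECT(2);
    return out;
}

/* acc[idx[k] - 1] += dXcol[k] for idx[k] > 0; acc has length len */
SEXP C_col2im_scatter(SEXP dXcol, SEXP idx, SEXP len)
{
    const double *d = REAL(dXcol);
    const int *id = INTEGER(idx);
    const R_xlen_t n = XLENGTH(idx);
    const R_xlen_t m = (R_xlen_t) REAL(len)[0];
    SEXP out = PROTECT(allocVector(REALSXP, m));
    double *o = REAL(out);
    memset(o, 0, m * sizeof(double));
    for (R_xlen_t k = 0; k < n; k++) {
        const int j = id[k];
        if (j > 0) o[j - 1] += d[k];
    }
    UNPROTECT(1);
    return out;
}
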