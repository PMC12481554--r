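#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_im2col_gather(SEXP xv, SEXP idx);
SEXP C_col2im_scatter(SEXP dXcol, SEXP idx, SEXP len);

static const R_CallMethodDef callMethods[] = {
    {"C_im2col_gather", (DL_FUNC) &C_im2col_gather, 2},
    {"C_col2im_scatter", (DL_FUNC) &C_col2im_scatter, 3},
    {NULL, NULL, 0}
};

void R_init_stripgan(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
    R_forceSymbols(info, TRUE);
}
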