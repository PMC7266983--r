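#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_rif_sim(SEXP stops_, SEXP reset_, SEXP y0_, SEXP theta_, SEXP dose_t_,
               SEXP dose_mass_, SEXP dose_ktr_, SEXP km_mult_, SEXP ka_mult_,
               SEXP tol_);

static const R_CallMethodDef CallEntries[] = {
    {"C_rif_sim", (DL_FUNC) &C_rif_sim, 10},
    {NULL, NULL, 0}
};

void R_init_rifmipd(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
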