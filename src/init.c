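#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_h5_write(SEXP path, SEXP names, SEXP objects);
SEXP C_h5_read(SEXP path, SEXP name);
SEXP C_h5_exists(SEXP path, SEXP name);

static const R_CallMethodDef CallEntries[] = {
    {"C_h5_write",  (DL_FUNC) &C_h5_write,  3},
    {"C_h5_read",   (DL_FUNC) &C_h5_read,   2},
    {"C_h5_exists", (DL_FUNC) &C_h5_exists, 2},
    {NULL, NULL, 0}
};

void R_init_coilsketch(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
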