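#include <R.h>
#include <R_ext/Rdynload.h>

void cdt_initmod(void (*odeparms)(int *, double *));
void cdt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"cdt_initmod", (DL_FUNC) &cdt_initmod, 1},
    {"cdt_derivs",  (DL_FUNC) &cdt_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_tyrcycle(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
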