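#include <R.h>
#include <R_ext/Rdynload.h>

void camnet_init(void (* odeparms)(int *, double *));
void camnet_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"camnet_init",   (DL_FUNC) &camnet_init,   1},
    {"camnet_derivs", (DL_FUNC) &camnet_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_camnet(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
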