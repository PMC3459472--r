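#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void sanpace_init_boyett(void (*odeparms)(int *, double *));
void sanpace_deriv_boyett(int *, double *, double *, double *, double *, int *);
void sanpace_eval_boyett(double *, double *, double *, double *);
void sanpace_init_kurata(void (*odeparms)(int *, double *));
void sanpace_deriv_kurata(int *, double *, double *, double *, double *, int *);
void sanpace_eval_kurata(double *, double *, double *, double *);

static const R_CMethodDef CEntries[] = {
    {"sanpace_init_boyett",  (DL_FUNC) &sanpace_init_boyett,  1},
    {"sanpace_deriv_boyett", (DL_FUNC) &sanpace_deriv_boyett, 6},
    {"sanpace_eval_boyett",  (DL_FUNC) &sanpace_eval_boyett,  4},
    {"sanpace_init_kurata",  (DL_FUNC) &sanpace_init_kurata,  1},
    {"sanpace_deriv_kurata", (DL_FUNC) &sanpace_deriv_kurata, 6},
    {"sanpace_eval_kurata",  (DL_FUNC) &sanpace_eval_kurata,  4},
    {NULL, NULL, 0}
};

void R_init_sanpace(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
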