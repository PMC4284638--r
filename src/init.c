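#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void barswitch_full_init(void (*odeparms)(int *, double *));
void barswitch_full_rhs(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip);
SEXP C_simplified_screen(SEXP s_masks, SEXP s_params, SEXP s_doses,
                         SEXP s_b0frac, SEXP s_tol);

static const R_CallMethodDef callMethods[] = {
    {"C_simplified_screen", (DL_FUNC) &C_simplified_screen, 5},
    {NULL, NULL, 0}
};

void R_init_barswitch(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE); /* deSolve looks up the RHS by name */
}
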