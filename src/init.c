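#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* .Call wrappers generated in RcppExports.cpp */
extern SEXP _commsel_chem_step_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                   SEXP, SEXP, SEXP, SEXP);
extern SEXP _commsel_sample_delta_cpp(SEXP, SEXP, SEXP);
extern SEXP _commsel_mutate_cell_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                     SEXP);
extern SEXP _commsel_mature_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                SEXP, SEXP, SEXP, SEXP);

/* deSolve-facing routines in hm_ode.c */
extern void hm_initmod(void (*odeparms)(int *, double *));
extern void hm_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"_commsel_chem_step_cpp", (DL_FUNC)&_commsel_chem_step_cpp, 11},
    {"_commsel_sample_delta_cpp", (DL_FUNC)&_commsel_sample_delta_cpp, 3},
    {"_commsel_mutate_cell_cpp", (DL_FUNC)&_commsel_mutate_cell_cpp, 7},
    {"_commsel_mature_cpp", (DL_FUNC)&_commsel_mature_cpp, 18},
    {NULL, NULL, 0}};

static const R_CMethodDef CEntries[] = {
    {"hm_initmod", (DL_FUNC)&hm_initmod, 1},
    {"hm_derivs", (DL_FUNC)&hm_derivs, 6},
    {NULL, NULL, 0}};

void R_init_commsel(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
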