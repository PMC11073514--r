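// Native routine registration: the Rcpp .Call entries plus the deSolve
// compiled-model routines (cdx_initmod / cdx_derivs) looked up by name.
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP _cardiox_cdx_set_parms_cpp(SEXP);
extern SEXP _cardiox_cdx_cpp_param_names(void);
extern SEXP _cardiox_cdx_cpp_mod_names(void);
extern SEXP _cardiox_cdx_rhs_point_cpp(SEXP, SEXP, SEXP, SEXP);
extern SEXP _cardiox_cdx_schedule_eval_cpp(SEXP, SEXP, SEXP, SEXP);

void cdx_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
                int *ip);

static const R_CallMethodDef CallEntries[] = {
  {"_cardiox_cdx_set_parms_cpp", (DL_FUNC) &_cardiox_cdx_set_parms_cpp, 1},
  {"_cardiox_cdx_cpp_param_names", (DL_FUNC) &_cardiox_cdx_cpp_param_names, 0},
  {"_cardiox_cdx_cpp_mod_names", (DL_FUNC) &_cardiox_cdx_cpp_mod_names, 0},
  {"_cardiox_cdx_rhs_point_cpp", (DL_FUNC) &_cardiox_cdx_rhs_point_cpp, 4},
  {"_cardiox_cdx_schedule_eval_cpp", (DL_FUNC) &_cardiox_cdx_schedule_eval_cpp, 4},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"cdx_derivs", (DL_FUNC) &cdx_derivs, 6},
  {NULL, NULL, 0}
};

void R_init_cardiox(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
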