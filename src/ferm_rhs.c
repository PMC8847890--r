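/* Compiled right-hand side of the cocoa fermentation ODE variants,
 * in the deSolve compiled-model calling convention.
 *
 * parms layout: 43 kinetic parameters in the canonical order of
 * ferm_parameter_table(), followed by 5 mechanism flags (0/1).
 * States: Glc, Fru, EtOH, LA, Ac, Y, LAB, AAB.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 48

static double parms[N_PARMS];

void cocoaferm_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* Monod growth, zero for non-positive substrate or biomass. Transient
 * negative excursions of the integrator are clamped to zero at rate
 * evaluation only, so the vector field stays defined near the boundary. */
static double monod(double mu, double K, double S, double X)
{
    if (S <= 0.0 || X <= 0.0) return 0.0;
    return mu * S / (S + K) * X;
}

static double contois(double mu, double K, double S, double X)
{
    if (S <= 0.0 || X <= 0.0) return 0.0;
    return mu * S / (S + K * X) * X;
}

static double pos(double x) { return x > 0.0 ? x : 0.0; }

void cocoaferm_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const double *p = parms;
    double Glc = pos(y[0]), Fru = pos(y[1]), EtOH = pos(y[2]);
    double LA = pos(y[3]), Ac = pos(y[4]);
    double Y = pos(y[5]), LAB = pos(y[6]), AAB = pos(y[7]);
    double m1 = p[43], m2 = p[44], m3 = p[45], m4 = p[46], m5 = p[47];

    double v1  = monod(p[0], p[8],  Glc,  Y);
    double v2  = monod(p[1], p[9],  Fru,  Y);
    double v3  = monod(p[3], p[11], Glc,  LAB);
    double v4  = monod(p[5], p[13], EtOH, AAB);
    double v5  = contois(p[6], p[14], LA, AAB);
    double v6  = p[16] * Y * EtOH;
    double v7  = p[17] * LAB * LA;
    double v8  = p[18] * AAB * Ac * Ac;
    double v9  = m2 * monod(p[4], p[12], Fru, LAB);
    double v10 = m4 * monod(p[2], p[10], LA,  Y);
    double v11 = m5 * monod(p[7], p[15], Ac,  AAB);
    double d1  = m1 * p[40] * EtOH;
    double d2  = m1 * p[41] * LA;
    double d3  = m1 * p[42] * Ac;

    ydot[0] = -p[19] * v1 - p[20] * v3;                       /* Glc  */
    ydot[1] = -p[21] * v2 - m2 * p[22] * v9;                  /* Fru  */
    ydot[2] = p[23] * v1 + p[24] * v2 - p[28] * v4            /* EtOH */
              + m2 * (p[26] * v3 + p[27] * v9)
              + m4 * p[25] * v10 - d1;
    ydot[3] = p[29] * v3 - p[31] * v5                         /* LA   */
              + m2 * p[30] * v9 - m4 * p[32] * v10 - d2;
    ydot[4] = p[33] * v3 + p[35] * v4 + p[36] * v5            /* Ac   */
              + m2 * p[34] * v9
              + m3 * (p[37] * v1 + p[38] * v2)
              - m5 * p[39] * v11 - d3;
    ydot[5] = v1 + v2 - v6 + m4 * v10;                        /* Y    */
    ydot[6] = v3 - v7 + m2 * v9;                              /* LAB  */
    ydot[7] = v4 + v5 - v8 + m5 * v11;                        /* AAB  */
}

static const R_CMethodDef CEntries[] = {
    {"cocoaferm_initmod", (DL_FUNC) &cocoaferm_initmod, 1},
    {"cocoaferm_derivs",  (DL_FUNC) &cocoaferm_derivs,  6},
    {NULL, NULL, 0}
};

extern SEXP ferm_simulate_c(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP ferm_resid_c(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP ferm_mcmc_c(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                        SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"ferm_simulate_c", (DL_FUNC) &ferm_simulate_c, 6},
    {"ferm_resid_c",    (DL_FUNC) &ferm_resid_c,    9},
    {"ferm_mcmc_c",     (DL_FUNC) &ferm_mcmc_c,    14},
    {NULL, NULL, 0}
};

void R_init_cocoaferm(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
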