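/* Compiled right-hand side of the five-species siRNA delivery model,
 * in the standard deSolve compiled-model form. The Heaviside escape
 * switch is handled on the R side by integrating in segments; within a
 * segment the effective escape rate (parms[1]) is constant.
 *
 * parms layout: k1, k2_eff, k3, k4, k5, k6, k7, k8, k9, E, R0, conserved
 * state layout: N, S, SR, SRM, M  (molecules per cell)
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[12];

void lnp_initmod(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void lnp_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double k1 = parms[0], k2e = parms[1], k3 = parms[2],
                 k4 = parms[3], k5 = parms[4], k6 = parms[5],
                 k7 = parms[6], k8 = parms[7], k9 = parms[8],
                 E = parms[9], R0 = parms[10];
    const int conserved = (int) parms[11];
    const double N = y[0], S = y[1], SR = y[2], SRM = y[3], M = y[4];

    double R = conserved ? R0 - SR - SRM : R0;
    if (R < 0.0) R = 0.0;

    ydot[0] = k1 * E - (k2e + k3) * N;
    ydot[1] = k2e * N - k5 * S - k4 * S * R;
    ydot[2] = k4 * S * R - k6 * M * SR;
    ydot[3] = k6 * M * SR - k7 * SRM;
    ydot[4] = k8 - k9 * M - k7 * SRM;
}

static const R_CMethodDef CEntries[] = {
    {"lnp_initmod", (DL_FUNC) &lnp_initmod, 1},
    {"lnp_derivs",  (DL_FUNC) &lnp_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_lnpkinetics(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
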