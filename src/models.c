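/* Compiled right-hand sides for deSolve.
 *
 * Chemostat state y = (X1, X2, S0, S1, S2), 16 parameters:
 *   phi, mu1, mu2, s0in, s1in, s2in, k10, k12, k20, k21,
 *   nu01, nu02, nu11, nu12, nu21, nu22
 * eLV state y = (X1, X2), 11 parameters:
 *   d, r1, r2, a1, a2, b11, b12, b21, b22, c1, c2
 *
 * Negative excursions from round-off are treated as zero inside the growth
 * terms so Monod fractions stay in [0, 1).
 */
#include <R.h>

static double cparms[16];
static double lparms[11];

void mutucomp_chemo_init(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, cparms);
}

void mutucomp_chemo_derivs(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double phi = cparms[0], mu1 = cparms[1], mu2 = cparms[2];
    double s0in = cparms[3], s1in = cparms[4], s2in = cparms[5];
    double k10 = cparms[6], k12 = cparms[7], k20 = cparms[8], k21 = cparms[9];
    double nu01 = cparms[10], nu02 = cparms[11], nu11 = cparms[12];
    double nu12 = cparms[13], nu21 = cparms[14], nu22 = cparms[15];

    double x1 = y[0], x2 = y[1];
    double s0 = y[2] > 0 ? y[2] : 0;
    double s1 = y[3] > 0 ? y[3] : 0;
    double s2 = y[4] > 0 ? y[4] : 0;

    double f1 = mu1 * (s0 / (k10 + s0)) * (s2 / (k12 + s2));
    double f2 = mu2 * (s0 / (k20 + s0)) * (s1 / (k21 + s1));

    ydot[0] = (f1 - phi) * x1;
    ydot[1] = (f2 - phi) * x2;
    ydot[2] = phi * (s0in - y[2]) + nu01 * f1 * x1 + nu02 * f2 * x2;
    ydot[3] = phi * (s1in - y[3]) + nu11 * f1 * x1 + nu12 * f2 * x2;
    ydot[4] = phi * (s2in - y[4]) + nu21 * f1 * x1 + nu22 * f2 * x2;
}

void mutucomp_elv_init(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, lparms);
}

void mutucomp_elv_derivs(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    double d = lparms[0], r1 = lparms[1], r2 = lparms[2];
    double a1 = lparms[3], a2 = lparms[4];
    double b11 = lparms[5], b12 = lparms[6], b21 = lparms[7], b22 = lparms[8];
    double c1 = lparms[9], c2 = lparms[10];

    double x1 = y[0], x2 = y[1];

    ydot[0] = (r1 * (a1 - b11 * x1 + b12 * x2 - c1 * x2 * x2) - d) * x1;
    ydot[1] = (r2 * (a2 - b22 * x2 + b21 * x1 - c2 * x1 * x1) - d) * x2;
}
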