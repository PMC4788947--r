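/* Reduced deterministic I1-FFL circuit model for deSolve's compiled-model
 * interface.  Two variants are provided:
 *
 *   derivs      : 9 circuit states + 2 quadrature states accumulating the
 *                 total variation of the output protein C (x8) and of the
 *                 repressor B (x6).
 *   derivs_load : same with a downstream binding load appended (free load
 *                 x10, bound complex x11), 13 states in total.
 *
 * Units are nM and minutes throughout.  The parameter vector layout must
 * match .i1ffl_parms() on the R side exactly.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 32

static double parms[N_PARMS];

#define kmA_CgA  parms[0]
#define dmA      parms[1]
#define kpA      parms[2]
#define dA       parms[3]
#define k2       parms[4]
#define k_2      parms[5]
#define kd       parms[6]
#define dI       parms[7]
#define k3       parms[8]
#define k_3      parms[9]
#define dAI      parms[10]
#define dAI2     parms[11]
#define kmB_CgB  parms[12]
#define gamma1   parms[13]
#define dmB      parms[14]
#define kpB      parms[15]
#define dB       parms[16]
#define kmC_CgC  parms[17]
#define gamma2   parms[18]
#define gamma3   parms[19]
#define gamma4   parms[20]
#define gamma5   parms[21]
#define beta1    parms[22]
#define beta2    parms[23]
#define dmC      parms[24]
#define kpC      parms[25]
#define dC       parms[26]
#define Kcells   parms[27]
#define dIe      parms[28]
#define K1       parms[29]
#define K2       parms[30]
#define hold_x9  parms[31]

void initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* Monomer A.I from the quasi-steady-state quadratic
 * 2 k3 M^2 + (dAI + k_2) M - (k2 x2 x3 + 2 k_3 x4) = 0, non-negative root. */
static double monomer(double x2, double x3, double x4)
{
    double s = k2 * x2 * x3 + 2.0 * k_3 * x4;
    double a = dAI + k_2;
    if (s < 0.0) s = 0.0;           /* guard transient negative states */
    return (-a + sqrt(a * a + 8.0 * k3 * s)) / (4.0 * k3);
}

/* Core 9-state derivatives; dx8_extra carries load-binding flux on x8. */
static void core(double *y, double *dy, double dx8_extra)
{
    double x1 = y[0], x2 = y[1], x3 = y[2], x4 = y[3], x5 = y[4];
    double x6 = y[5], x7 = y[6], x8 = y[7], x9 = y[8];
    double M = monomer(x2, x3, x4);
    double hillB = x4 / (gamma1 + x4);
    double numC = x4 + beta1 * gamma4 * x6 + beta2 * gamma5 * x4 * x6;
    double denC = gamma2 + gamma3 * x4 + gamma4 * x6 + gamma5 * x4 * x6;

    dy[0] = kmA_CgA - dmA * x1;
    dy[1] = kpA * x1 - dA * x2 - k2 * x2 * x3 + k_2 * M;
    dy[2] = -k2 * x2 * x3 + k_2 * M + kd * (x9 - x3) - dI * x3;
    dy[3] = k3 * M * M - k_3 * x4 - dAI2 * x4;
    dy[4] = kmB_CgB * hillB - dmB * x5;
    dy[5] = kpB * x5 - dB * x6;
    dy[6] = kmC_CgC * numC / denC - dmC * x7;
    dy[7] = kpC * x7 - dC * x8 + dx8_extra;
    dy[8] = (hold_x9 > 0.5) ? 0.0 : Kcells * kd * (x3 - x9) - dIe * x9;
}

void derivs(int *neq, double *t, double *y, double *ydot,
            double *yout, int *ip)
{
    core(y, ydot, 0.0);
    ydot[9]  = fabs(ydot[7]);   /* d/dt TV(x8) */
    ydot[10] = fabs(ydot[5]);   /* d/dt TV(x6) */
}

void derivs_load(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double x8 = y[7], x10 = y[9], x11 = y[10];
    double bind = -K1 * x8 * x10 + K2 * x11;
    core(y, ydot, bind);
    ydot[9]  = bind;            /* dx10 */
    ydot[10] = -bind;           /* dx11 */
    ydot[11] = fabs(ydot[7]);
    ydot[12] = fabs(ydot[5]);
}
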