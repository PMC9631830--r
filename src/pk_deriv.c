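/* Right-hand side of the three-compartment piperacillin model for deSolve.
 *
 * States (amounts, mg):
 *   y[0] = X1 unbound central, y[1] = X2 interstitial fluid, y[2] = X3 peripheral
 * Parameters (via initfunc):
 *   p[0] ke_base  baseline elimination rate constant (1/h)
 *   p[1] kcp, p[2] kpc   central <-> peripheral transfer (1/h)
 *   p[3] kisf, p[4] kub  central -> ISF and ISF -> central transfer (1/h)
 *   p[5] rate     infusion rate into the central compartment (mg/h),
 *                 constant within one schedule segment
 *   p[6] A, p[7] P, p[8] phi  sinusoidal intra-day modulation of Ke:
 *                 ke(t) = ke_base * (1 + A * sin(2*pi*t/P + phi))
 *
 * Elimination acts on the central compartment only.
 */
#include <R.h>
#include <math.h>

static double parms[9];
#define ke_base parms[0]
#define kcp     parms[1]
#define kpc     parms[2]
#define kisf    parms[3]
#define kub     parms[4]
#define rate_iv parms[5]
#define amp     parms[6]
#define period  parms[7]
#define phase   parms[8]

void pk_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void pk_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double ke = ke_base;
    if (amp != 0.0)
        ke *= 1.0 + amp * sin(2.0 * M_PI * (*t) / period + phase);
    ydot[0] = rate_iv + kpc * y[2] + kub * y[1] - (ke + kcp + kisf) * y[0];
    ydot[1] = kisf * y[0] - kub * y[1];
    ydot[2] = kcp * y[0] - kpc * y[2];
}
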