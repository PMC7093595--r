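/* Eight-state 6MP -> 6-TGN -> neutrophil model for deSolve (compiled RHS).
 *
 * States (order fixed, see R/pkpd_core.R):
 *   y[0] x_6mpgut  mg      6MP in the GI tract
 *   y[1] x_6mp     mg      6MP in the central compartment
 *   y[2] x_6tgn    mg/L    active metabolite 6-TGN
 *   y[3] x_pr      G/L     proliferating cells
 *   y[4] x_tr1     G/L     transit 1
 *   y[5] x_tr2     G/L     transit 2
 *   y[6] x_tr3     G/L     transit 3
 *   y[7] x_ma      G/L     circulating neutrophils (ANC)
 *
 * Oral doses are impulses added to y[0] by the event mechanism, never part
 * of this continuous RHS.  parms[10] >= 0 clamps x_6tgn at that value
 * (used for drugged-equilibrium analyses); < 0 means dynamic.
 */
#include <R.h>
#include <math.h>

static double parms[11];
#define K_A    parms[0]
#define K20    parms[1]
#define FM3    parms[2]
#define K_ME   parms[3]
#define CL     parms[4]   /* clearance_6tgn(BSA), 1/day as applied */
#define K_TR   parms[5]
#define GAMMA  parms[6]
#define SLOPE  parms[7]
#define BASE   parms[8]
#define K_MA   parms[9]
#define CLAMP  parms[10]

void mtanc_initparms(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

void mtanc_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double gut = y[0], cen = y[1];
    double tgn = (CLAMP >= 0.0) ? CLAMP : y[2];
    double xpr = y[3], xtr1 = y[4], xtr2 = y[5], xtr3 = y[6], xma = y[7];
    int i;

    /* feedback term (Base/x_ma)^gamma undefined for x_ma <= 0: poison the
     * step so the solver rejects it rather than clamping the state */
    if (xma <= 0.0) {
        for (i = 0; i < 8; i++) ydot[i] = R_NaN;
        return;
    }

    {
        double edrug = SLOPE * tgn;
        double fb = pow(BASE / xma, GAMMA);

        ydot[0] = -K_A * gut;
        ydot[1] =  K_A * gut - K20 * cen;
        ydot[2] = (CLAMP >= 0.0) ? 0.0 : (FM3 * K_ME * cen - CL * tgn);
        ydot[3] = K_TR * xpr * ((1.0 - edrug) * fb - 1.0);
        ydot[4] = K_TR * (xpr - xtr1);
        ydot[5] = K_TR * (xtr1 - xtr2);
        ydot[6] = K_TR * (xtr2 - xtr3);
        ydot[7] = K_TR * xtr3 - K_MA * xma;
    }
}
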