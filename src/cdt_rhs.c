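/* Right-hand side of the detyrosination/tyrosination cycle ODE, for deSolve.
 *
 * State order:     TubTyr, TubDetyr, MTDetyr, MTTyr, TTL, TCP
 * Parameter order: kp1, kp2, km1, mc1, km2, mc2, k1, Vm2, Km2
 *
 * TTL and TCP are inert species (zero derivative); TCP enters the
 * detyrosination flux, TTL appears in no rate law.  Concentrations are
 * clipped at 0 before flux evaluation to guard against integrator
 * overshoot; the Michaelis denominators mc + MT and Km2 + TubDetyr are
 * then strictly positive for positive constants.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[9];
#define kp1 parms[0]
#define kp2 parms[1]
#define km1 parms[2]
#define mc1 parms[3]
#define km2 parms[4]
#define mc2 parms[5]
#define k1  parms[6]
#define Vm2 parms[7]
#define Km2 parms[8]

void cdt_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void cdt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double TubTyr   = y[0] > 0 ? y[0] : 0;
    double TubDetyr = y[1] > 0 ? y[1] : 0;
    double MTDetyr  = y[2] > 0 ? y[2] : 0;
    double MTTyr    = y[3] > 0 ? y[3] : 0;
    double TCP      = y[5] > 0 ? y[5] : 0;

    double depol_detyr = km1 * MTDetyr / (mc1 + MTDetyr);
    double depol_tyr   = km2 * MTTyr / (mc2 + MTTyr);
    double detyr_flux  = k1 * MTTyr * TCP;
    double tyr_flux    = Vm2 * TubDetyr / (Km2 + TubDetyr);

    ydot[0] = depol_tyr - kp2 * TubTyr + tyr_flux;            /* TubTyr   */
    ydot[1] = depol_detyr - kp1 * TubDetyr - tyr_flux;        /* TubDetyr */
    ydot[2] = kp1 * TubDetyr - depol_detyr + detyr_flux;      /* MTDetyr  */
    ydot[3] = kp2 * TubTyr - depol_tyr - detyr_flux;          /* MTTyr    */
    ydot[4] = 0.0;                                            /* TTL      */
    ydot[5] = 0.0;                                            /* TCP      */
}
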