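/* MEND-with-dormancy right-hand side for deSolve's compiled-model interface.
 *
 * All rate parameters arrive already scaled to the run temperature (the
 * Arrhenius factors and the temperature-adjusted carbon use efficiency are
 * applied on the R side, where they are unit-tested), so this file is pure
 * mass balance.  State order (mg C cm^-3):
 *   y[0] P1   oxidative-degradable POC
 *   y[1] P2   hydrolytic-degradable POC
 *   y[2] M    mineral-associated OC
 *   y[3] D    dissolved OC
 *   y[4] Q    adsorbed DOC
 *   y[5] BA   active microbial biomass
 *   y[6] BD   dormant microbial biomass
 *   y[7] EP1, y[8] EP2, y[9] EM  enzyme pools
 *   y[10] CO2 cumulative respired C
 */
#include <R.h>

static double parms[24];
#define VP1   parms[0]
#define KP1   parms[1]
#define VP2   parms[2]
#define KP2   parms[3]
#define VM    parms[4]
#define KM    parms[5]
#define KADS  parms[6]
#define KDES  parms[7]
#define QMAX  parms[8]
#define FRD   parms[9]
#define GD    parms[10]
#define RM    parms[11]
#define PEP1  parms[12]
#define PEP2  parms[13]
#define PEM   parms[14]
#define RE    parms[15]
#define BETA  parms[16]
#define VG    parms[17]
#define VMT   parms[18]
#define KD    parms[19]
#define YG    parms[20]
#define IP1   parms[21]
#define IP2   parms[22]
#define ID    parms[23]

void mend_init(void (*odeparms)(int *, double *))
{
    int n = 24;
    odeparms(&n, parms);
}

void mend_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    /* clamp tiny solver under-shoots so every outgoing flux vanishes
       smoothly as its source pool reaches zero */
    double P1  = y[0] > 0 ? y[0] : 0;
    double P2  = y[1] > 0 ? y[1] : 0;
    double M   = y[2] > 0 ? y[2] : 0;
    double D   = y[3] > 0 ? y[3] : 0;
    double Q   = y[4] > 0 ? y[4] : 0;
    double BA  = y[5] > 0 ? y[5] : 0;
    double BD  = y[6] > 0 ? y[6] : 0;
    double EP1 = y[7] > 0 ? y[7] : 0;
    double EP2 = y[8] > 0 ? y[8] : 0;
    double EM  = y[9] > 0 ? y[9] : 0;

    double S  = D / (KD + D);                      /* substrate saturation */
    double F1 = (VG + VMT) * S * BA / YG;          /* DOC uptake           */
    double F2 = VP1 * EP1 * P1 / (KP1 + P1);       /* P1 decomposition     */
    double F3 = VP2 * EP2 * P2 / (KP2 + P2);       /* P2 decomposition     */
    double F4 = VM * EM * M / (KM + M);            /* M decomposition      */
    double qfrac = Q / QMAX;
    double F5 = KADS * D * (1 - qfrac);            /* DOC adsorption       */
    double F6 = KDES * qfrac;                      /* DOC desorption       */
    double F7 = (1 - S) * VMT * BA;                /* dormancy A -> D      */
    double F8 = S * VMT * BD;                      /* reactivation D -> A  */

    double maint_a = VMT * S * BA;
    double maint_d = BETA * VMT * BD;
    double growth_resp = (1 - YG) * F1;
    double growth = YG * F1 - maint_a;             /* = VG * S * BA        */
    double mort = RM * BA;
    double eprod = (PEP1 + PEP2 + PEM) * BA;
    double eturn = RE * (EP1 + EP2 + EM);

    ydot[0] = IP1 - F2;
    ydot[1] = IP2 + (1 - GD) * mort - F3;
    ydot[2] = (1 - FRD) * (F2 + F3) - F4;
    ydot[3] = ID + FRD * (F2 + F3) + F4 + GD * mort + eturn - F1 - F5 + F6;
    ydot[4] = F5 - F6;
    ydot[5] = growth - mort - eprod - F7 + F8;
    ydot[6] = F7 - F8 - maint_d;
    ydot[7] = PEP1 * BA - RE * EP1;
    ydot[8] = PEP2 * BA - RE * EP2;
    ydot[9] = PEM * BA - RE * EM;
    ydot[10] = growth_resp + maint_a + maint_d;
}
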