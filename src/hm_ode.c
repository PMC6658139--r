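/* Coupled continuous-biomass dynamics of the Helper-Manufacturer community,
 * states y = (H, M, R, B, P), for use through deSolve (dllname = "commsel",
 * initfunc = "hm_initmod", func = "hm_derivs").
 *
 * Parameter vector (13):
 *  gHmax, gMmax, affHR, affMR, affMB, cRM, cRH, cBM, deltaH, deltaM,
 *  fP, B0inv (1/B0, 0 = no Byproduct inhibition of H),
 *  excessB (> 0.5 = Byproduct saturating; M reduces to Monod growth on R)
 */
#include <R.h>
#include <math.h>

static double parms[13];

void hm_initmod(void (*odeparms)(int *, double *)) {
  int n = 13;
  odeparms(&n, parms);
}

void hm_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
               int *ip) {
  double H = y[0], M = y[1];
  double R = y[2] > 0 ? y[2] : 0;
  double B = y[3] > 0 ? y[3] : 0;
  double gHmax = parms[0], gMmax = parms[1];
  double affHR = parms[2], affMR = parms[3], affMB = parms[4];
  double cRM = parms[5], cRH = parms[6], cBM = parms[7];
  double dH = parms[8], dM = parms[9], fP = parms[10];
  double B0inv = parms[11], excessB = parms[12];
  double x, gH, gM, RM, BM;

  x = R * affHR;
  gH = (x > 0) ? gHmax * x / (x + 1) : 0;
  if (B0inv > 0) gH *= exp(-B * B0inv);

  RM = R * affMR;
  BM = B * affMB;
  if (excessB > 0.5)
    gM = (RM > 0) ? gMmax * RM / (RM + 1) : 0;
  else
    gM = (RM > 0 && BM > 0)
             ? gMmax * RM * BM / (RM + BM) * (1 / (RM + 1) + 1 / (BM + 1))
             : 0;

  ydot[0] = gH * H - dH * H;
  ydot[1] = (1 - fP) * gM * M - dM * M;
  ydot[2] = -cRM * gM * M - cRH * gH * H;
  ydot[3] = (excessB > 0.5) ? 0 : gH * H - cBM * gM * M;
  ydot[4] = fP * gM * M;
}
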