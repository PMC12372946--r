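/* Compiled right-hand side and dose-event handlers for the
 * tear/aqueous/vitreous ranibizumab-VEGF model, driven by deSolve.
 *
 * State vector y (pmol/mL):
 *   0 r_tear, 1 v_aq, 2 r_aq, 3 u_aq, 4 w_aq, 5 v_vit, 6 r_vit, 7 u_vit,
 *   8 w_vit.
 *
 * Parameter vector (see .pack_parms in R/simulate.R):
 *   0 tau_loss, 1 V_drop, 2 V_tear_norm, 3 V_tear_res, 4 V_aq, 5 V_vit,
 *   6 A_tear_aq, 7 A_aq_vit, 8 A_vit_ret, 9 k_on, 10 k_off,
 *   11..14 delta_aq (v,r,u,w), 15..18 delta_vit (v,r,u,w),
 *   19 beta_tear_aq_r, 20..23 beta_aq_vit (v,r,u,w),
 *   24..26 beta_vit_ret (r,u,w), 27 phi_vit_v, 28 psi_tear, 29 psi_aq,
 *   30 r_dose, 31 r_tear_init,
 *   32 tear_active, 33 tear_volume_mode (0 const_norm, 1 depleting_human,
 *   2 const_drop_porcine, 3 depleting_porcine), 34 tear_conc_mode
 *   (0 depleting, 1 held), 35 vegf_active.
 *
 * The event table (global times + bitmask codes: 1 drop, 2 injection,
 * 4 lens on, 8 lens off, 0 integrator restart only) is installed with
 * C_ocu_set_events before each integration; the event handler tracks the
 * last drop time (tear volume runs on local time) and the lens state.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 36
static double parms[NPARMS];

#define MAXEV 250000
static double ev_times[MAXEV];
static int ev_codes[MAXEV];
static int n_ev = 0;
static int ev_cursor = 0;
static double last_drop = -1.0;   /* negative: no drop has occurred */
static int lens_worn = 0;

void ocu_initmod(void (*odeparms)(int *, double *)) {
  int n = NPARMS;
  odeparms(&n, parms);
}

SEXP C_ocu_set_events(SEXP times, SEXP codes, SEXP last_drop0, SEXP lens0) {
  int n = LENGTH(times);
  if (n > MAXEV) error("too many treatment events (%d > %d)", n, MAXEV);
  for (int i = 0; i < n; i++) {
    ev_times[i] = REAL(times)[i];
    ev_codes[i] = INTEGER(codes)[i];
  }
  n_ev = n;
  ev_cursor = 0;
  last_drop = REAL(last_drop0)[0];
  lens_worn = INTEGER(lens0)[0];
  return R_NilValue;
}

static double tear_vol(double t) {
  double tau = parms[0], Vd = parms[1], Vn = parms[2], Vres = parms[3];
  double tl;
  int mode = (int) parms[33];
  switch (mode) {
  case 0: return Vn;
  case 1:
    if (last_drop < 0) return Vn;
    tl = t - last_drop;
    if (tl >= tau) return Vn;
    return Vn + (Vres - Vn) * (1.0 - tl / tau);
  case 2: return Vd;
  default: /* 3: porcine run-off; drop applied at local t = 0 */
    tl = (last_drop < 0) ? t : t - last_drop;
    if (tl >= tau) return 0.0;
    return Vd * (1.0 - tl / tau);
  }
}

void ocu_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  double Vaq = parms[4], Vvit = parms[5], Ata = parms[6], Aav = parms[7],
    Avr = parms[8], kon = parms[9], koff = parms[10], bta = parms[19],
    phi = parms[27], psit = parms[28], psia = parms[29];
  int tear_active = (int) parms[32];
  int held = ((int) parms[34]) == 1 || lens_worn;
  int vegf = (int) parms[35];
  double flux_ta = 0.0;

  ydot[0] = 0.0;
  if (tear_active) {
    if (held) {
      flux_ta = bta * Ata * y[0];
    } else {
      double Vt = tear_vol(*t);
      if (Vt > 0.0) {
        ydot[0] = -(bta * Ata + psit) / Vt * y[0];
        flux_ta = bta * Ata * y[0];
      }
    }
  }

  if (vegf) {
    const double bav[4] = {parms[20], parms[21], parms[22], parms[23]};
    const double bvr[4] = {0.0, parms[24], parms[25], parms[26]};
    const double dAq[4] = {parms[11], parms[12], parms[13], parms[14]};
    const double dVit[4] = {parms[15], parms[16], parms[17], parms[18]};
    double rxa[4], rxv[4];
    /* reaction terms, order v, r, u, w */
    {
      double v = y[1], r = y[2], u = y[3], w = y[4];
      double b1 = 2.0 * kon * v * r, u1 = koff * u;
      double b2 = kon * r * u, u2 = 2.0 * koff * w;
      rxa[0] = u1 - b1;
      rxa[1] = (u1 - b1) + (u2 - b2);
      rxa[2] = -u1 + b1 + u2 - b2;
      rxa[3] = -u2 + b2;
    }
    {
      double v = y[5], r = y[6], u = y[7], w = y[8];
      double b1 = 2.0 * kon * v * r, u1 = koff * u;
      double b2 = kon * r * u, u2 = 2.0 * koff * w;
      rxv[0] = u1 - b1;
      rxv[1] = (u1 - b1) + (u2 - b2);
      rxv[2] = -u1 + b1 + u2 - b2;
      rxv[3] = -u2 + b2;
    }
    for (int s = 0; s < 4; s++) {
      int ia = 1 + s, iv = 5 + s;
      double diff = y[iv] - y[ia];
      ydot[ia] = rxa[s] - dAq[s] * y[ia] + bav[s] * Aav / Vaq * diff -
        psia / Vaq * y[ia];
      ydot[iv] = rxv[s] - dVit[s] * y[iv] - bav[s] * Aav / Vvit * diff;
      if (s > 0 && bvr[s] > 0.0)
        ydot[iv] -= bvr[s] * Avr / Vvit * y[iv];
    }
    ydot[2] += flux_ta / Vaq;     /* gain from tear (drug only) */
    ydot[5] += phi / Vvit;        /* retinal VEGF supply */
  } else {
    double bavr = parms[21], dar = parms[12], dvr = parms[16],
      bvrr = parms[24];
    double diff = y[6] - y[2];
    ydot[1] = ydot[3] = ydot[4] = ydot[5] = ydot[7] = ydot[8] = 0.0;
    ydot[2] = -dar * y[2] + bavr * Aav / Vaq * diff - psia / Vaq * y[2] +
      flux_ta / Vaq;
    ydot[6] = -dvr * y[6] - bavr * Aav / Vvit * diff;
    if (bvrr > 0.0) ydot[6] -= bvrr * Avr / Vvit * y[6];
  }
}

void ocu_event(int *n, double *t, double *y) {
  while (ev_cursor < n_ev && ev_times[ev_cursor] < *t - 1e-9) ev_cursor++;
  while (ev_cursor < n_ev && fabs(ev_times[ev_cursor] - *t) <= 1e-9) {
    int code = ev_codes[ev_cursor];
    if (code & 1) {             /* drop: instantaneous mixing */
      double Vn = parms[2], Vd = parms[1];
      y[0] = y[0] * Vn / (Vn + Vd) + parms[30] * Vd / (Vn + Vd);
      last_drop = *t;
    }
    if (code & 4) {             /* lens on */
      y[0] = parms[31];
      lens_worn = 1;
    }
    if (code & 8) lens_worn = 0; /* lens off */
    if (code & 2)               /* injection */
      y[6] += parms[30] * parms[1] / parms[5];
    ev_cursor++;
  }
}

static const R_CallMethodDef CallEntries[] = {
  {"C_ocu_set_events", (DL_FUNC) &C_ocu_set_events, 4},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"ocu_initmod", (DL_FUNC) &ocu_initmod, 1},
  {"ocu_derivs", (DL_FUNC) &ocu_derivs, 6},
  {"ocu_event", (DL_FUNC) &ocu_event, 3},
  {NULL, NULL, 0}
};

void R_init_ocuvegf(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
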