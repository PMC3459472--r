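/* Compiled right-hand sides for the sinoatrial node cell models.
 *
 * Two model families are implemented:
 *   - "boyett"  : central/peripheral rabbit SAN membrane model in the
 *                 Zhang-2000 lineage, extended with a sustained inward
 *                 current (I_st) and a two-store SR Ca2+ handling subsystem.
 *                 Native units: uS / nA / uF, gate time constants in ms
 *                 (converted from the s-based source expressions).
 *   - "kurata"  : rabbit SAN primary pacemaker model in the Kurata-2002
 *                 lineage (per-pF conductances, subspace Ca2+ compartment,
 *                 kinetic Ca2+ buffers, no I_st).
 *
 * Both expose the deSolve compiled-code interface (initfunc/derivs with
 * currents as extra output variables, in pA) and a direct .C entry point
 * used for single-state current evaluation.
 *
 * ISO modulation enters exclusively through parameters: conductance scale
 * factors are pre-applied in R; the voltage shifts (shift_f, shift_kr) and
 * the deactivation-rate factor (taukr_scale) are parameters read here.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

static double FARADAY = 96485.0;   /* C/mol */
static double RTF     = 26.712338; /* mV, R*T/F at 310 K */

/* ------------------------------------------------------------------ */
/* Boyett-family model                                                 */
/* ------------------------------------------------------------------ */

#define B_NSTATE 20
#define B_NCUR   18
#define B_NPAR   40

/* state indices */
enum { bV, bM, bH1, bH2, bDL, bFL, bDT, bFT, bQ, bR,
       bPAF, bPAS, bPIK, bXS, bY, bQA, bQI, bCAI, bCAUP, bCAREL };

/* parameter indices */
enum { pCM, pGNA, pGCAL, pGCAT, pGTO, pGSUS, pGKR, pGKS, pGFNA, pGFK,
       pGBNA, pGBCA, pGBK, pKNACA, pIPMAX, pGST, pEST,
       pPUP, pPREL, pKUP, pKREL, pTAUTR, pVI, pVUP, pVREL,
       pNAI, pNAO, pKI, pKO, pCAO, pECAL, pECAT,
       pSHIFTF, pSHIFTKR, pTAUKRS, pTAUFLF,
       pDLVH, pFLVH, pPAVH, pPASL };

static void boyett_core(const double *y, const double *p,
                        double *dy, double *cur)
{
    double V = y[bV];
    double cai = y[bCAI], caup = y[bCAUP], carel = y[bCAREL];

    double e_na = RTF * log(p[pNAO] / p[pNAI]);
    double e_k  = RTF * log(p[pKO] / p[pKI]);
    double e_ks = RTF * log((p[pKO] + 0.12 * p[pNAO]) /
                            (p[pKI] + 0.12 * p[pNAI]));
    double e_ca = 0.5 * RTF * log(p[pCAO] / cai);

    /* --- I_Na (GHK flux form; absent in the central cell) ---------- */
    double i_na = 0.0;
    if (p[pGNA] > 0.0) {
        double h = y[bH2], h1 = y[bH1];
        double f_na = 0.0952 * exp(-0.063 * (V + 34.4)) /
                      (1.0 + 1.66 * exp(-0.225 * (V + 63.7))) + 0.0869;
        double hh = (1.0 - f_na) * h1 + f_na * h;
        double num = expm1((V - e_na) / RTF);
        double den = expm1(V / RTF);
        double ghk = (fabs(den) < 1e-10) ? RTF * num : V * num / den;
        i_na = p[pGNA] * y[bM] * y[bM] * y[bM] * hh *
               p[pNAO] * (FARADAY / RTF) * ghk;
    }

    /* --- I_CaL ----------------------------------------------------- */
    double i_cal = p[pGCAL] *
        (y[bFL] * y[bDL] + 0.006 / (1.0 + exp(-(V + 14.1) / 6.0))) *
        (V - p[pECAL]);

    /* --- I_CaT ----------------------------------------------------- */
    double i_cat = p[pGCAT] * y[bDT] * y[bFT] * (V - p[pECAT]);

    /* --- I_to / I_sus ---------------------------------------------- */
    double i_to  = p[pGTO] * y[bQ] * y[bR] * (V - e_k);
    double i_sus = p[pGSUS] * y[bR] * (V - e_k);

    /* --- I_Kr ------------------------------------------------------ */
    double pa = 0.6 * y[bPAF] + 0.4 * y[bPAS];
    double i_kr = p[pGKR] * pa * y[bPIK] * (V - e_k);

    /* --- I_Ks ------------------------------------------------------ */
    double i_ks = p[pGKS] * y[bXS] * y[bXS] * (V - e_ks);

    /* --- I_f -------------------------------------------------------- */
    double i_fna = p[pGFNA] * y[bY] * (V - e_na);
    double i_fk  = p[pGFK]  * y[bY] * (V - e_k);

    /* --- I_st ------------------------------------------------------- */
    double i_st = p[pGST] * y[bQA] * y[bQI] * (V - p[pEST]);

    /* --- backgrounds, exchanger, pump ------------------------------- */
    double i_bna = p[pGBNA] * (V - e_na);
    double i_bca = p[pGBCA] * (V - e_ca);
    double i_bk  = p[pGBK]  * (V - e_k);

    double nai3 = p[pNAI] * p[pNAI] * p[pNAI];
    double nao3 = p[pNAO] * p[pNAO] * p[pNAO];
    double i_naca = p[pKNACA] *
        (nai3 * p[pCAO] * exp(0.03743 * V * 0.5) -
         nao3 * cai     * exp(-0.03743 * V * 0.5)) /
        (1.0 + 1e-4 * (cai * nao3 + p[pCAO] * nai3));

    double i_p = p[pIPMAX] *
        pow(p[pNAI] / (5.64 + p[pNAI]), 3.0) *
        pow(p[pKO] / (0.621 + p[pKO]), 2.0) *
        1.6 / (1.5 + exp(-(V + 60.0) / 40.0));

    double i_tot = i_na + i_cal + i_cat + i_to + i_sus + i_kr + i_ks +
                   i_fna + i_fk + i_st + i_bna + i_bca + i_bk + i_naca + i_p;

    /* --- gate kinetics (source taus in s -> ms) --------------------- */
    /* m */
    double m_inf = pow(1.0 / (1.0 + exp(-(V + 30.32) / 5.46)), 1.0 / 3.0);
    double tau_m = 1000.0 * (0.0006247 /
        (0.832 * exp(-0.335 * (V + 56.7)) + 0.627 * exp(0.082 * (V + 65.01)))
        + 4.0e-5);
    dy[bM] = (m_inf - y[bM]) / tau_m;

    /* h1, h2 */
    double h_inf = 1.0 / (1.0 + exp((V + 66.1) / 6.4));
    double tau_h1 = 1000.0 * (3.717e-6 * exp(-0.2815 * (V + 17.11)) /
        (1.0 + 0.003732 * exp(-0.3426 * (V + 37.76))) + 5.977e-4);
    double tau_h2 = 1000.0 * (3.186e-8 * exp(-0.6219 * (V + 18.8)) /
        (1.0 + 7.189e-5 * exp(-0.6683 * (V + 34.07))) + 3.556e-3);
    dy[bH1] = (h_inf - y[bH1]) / tau_h1;
    dy[bH2] = (h_inf - y[bH2]) / tau_h2;

    /* d_L */
    double a_dl;
    {
        double t1 = -28.38 * (V + 35.0), d1 = expm1(-(V + 35.0) / 2.5);
        double t2 = -84.9 * V,           d2 = expm1(-0.208 * V);
        double f1 = (fabs(d1) < 1e-10) ? 28.38 * 2.5 : t1 / d1;
        double f2 = (fabs(d2) < 1e-10) ? 84.9 / 0.208 : t2 / d2;
        a_dl = f1 + f2;
    }
    double b_dl;
    {
        double t = 11.42 * (V - 5.0), d = expm1(0.4 * (V - 5.0));
        b_dl = (fabs(d) < 1e-10) ? 11.42 / 0.4 : t / d;
    }
    double dl_inf = 1.0 / (1.0 + exp(-(V - p[pDLVH]) / 6.0));
    double tau_dl = 2000.0 / (a_dl + b_dl);
    dy[bDL] = (dl_inf - y[bDL]) / tau_dl;

    /* f_L */
    double a_fl;
    {
        double t = 3.75 * (V + 28.0), d = expm1((V + 28.0) / 4.0);
        a_fl = (fabs(d) < 1e-10) ? 3.75 * 4.0 : t / d;
    }
    double b_fl = 30.0 / (1.0 + exp(-(V + 28.0) / 4.0));
    double fl_inf = 1.0 / (1.0 + exp((V - p[pFLVH]) / 5.0));
    double tau_fl = 1000.0 * p[pTAUFLF] / (a_fl + b_fl);
    dy[bFL] = (fl_inf - y[bFL]) / tau_fl;

    /* d_T, f_T */
    double a_dt = 1068.0 * exp((V + 26.3) / 30.0);
    double b_dt = 1068.0 * exp(-(V + 26.3) / 30.0);
    double dt_inf = 1.0 / (1.0 + exp(-(V + 37.0) / 6.8));
    dy[bDT] = (dt_inf - y[bDT]) * (a_dt + b_dt) / 1000.0;

    double a_ft = 15.3 * exp(-(V + 71.7) / 83.3);
    double b_ft = 15.0 * exp((V + 71.7) / 15.38);
    double ft_inf = 1.0 / (1.0 + exp((V + 71.0) / 9.0));
    dy[bFT] = (ft_inf - y[bFT]) * (a_ft + b_ft) / 1000.0;

    /* q, r */
    double q_inf = 1.0 / (1.0 + exp((V + 59.37) / 13.1));
    double tau_q = 1000.0 * (0.0101 + 0.06517 /
        (0.57 * exp(-0.08 * (V + 49.0)) + 2.4e-5 * exp(0.1 * (V + 50.93))));
    dy[bQ] = (q_inf - y[bQ]) / tau_q;

    double r_inf = 1.0 / (1.0 + exp(-(V - 10.93) / 19.7));
    double tau_r = 1000.0 * (0.00298 + 0.01559 /
        (1.037 * exp(0.09 * (V + 30.61)) + 0.369 * exp(-0.12 * (V + 23.84))));
    dy[bR] = (r_inf - y[bR]) / tau_r;

    /* I_Kr gates; activation shifted by shift_kr (negative = leftward),
     * both activation time constants divided by taukr_scale */
    double vs = V - p[pSHIFTKR];
    double pa_inf = 1.0 / (1.0 + exp(-(vs - p[pPAVH]) / p[pPASL]));
    double tau_paf = 1000.0 /
        (37.2 * exp((V - 9.0) / 15.9) + 0.96 * exp(-(V - 9.0) / 22.5)) /
        p[pTAUKRS];
    double tau_pas = 1000.0 /
        (4.2 * exp((V - 9.0) / 17.0) + 0.15 * exp(-(V - 9.0) / 21.6)) /
        p[pTAUKRS];
    dy[bPAF] = (pa_inf - y[bPAF]) / tau_paf;
    dy[bPAS] = (pa_inf - y[bPAS]) / tau_pas;

    double pi_inf = 1.0 / (1.0 + exp((V + 18.6) / 10.1));
    dy[bPIK] = (pi_inf - y[bPIK]) / 2.0;

    /* xs */
    double a_xs = 14.0 / (1.0 + exp(-(V - 40.0) / 9.0));
    double b_xs = exp(-V / 45.0);
    dy[bXS] = (a_xs / (a_xs + b_xs) - y[bXS]) * (a_xs + b_xs) / 1000.0;

    /* y (I_f); steady-state curve shifted by +shift_f (depolarizing),
     * time constant unshifted */
    double vf = V - p[pSHIFTF];
    double a_ys = exp(-(vf + 78.91) / 26.62);
    double b_ys = exp((vf + 75.13) / 21.25);
    double a_y  = exp(-(V + 78.91) / 26.62);
    double b_y  = exp((V + 75.13) / 21.25);
    double y_inf = a_ys / (a_ys + b_ys);
    double tau_y = 1000.0 / (a_y + b_y);
    dy[bY] = (y_inf - y[bY]) / tau_y;

    /* I_st gates (native ms) */
    double qa_inf = 1.0 / (1.0 + exp(-(V + 57.0) / 5.0));
    double a_qa = 1.0 / (0.15 * exp(-V / 11.0) + 0.2 * exp(-V / 700.0));
    double b_qa = 1.0 / (16.0 * exp(V / 8.0) + 15.0 * exp(V / 50.0));
    dy[bQA] = (qa_inf - y[bQA]) * (a_qa + b_qa);

    double a_qi = 1.0 / (3100.0 * exp(V / 13.0) + 700.0 * exp(V / 70.0));
    double b_qi = 1.0 / (95.0 * exp(-V / 10.0) + 50.0 * exp(-V / 700.0)) +
                  0.000229 / (1.0 + exp(-V / 5.0));
    double qi_inf = a_qi / (a_qi + b_qi);
    double tau_qi = 6.65 / (a_qi + b_qi);
    dy[bQI] = (qi_inf - y[bQI]) / tau_qi;

    /* --- SR Ca2+ handling (two stores, CICR gated by Cai) ----------- */
    double j_up  = p[pPUP] * cai / (cai + p[pKUP]);
    double j_tr  = (caup - carel) / p[pTAUTR];
    double ca4 = cai * cai * cai * cai;
    double kr4 = p[pKREL] * p[pKREL] * p[pKREL] * p[pKREL];
    double hill  = ca4 / (ca4 + kr4);   /* steep CICR trigger */
    double j_rel = p[pPREL] * carel * hill;

    /* rapid buffering (troponin-Ca + calmodulin) in the myoplasm,
     * calsequestrin in the release store */
    double ktc = 0.00502, kcm = 0.00238, kcq = 0.833;
    double beta_i = 1.0 / (1.0 +
        0.031 * ktc / ((ktc + cai) * (ktc + cai)) +
        0.045 * kcm / ((kcm + cai) * (kcm + cai)));
    double beta_rel = 1.0 / (1.0 +
        10.0 * kcq / ((kcq + carel) * (kcq + carel)));

    double i_ca_net = i_cal + i_cat + i_bca - 2.0 * i_naca; /* nA */
    dy[bCAI] = beta_i * (-i_ca_net * 1000.0 / (2.0 * FARADAY * p[pVI]) +
                         (j_rel * p[pVREL] - j_up * p[pVUP]) / p[pVI]);
    dy[bCAUP]  = j_up - j_tr * p[pVREL] / p[pVUP];
    dy[bCAREL] = beta_rel * (j_tr - j_rel);

    /* --- membrane ---------------------------------------------------*/
    dy[bV] = -(i_tot / p[pCM]) * 1e-3;  /* nA/uF = mV/s -> mV/ms */

    if (cur) {
        cur[0]  = i_na   * 1000.0;
        cur[1]  = i_cal  * 1000.0;
        cur[2]  = i_cat  * 1000.0;
        cur[3]  = i_to   * 1000.0;
        cur[4]  = i_sus  * 1000.0;
        cur[5]  = i_kr   * 1000.0;
        cur[6]  = i_ks   * 1000.0;
        cur[7]  = (i_kr + i_ks) * 1000.0;
        cur[8]  = i_fna  * 1000.0;
        cur[9]  = i_fk   * 1000.0;
        cur[10] = (i_fna + i_fk) * 1000.0;
        cur[11] = i_st   * 1000.0;
        cur[12] = i_bna  * 1000.0;
        cur[13] = i_bca  * 1000.0;
        cur[14] = i_bk   * 1000.0;
        cur[15] = i_naca * 1000.0;
        cur[16] = i_p    * 1000.0;
        cur[17] = i_tot  * 1000.0;
    }
}

static double boyett_parms[B_NPAR];

void sanpace_init_boyett(void (*odeparms)(int *, double *))
{
    int n = B_NPAR;
    odeparms(&n, boyett_parms);
}

void sanpace_deriv_boyett(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    boyett_core(y, boyett_parms, ydot, (ip[0] >= B_NCUR) ? yout : NULL);
}

/* direct evaluation at a single state (used by evaluate_currents) */
void sanpace_eval_boyett(double *y, double *parms, double *dy, double *cur)
{
    boyett_core(y, parms, dy, cur);
}

/* ------------------------------------------------------------------ */
/* Kurata-family model                                                 */
/* ------------------------------------------------------------------ */

#define K_NSTATE 23
#define K_NCUR   15
#define K_NPAR   35

enum { kV, kDL, kFL, kFCA, kDT, kFT, kPAF, kPAS, kPIK, kN, kQ, kR, kY,
       kCAI, kCASUB, kCAREL, kCAUP, kFTC, kFTMC, kFTMM, kFCMI, kFCMS, kFCQ };

enum { qCM, qGCAL, qGCAT, qGKR, qGKS, qGTO, qGSUS, qGH, qGBNA, qGBCA,
       qKNACA, qIPMAX, qPUP, qPREL, qKUP, qKREL, qTAUTR, qTAUDIF,
       qVI, qVSUB, qVUP, qVREL, qNAI, qNAO, qKI, qKO, qCAO,
       qECAL, qECAT, qKMFCA, qAFCA, qSHIFTF, qSHIFTKR, qTAUKRS, qDTVH };

static void kurata_core(const double *y, const double *p,
                        double *dy, double *cur)
{
    double V = y[kV];
    double cai = y[kCAI], casub = y[kCASUB];
    double carel = y[kCAREL], caup = y[kCAUP];
    double cm = p[qCM];

    double e_na = RTF * log(p[qNAO] / p[qNAI]);
    double e_k  = RTF * log(p[qKO] / p[qKI]);
    double e_ks = RTF * log((p[qKO] + 0.12 * p[qNAO]) /
                            (p[qKI] + 0.12 * p[qNAI]));
    double e_ca = 0.5 * RTF * log(p[qCAO] / casub);

    /* densities in pA/pF */
    double i_cal = p[qGCAL] * y[kDL] * y[kFL] * y[kFCA] * (V - p[qECAL]);
    double i_cat = p[qGCAT] * y[kDT] * y[kFT] * (V - p[qECAT]);

    double pa = 0.6 * y[kPAF] + 0.4 * y[kPAS];
    double i_kr = p[qGKR] * pa * y[kPIK] * (V - e_k);
    double i_ks = p[qGKS] * y[kN] * y[kN] * (V - e_ks);

    double i_to  = p[qGTO] * y[kQ] * y[kR] * (V - e_k);
    double i_sus = p[qGSUS] * y[kR] * (V - e_k);

    double i_hna = p[qGH] * 0.3833 * y[kY] * (V - e_na);
    double i_hk  = p[qGH] * 0.6167 * y[kY] * (V - e_k);

    double i_bna = p[qGBNA] * (V - e_na);
    double i_bca = p[qGBCA] * (V - e_ca);

    double nai3 = p[qNAI] * p[qNAI] * p[qNAI];
    double nao3 = p[qNAO] * p[qNAO] * p[qNAO];
    double i_naca = p[qKNACA] *
        (nai3 * p[qCAO] * exp(0.03743 * V * 0.5) -
         nao3 * casub   * exp(-0.03743 * V * 0.5)) /
        (1.0 + 1e-4 * (casub * nao3 + p[qCAO] * nai3));

    double i_p = p[qIPMAX] *
        pow(p[qNAI] / (5.64 + p[qNAI]), 3.0) *
        pow(p[qKO] / (0.621 + p[qKO]), 2.0) *
        1.6 / (1.5 + exp(-(V + 60.0) / 40.0));

    double i_tot = i_cal + i_cat + i_kr + i_ks + i_to + i_sus +
                   i_hna + i_hk + i_bna + i_bca + i_naca + i_p;

    /* --- gates (ms) -------------------------------------------------*/
    double dl_inf = 1.0 / (1.0 + exp(-(V + 14.1) / 6.0));
    double a_dl, b_dl;
    {
        double t1 = -0.02839 * (V + 35.0), d1 = expm1(-(V + 35.0) / 2.5);
        double t2 = -0.0849 * V,           d2 = expm1(-V / 4.8);
        double f1 = (fabs(d1) < 1e-10) ? 0.02839 * 2.5 : t1 / d1;
        double f2 = (fabs(d2) < 1e-10) ? 0.0849 * 4.8 : t2 / d2;
        a_dl = f1 + f2;
        double t3 = 0.01143 * (V - 5.0), d3 = expm1((V - 5.0) / 2.5);
        b_dl = (fabs(d3) < 1e-10) ? 0.01143 * 2.5 : t3 / d3;
    }
    dy[kDL] = (dl_inf - y[kDL]) * (a_dl + b_dl);

    double fl_inf = 1.0 / (1.0 + exp((V + 30.0) / 5.0));
    double tau_fl = 257.1 * exp(-pow((V + 32.5) / 13.9, 2.0)) + 44.3;
    dy[kFL] = (fl_inf - y[kFL]) / tau_fl;

    double fca_inf = p[qKMFCA] / (p[qKMFCA] + casub);
    double tau_fca = fca_inf / p[qAFCA];
    dy[kFCA] = (fca_inf - y[kFCA]) / tau_fca;

    double dt_inf = 1.0 / (1.0 + exp(-(V - p[qDTVH]) / 6.8));
    double tau_dt = 1.0 / (1.068 * exp((V + 26.3) / 30.0) +
                           1.068 * exp(-(V + 26.3) / 30.0));
    dy[kDT] = (dt_inf - y[kDT]) / tau_dt;

    double ft_inf = 1.0 / (1.0 + exp((V + 61.7) / 5.6));
    double tau_ft = 1.0 / (0.0153 * exp(-(V + 61.7) / 83.3) +
                           0.015 * exp((V + 61.7) / 15.38));
    dy[kFT] = (ft_inf - y[kFT]) / tau_ft;

    double vs = V - p[qSHIFTKR];
    double pa_inf = 1.0 / (1.0 + exp(-(vs + 23.2) / 10.6));
    double tau_paf = 0.84655354 /
        (0.0372 * exp(V / 15.9) + 0.00096 * exp(-V / 22.5)) / p[qTAUKRS];
    double tau_pas = 0.84655354 /
        (0.0042 * exp(V / 17.0) + 0.00015 * exp(-V / 21.6)) / p[qTAUKRS];
    dy[kPAF] = (pa_inf - y[kPAF]) / tau_paf;
    dy[kPAS] = (pa_inf - y[kPAS]) / tau_pas;

    double pi_inf = 1.0 / (1.0 + exp((V + 28.6) / 17.1));
    double tau_pi = 1.0 / (0.1 * exp(-V / 54.645) + 0.656 * exp(V / 106.157));
    dy[kPIK] = (pi_inf - y[kPIK]) / tau_pi;

    double a_n = 0.014 / (1.0 + exp(-(V - 40.0) / 9.0));
    double b_n = 0.001 * exp(-V / 45.0);
    dy[kN] = a_n * (1.0 - y[kN]) - b_n * y[kN];

    double q_inf = 1.0 / (1.0 + exp((V + 49.0) / 13.0));
    double tau_q = 6.06 + 39.102 /
        (0.57 * exp(-0.08 * (V + 44.0)) + 0.065 * exp(0.1 * (V + 45.93)));
    dy[kQ] = (q_inf - y[kQ]) / tau_q;

    double r_inf = 1.0 / (1.0 + exp(-(V - 19.3) / 15.0));
    double tau_r = 2.75 + 14.40516 /
        (1.037 * exp(0.09 * (V + 30.61)) + 0.369 * exp(-0.12 * (V + 23.84)));
    dy[kR] = (r_inf - y[kR]) / tau_r;

    double vf = V - p[qSHIFTF];
    double y_inf = 1.0 / (1.0 + exp((vf + 64.0) / 13.5));
    double tau_y = 0.7166529 /
        (exp(-(V + 386.9) / 45.302) + exp((V - 73.08) / 19.231));
    dy[kY] = (y_inf - y[kY]) / tau_y;

    /* --- Ca2+ handling ----------------------------------------------*/
    double j_up = p[qPUP] / (1.0 + p[qKUP] / cai);
    double j_tr = (caup - carel) / p[qTAUTR];
    double krc = p[qKREL] / casub;
    double j_rel = p[qPREL] * (carel - casub) / (1.0 + krc * krc);
    double j_dif = (casub - cai) / p[qTAUDIF];

    double dftc  = 88.8 * cai * (1.0 - y[kFTC]) - 0.446 * y[kFTC];
    double dftmc = 227.7 * cai * (1.0 - y[kFTMC] - y[kFTMM]) -
                   0.00751 * y[kFTMC];
    double dftmm = 2.277 * 2.5 * (1.0 - y[kFTMC] - y[kFTMM]) -
                   0.751 * y[kFTMM];
    double dfcmi = 227.7 * cai * (1.0 - y[kFCMI]) - 0.542 * y[kFCMI];
    double dfcms = 227.7 * casub * (1.0 - y[kFCMS]) - 0.542 * y[kFCMS];
    double dfcq  = 0.534 * carel * (1.0 - y[kFCQ]) - 0.445 * y[kFCQ];
    dy[kFTC] = dftc;  dy[kFTMC] = dftmc; dy[kFTMM] = dftmm;
    dy[kFCMI] = dfcmi; dy[kFCMS] = dfcms; dy[kFCQ] = dfcq;

    double i_ca_sub = (i_cal + i_cat + i_bca - 2.0 * i_naca) * cm; /* pA */
    dy[kCASUB] = -i_ca_sub / (2.0 * FARADAY * p[qVSUB]) +
                 j_rel * p[qVREL] / p[qVSUB] - j_dif - 0.045 * dfcms;
    dy[kCAI] = (j_dif * p[qVSUB] - j_up * p[qVUP]) / p[qVI] -
               (0.045 * dfcmi + 0.031 * dftc + 0.062 * dftmc);
    dy[kCAREL] = j_tr - j_rel - 10.0 * dfcq;
    dy[kCAUP]  = j_up - j_tr * p[qVREL] / p[qVUP];

    dy[kV] = -i_tot; /* pA/pF = mV/ms */

    if (cur) {
        cur[0]  = i_cal * cm;
        cur[1]  = i_cat * cm;
        cur[2]  = i_to  * cm;
        cur[3]  = i_sus * cm;
        cur[4]  = i_kr  * cm;
        cur[5]  = i_ks  * cm;
        cur[6]  = (i_kr + i_ks) * cm;
        cur[7]  = i_hna * cm;
        cur[8]  = i_hk  * cm;
        cur[9]  = (i_hna + i_hk) * cm;
        cur[10] = i_bna * cm;
        cur[11] = i_bca * cm;
        cur[12] = i_naca * cm;
        cur[13] = i_p * cm;
        cur[14] = i_tot * cm;
    }
}

static double kurata_parms[K_NPAR];

void sanpace_init_kurata(void (*odeparms)(int *, double *))
{
    int n = K_NPAR;
    odeparms(&n, kurata_parms);
}

void sanpace_deriv_kurata(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    kurata_core(y, kurata_parms, ydot, (ip[0] >= K_NCUR) ? yout : NULL);
}

void sanpace_eval_kurata(double *y, double *parms, double *dy, double *cur)
{
    kurata_core(y, parms, dy, cur);
}
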