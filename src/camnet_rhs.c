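/* Compiled right-hand side of the CaM-CaMKII-PP1 signalling network,
 * in the deSolve compiled-model convention (initfunc + derivs).
 *
 * State vector (length 25, all uM):
 *   0..8  free CaM nine-state grid (C-lobe occupancy fast, N-lobe slow):
 *         CaM0, CaM1C, CaM2C, CaM1N, CaM1C1N, CaM2C1N, CaM2N, CaM1C2N, CaM4
 *   9  CaMAC1      10 CaMAC8     11 CaMPDE1   12 CaMCaNA   13 CaCaNB
 *   14 CaMCaMKII   15 CaMCaMKIIP 16 CaMKIIP   17 cAMP      18 PDE4BP
 *   19 PDE4DP      20 I1P        21 I1PP1     22 R2C2cAMP2 23 R2C2cAMP4
 *   24 PKAc
 *
 * The parameter block is the canonical 78-element parameter vector
 * (R/parameters.R order), followed by run-time extras
 *   [78] mode (1 full PKA, 2 reduced PKA)
 *   [79] k19 orientation (0 reversed, 1 as printed)
 *   [80] n_pulses  [81] A  [82] tau  [83] Ca_basal
 *   [84...] pulse times (padded with zeros up to MAXPULSE)
 *
 * Free pools (inhibited AC1, free CaMKII, free PP1, ...) are computed
 * algebraically from the totals, so pool conservation is exact by
 * construction; only the free-CaM pool relies on solver accuracy.
 */

#include <R.h>
#include <math.h>

#define NBASE 78
#define MAXPULSE 1024
#define NPARMS (NBASE + 6 + MAXPULSE)

static double P[NPARMS];

/* canonical parameter indices (must match R/parameters.R .param_names) */
#define kon_NT   P[0]
#define kon_NR   P[1]
#define koff_NT  P[2]
#define koff_NR  P[3]
#define kon_CT   P[4]
#define kon_CR   P[5]
#define koff_CT  P[6]
#define koff_CR  P[7]
#define kc1f     P[8]
#define kc1b     P[9]
#define kc2f     P[10]
#define kc2b     P[11]
#define kc3f     P[12]
#define kc3b     P[13]
#define kc4f     P[14]
#define kc4b1    P[15]
#define Kd1      P[16]
#define n1       P[17]
#define kc4b2    P[18]
#define Kd2      P[19]
#define n2       P[20]
#define kc5f     P[21]
#define kc5b1    P[22]
#define kc5b2    P[23]
#define kcat1    P[24]
#define kcat2    P[25]
#define kcat3    P[26]
#define kcat4    P[27]
#define Km4      P[28]
#define k10      P[29]
#define kcat5    P[30]
#define kcat6    P[31]
#define Km5      P[32]
#define kcat7    P[33]
#define kcat8    P[34]
#define Km7      P[35]
#define kcat9    P[36]
#define kcat10   P[37]
#define Km9      P[38]
#define kcat11   P[39]
#define Km11     P[40]
#define kcat12   P[41]
#define Km12     P[42]
#define kcat13   P[43]
#define Km13     P[44]
#define kcat14   P[45]
#define kcat15   P[46]
#define Km15     P[47]
#define kcat16   P[48]
#define Km16     P[49]
#define k17f     P[50]
#define k17b     P[51]
#define k18f     P[52]
#define k18b     P[53]
#define k19f     P[54]
#define k19b     P[55]
#define PKA_max  P[56]
#define IC50     P[57]
#define n_pka    P[58]
#define CaM_T    P[59]
#define CaMKII_T P[60]
#define AC1_T    P[61]
#define AC8_T    P[62]
#define ACstar_T P[63]
#define PDE1_T   P[64]
#define PP2B_T   P[65]
#define PP1_T    P[66]
#define PP2A_T   P[67]
#define I1_T     P[68]
#define PDE4B_T  P[69]
#define PDE4D_T  P[70]
#define R2C2_T   P[71]
#define K1       P[72]
#define kB_on    P[73]
#define kI1_on   P[74]
#define kI1_off  P[75]
/* P[76] Ca_basal, P[77] tau_decay: superseded by the protocol extras */

#define MODE     P[NBASE + 0]
#define ORIENT   P[NBASE + 1]
#define NPULSE   P[NBASE + 2]
#define AMP      P[NBASE + 3]
#define TAU      P[NBASE + 4]
#define CABASAL  P[NBASE + 5]
#define PTIME(i) P[NBASE + 6 + (i)]

void camnet_init(void (* odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, P);
}

static double calcium_at(double t)
{
    int i, np = (int) NPULSE;
    double ca = CABASAL, el;
    for (i = 0; i < np; i++) {
        el = t - PTIME(i);
        if (el >= 0.0 && el < 40.0 * TAU)
            ca += AMP * exp(-el / TAU);
    }
    return ca;
}

static double hill(double x, double K, double n)
{
    double xn;
    if (x <= 0.0) return 0.0;
    xn = pow(x / K, n);
    return xn / (1.0 + xn);
}

void camnet_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double Ca = calcium_at(*t);
    double CaM4 = y[8];
    double d[25];
    int i, c, n;
    double konC[2], koffC[2], konN[2], koffN[2];

    for (i = 0; i < 25; i++) d[i] = 0.0;

    /* --- nine-state CaM grid (independent lobes, T then R rates) --- */
    konC[0] = kon_CT;  konC[1] = kon_CR;
    koffC[0] = koff_CT; koffC[1] = koff_CR;
    konN[0] = kon_NT;  konN[1] = kon_NR;
    koffN[0] = koff_NT; koffN[1] = koff_NR;
    for (n = 0; n < 3; n++)
        for (c = 0; c < 2; c++) {
            int a = c + 3 * n, b = (c + 1) + 3 * n;
            double v = konC[c] * Ca * y[a] - koffC[c] * y[b];
            d[a] -= v; d[b] += v;
        }
    for (c = 0; c < 3; c++)
        for (n = 0; n < 2; n++) {
            int a = c + 3 * n, b = c + 3 * (n + 1);
            double v = konN[n] * Ca * y[a] - koffN[n] * y[b];
            d[a] -= v; d[b] += v;
        }

    /* --- free pools from totals --- */
    {
    double ac1f  = AC1_T - y[9];
    double ac8f  = AC8_T - y[10];
    double pde1f = PDE1_T - y[11];
    double canaf = PP2B_T - y[12];
    double canbf = PP2B_T - y[13];
    double kiif  = CaMKII_T - y[14] - y[15] - y[16];
    double pp1f  = PP1_T - y[21];
    double i1f   = I1_T - y[20] - y[21];
    double pde4b = PDE4B_T - y[18];
    double pde4d = PDE4D_T - y[19];
    double camp  = y[17];

    /* --- CaM4-target binding --- */
    double gate = (PP2B_T > 0.0) ? y[13] / PP2B_T : 0.0;
    double koff4 = kc4b1 * hill(Ca, Kd1, n1) + kc4b2 * (1.0 - hill(Ca, Kd2, n2));
    double v_ac1  = kc1f * CaM4 * ac1f  - kc1b * y[9];
    double v_ac8  = kc2f * CaM4 * ac8f  - kc2b * y[10];
    double v_pde1 = kc3f * CaM4 * pde1f - kc3b * y[11];
    double v_cana = kc4f * gate * CaM4 * canaf - koff4 * y[12];
    double v_canb = kB_on * Ca * canbf - kB_on * K1 * y[13];
    double v_kii  = kc5f * CaM4 * kiif  - kc5b1 * y[14];
    double v_kiip = kc5f * CaM4 * y[16] - kc5b2 * y[15];

    /* --- CaMKII T286 autophosphorylation (neighbour occupancy) --- */
    double pnb = (CaMKII_T > 0.0) ? (y[14] + y[15]) / CaMKII_T : 0.0;
    double v_auto = kcat14 * y[14] * pnb;

    /* --- dephosphorylation of (CaM)CaMKII-P by PP1 and PP2A --- */
    double S = y[15] + y[16];
    double v_dep = 0.0, v_dep_b = 0.0, v_dep_f = 0.0;
    if (S > 1e-300) {
        v_dep = kcat15 * pp1f * S / (Km15 + S) + kcat16 * PP2A_T * S / (Km16 + S);
        v_dep_b = v_dep * y[15] / S;
        v_dep_f = v_dep * y[16] / S;
    }

    /* --- PKA activity --- */
    double pkac;
    if ((int) MODE == 1) {
        pkac = y[24];
    } else {
        pkac = (camp > 0.0) ? PKA_max / (1.0 + pow(IC50 / camp, n_pka)) : 0.0;
    }

    /* --- cAMP production and hydrolysis --- */
    double v_prod = kcat1 * y[9] + kcat2 * y[10] + kcat3 * ACstar_T;
    double v_h1 = (kcat5 * pde1f + kcat6 * y[11]) * camp / (Km5 + camp);
    double v_h4b = (kcat7 * pde4b + kcat8 * y[18]) * camp / (Km7 + camp);
    double v_h4d = (kcat9 * pde4d + kcat10 * y[19]) * camp / (Km9 + camp);

    /* --- PKA feedback on PDE4B/D --- */
    double v_pb = kcat4 * pkac * pde4b / (Km4 + pde4b);
    double v_pd = kcat4 * pkac * pde4d / (Km4 + pde4d);

    /* --- inhibitor-1 / PP1 --- */
    double v_i1p  = kcat11 * pkac * i1f / (Km11 + i1f);
    double v_i1d  = kcat12 * PP2A_T * y[20] / (Km12 + y[20])
                  + kcat13 * y[12] * y[20] / (Km13 + y[20]);
    double v_bind = kI1_on * y[20] * pp1f - kI1_off * y[21];

    /* --- assemble --- */
    d[8]  += -(v_ac1 + v_ac8 + v_pde1 + v_cana + v_kii + v_kiip);
    d[9]  = v_ac1;
    d[10] = v_ac8;
    d[11] = v_pde1;
    d[12] = v_cana;
    d[13] = v_canb;
    d[14] = v_kii - v_auto + v_dep_b;
    d[15] = v_auto + v_kiip - v_dep_b;
    d[16] = -v_kiip - v_dep_f;
    d[17] = v_prod - v_h1 - v_h4b - v_h4d;
    d[18] = v_pb - k10 * y[18];
    d[19] = v_pd - k10 * y[19];
    d[20] = v_i1p - v_i1d - v_bind;
    d[21] = v_bind;

    if ((int) MODE == 1) {
        double r2c2 = R2C2_T - y[22] - y[23] - 0.5 * y[24];
        double v17 = k17f * r2c2 * camp * camp - k17b * y[22];
        double v18 = k18f * y[22] * camp * camp - k18b * y[23];
        double v19;
        if ((int) ORIENT == 1)
            v19 = k19f * y[23] - k19b * (0.5 * y[24]) * y[24] * y[24];
        else
            v19 = k19b * y[23] - k19f * (0.5 * y[24]) * y[24] * y[24];
        d[22] = v17 - v18;
        d[23] = v18 - v19;
        d[24] = 2.0 * v19;
        d[17] += -2.0 * v17 - 2.0 * v18;
    }
    }

    for (i = 0; i < 25; i++) ydot[i] = d[i];
    if (ip[0] >= 1) yout[0] = Ca;
}
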