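/* GENERATED from the declarative model definition -- do not edit by hand.
 * Compiled right-hand side of the full beta-AR signalling network
 * (32 states, 105 kinetic parameters) in deSolve compiled-code form.
 * parms layout: [kinetic params (105) | pool totals (24) | controls (7)]
 * controls: ISO dose L (M), beta1/beta2 blocker conc + K_I (M),
 *           cAMP clamp flag + clamp level (uM). */
#include <R.h>
#include <Rmath.h>
#include <math.h>
#define NPARMS_FULL 136
static double p[NPARMS_FULL];

void barswitch_full_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS_FULL;
    odeparms(&n, p);
}

static double hillf(double x, double K, double n)
{
    double a, b;
    if (x <= 0.0) return 0.0;
    a = R_pow(x, n); b = R_pow(K, n);
    return a / (a + b);
}

static double inhf(double x, double K, double n, double a)
{
    double u = a * x, num, den;
    if (u <= 0.0) return 1.0;
    num = R_pow(K, n); den = num + R_pow(u, n);
    return num / den;
}

void barswitch_full_rhs(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    const double L = p[129];
    const double clamp_on = p[134];
    double occ1, occ2, q1, q2;
    q1 = L / p[1]; q2 = L / p[3];
    occ1 = q1 / (1.0 + q1 + p[130] / p[131]);
    occ2 = q2 / (1.0 + q2 + p[132] / p[133]);

    const double v_LRb1 = y[0] > 0.0 ? y[0] : 0.0;
    const double v_LRb2 = y[1] > 0.0 ? y[1] : 0.0;
    const double v_Gsa = y[2] > 0.0 ? y[2] : 0.0;
    const double v_Gia = y[3] > 0.0 ? y[3] : 0.0;
    const double v_ACa = y[4] > 0.0 ? y[4] : 0.0;
    const double v_cAMP = clamp_on > 0.5 ? p[135] : (y[5] > 0.0 ? y[5] : 0.0);
    const double v_PKAc = y[6] > 0.0 ? y[6] : 0.0;
    const double v_pI1 = y[7] > 0.0 ? y[7] : 0.0;
    const double v_pCREB = y[8] > 0.0 ? y[8] : 0.0;
    const double v_ICERm = y[9] > 0.0 ? y[9] : 0.0;
    const double v_ICER = y[10] > 0.0 ? y[10] : 0.0;
    const double v_PDE3m = y[11] > 0.0 ? y[11] : 0.0;
    const double v_PDE3 = y[12] > 0.0 ? y[12] : 0.0;
    const double v_PDE3p = y[13] > 0.0 ? y[13] : 0.0;
    const double v_pShc = y[14] > 0.0 ? y[14] : 0.0;
    const double v_SOSGrb2 = y[15] > 0.0 ? y[15] : 0.0;
    const double v_RasGTP = y[16] > 0.0 ? y[16] : 0.0;
    const double v_Rafa = y[17] > 0.0 ? y[17] : 0.0;
    const double v_pMEK = y[18] > 0.0 ? y[18] : 0.0;
    const double v_pERK = y[19] > 0.0 ? y[19] : 0.0;
    const double v_RSKa = y[20] > 0.0 ? y[20] : 0.0;
    const double v_MSKa = y[21] > 0.0 ? y[21] : 0.0;
    const double v_Bcl2m = y[22] > 0.0 ? y[22] : 0.0;
    const double v_Bcl2 = y[23] > 0.0 ? y[23] : 0.0;
    const double v_pPLB = y[24] > 0.0 ? y[24] : 0.0;
    const double v_pLCC = y[25] > 0.0 ? y[25] : 0.0;
    const double v_pRyR = y[26] > 0.0 ? y[26] : 0.0;
    const double v_pTnI = y[27] > 0.0 ? y[27] : 0.0;
    const double v_Cai = y[28] > 0.0 ? y[28] : 0.0;
    const double v_CaMCa = y[29] > 0.0 ? y[29] : 0.0;
    const double v_CaMKIIa = y[30] > 0.0 ? y[30] : 0.0;
    const double v_CNa = y[31] > 0.0 ? y[31] : 0.0;

    ydot[0] = + p[0] * p[105] * occ1 - p[0] * v_LRb1;  /* LRb1 */
    ydot[1] = + p[2] * p[106] * occ2 - p[2] * v_LRb2;  /* LRb2 */
    ydot[2] = + p[4] * v_LRb1 * (p[107]-v_Gsa) + p[5] * v_LRb2 * (p[107]-v_Gsa) - p[6] * v_Gsa;  /* Gsa */
    ydot[3] = + p[7] * v_LRb2 * hillf(v_PKAc,p[8],p[9]) * (p[108]-v_Gia) - p[10] * v_Gia;  /* Gia */
    ydot[4] = + p[11] * v_Gsa * inhf(v_Gia,p[12],1.0,1.0) * inhf(v_Cai,p[13],1.0,p[14]) * (p[109]-v_ACa) - p[15] * v_ACa;  /* ACa */
    ydot[5] = + p[16] + p[17] * v_ACa - p[18] * (v_cAMP/(p[19]+v_cAMP)) - p[20] * v_PDE3 * (v_cAMP/(p[19]+v_cAMP)) - p[21] * v_PDE3p * (v_cAMP/(p[19]+v_cAMP));  /* cAMP */
    ydot[6] = + p[22] * hillf(v_cAMP,p[23],p[24]) * (p[110]-v_PKAc) - p[25] * v_PKAc;  /* PKAc */
    ydot[7] = + p[26] * v_PKAc * (p[111]-v_pI1) - p[27] * v_pI1;  /* pI1 */
    ydot[8] = + p[29] * v_PKAc * (p[112]-v_pCREB) + p[30] * v_RSKa * (p[112]-v_pCREB) + p[31] * v_MSKa * (p[112]-v_pCREB) + p[32] * v_CaMKIIa * (p[112]-v_pCREB) - p[33] * p[128] * inhf(v_pI1,p[28],1.0,1.0) * v_pCREB - p[34] * v_CNa * v_pCREB;  /* pCREB */
    ydot[9] = + p[35] + p[36] * hillf(v_pCREB,p[37],p[38]) * inhf(v_ICER,p[39],1.0,1.0) - p[40] * v_ICERm;  /* ICERm */
    ydot[10] = + p[41] * v_ICERm - p[42] * v_ICER;  /* ICER */
    ydot[11] = + p[43] * inhf(v_ICER,p[44],p[45],p[46]) - p[47] * v_PDE3m;  /* PDE3m */
    ydot[12] = + p[48] * v_PDE3m - p[49] * v_PDE3;  /* PDE3 */
    ydot[13] = + p[50] * v_PKAc * (v_PDE3/(p[51]+v_PDE3)) - p[52] * v_PDE3p;  /* PDE3p */
    ydot[14] = + p[53] * (v_Gia/(p[54]+v_Gia)) * (p[113]-v_pShc) - p[55] * v_pShc;  /* pShc */
    ydot[15] = + p[56] * v_pShc * (p[114]-v_SOSGrb2) - p[57] * v_SOSGrb2;  /* SOSGrb2 */
    ydot[16] = + p[58] * v_SOSGrb2 * (p[115]-v_RasGTP) + p[59] * v_CaMKIIa * (p[115]-v_RasGTP) - p[60] * v_RasGTP;  /* RasGTP */
    ydot[17] = + p[61] * v_RasGTP * inhf(v_PKAc,p[62],1.0,p[63]) * (p[116]-v_Rafa) - p[64] * v_Rafa;  /* Rafa */
    ydot[18] = + p[65] * v_Rafa * (p[117]-v_pMEK) - p[66] * v_pMEK;  /* pMEK */
    ydot[19] = + p[67] * v_pMEK * (p[118]-v_pERK) - p[68] * v_pERK;  /* pERK */
    ydot[20] = + p[69] * v_pERK * (p[119]-v_RSKa) - p[70] * v_RSKa;  /* RSKa */
    ydot[21] = + p[71] * v_pERK * (p[120]-v_MSKa) - p[72] * v_MSKa;  /* MSKa */
    ydot[22] = + p[73] + p[74] * hillf(v_pCREB,p[75],p[76]) * inhf(v_ICER,p[77],p[78],p[79]) - p[80] * v_Bcl2m;  /* Bcl2m */
    ydot[23] = + p[81] * v_Bcl2m - p[82] * v_Bcl2;  /* Bcl2 */
    ydot[24] = + p[83] * v_PKAc * (p[121]-v_pPLB) - p[84] * p[128] * inhf(v_pI1,p[28],1.0,1.0) * v_pPLB;  /* pPLB */
    ydot[25] = + p[85] * v_PKAc * (p[122]-v_pLCC) - p[86] * v_pLCC;  /* pLCC */
    ydot[26] = + p[87] * v_PKAc * (p[123]-v_pRyR) - p[88] * v_pRyR;  /* pRyR */
    ydot[27] = + p[89] * v_PKAc * (p[124]-v_pTnI) - p[90] * v_pTnI;  /* pTnI */
    ydot[28] = + p[91] + p[92] * v_pLCC + p[92] * v_pRyR - p[93] * (v_Cai/(p[94]+v_Cai)) - p[95] * v_pPLB * (v_Cai/(p[94]+v_Cai)) - p[96] * v_Cai;  /* Cai */
    ydot[29] = + p[97] * hillf(v_Cai,p[98],p[99]) * (p[125]-v_CaMCa) - p[100] * v_CaMCa;  /* CaMCa */
    ydot[30] = + p[101] * v_CaMCa * (p[126]-v_CaMKIIa) - p[102] * v_CaMKIIa;  /* CaMKIIa */
    ydot[31] = + p[103] * v_CaMCa * (p[127]-v_CNa) - p[104] * v_CNa;  /* CNa */
    if (clamp_on > 0.5) ydot[5] = 0.0;
}

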