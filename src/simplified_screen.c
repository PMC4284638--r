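/* Steady-state screening engine for the simplified 5-node circuit model.
 *
 * Nodes: 0 PKA, 1 PDE, 2 ERK, 3 ICER, 4 Bcl2.
 * Links (mask bit order):
 *   0 S->PKA    1 S->ERK    2 PKA->ICER   3 ICER-|PDE
 *   4 PDE-|PKA  5 ICER-|Bcl2  6 ERK->Bcl2   7 PKA->Bcl2
 * Node ODE (non-dimensional): tau_x dx/dt = beta_x * A(x) * I(x) + b0_x - x
 * with A = product of Hill activation terms u^n/(K^n+u^n) over active
 * incoming activation links, I = product of Hill inhibition terms
 * Ki^n/(Ki^n+y^n) over active incoming inhibition links. Disconnected
 * activators are dropped; a node whose activators are all disconnected
 * falls back to basal production b0 alone; disconnected inhibitions
 * contribute a factor of 1. All simulations start from zero initial
 * conditions; b0_x = b0frac * beta_x.
 *
 * Parameter-set layout (26 doubles):
 *   tau[5] | beta[5] | K[8] (per link, Ki for inhibitory links) | n[8]
 *
 * Integration: adaptive Cash-Karp RK45 marched until steady state
 * (|beta*A*I + b0 - x| <= tol*(1+|x|) for every node) or t = 10*max(tau).
 */
#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <math.h>

#define NNODE 5
#define NLINK 8

typedef struct {
    double tau[NNODE], beta[NNODE], b0[NNODE], K[NLINK], n[NLINK];
    int on[NLINK];
    double S;
} sm_model;

static double hill_act(double u, double K, double n)
{
    double a, b;
    if (u <= 0.0) return 0.0;
    a = R_pow(u, n); b = R_pow(K, n);
    return a / (a + b);
}

static double hill_inh(double y, double K, double n)
{
    double a, b;
    if (y <= 0.0) return 1.0;
    a = R_pow(K, n); b = R_pow(y, n);
    return a / (a + b);
}

/* production term beta*A*I + b0 for each node */
static void sm_production(const sm_model *m, const double *x, double *prod)
{
    double PKA = x[0] > 0 ? x[0] : 0, PDE = x[1] > 0 ? x[1] : 0;
    double ERK = x[2] > 0 ? x[2] : 0, ICER = x[3] > 0 ? x[3] : 0;
    double a, inh;

    /* PKA: act S (link 0), inh PDE (link 4) */
    inh = m->on[4] ? hill_inh(PDE, m->K[4], m->n[4]) : 1.0;
    if (m->on[0])
        prod[0] = m->beta[0] * hill_act(m->S, m->K[0], m->n[0]) * inh + m->b0[0];
    else
        prod[0] = m->b0[0];

    /* PDE: constitutive, inh ICER (link 3) */
    inh = m->on[3] ? hill_inh(ICER, m->K[3], m->n[3]) : 1.0;
    prod[1] = m->beta[1] * inh + m->b0[1];

    /* ERK: act S (link 1) */
    if (m->on[1])
        prod[2] = m->beta[2] * hill_act(m->S, m->K[1], m->n[1]) + m->b0[2];
    else
        prod[2] = m->b0[2];

    /* ICER: act PKA (link 2) */
    if (m->on[2])
        prod[3] = m->beta[3] * hill_act(PKA, m->K[2], m->n[2]) + m->b0[3];
    else
        prod[3] = m->b0[3];

    /* Bcl2: act ERK (6) and/or PKA (7), inh ICER (5) */
    inh = m->on[5] ? hill_inh(ICER, m->K[5], m->n[5]) : 1.0;
    if (m->on[6] || m->on[7]) {
        a = 1.0;
        if (m->on[6]) a *= hill_act(ERK, m->K[6], m->n[6]);
        if (m->on[7]) a *= hill_act(PKA, m->K[7], m->n[7]);
        prod[4] = m->beta[4] * a * inh + m->b0[4];
    } else {
        prod[4] = m->b0[4];
    }
}

static void sm_rhs(const sm_model *m, const double *x, double *dx)
{
    double prod[NNODE];
    int i;
    sm_production(m, x, prod);
    for (i = 0; i < NNODE; i++)
        dx[i] = (prod[i] + 0.0 - x[i]) / m->tau[i];
}

/* Cash-Karp RK45 coefficients */
static const double ck_b[6][5] = {
    {0, 0, 0, 0, 0},
    {1.0/5, 0, 0, 0, 0},
    {3.0/40, 9.0/40, 0, 0, 0},
    {3.0/10, -9.0/10, 6.0/5, 0, 0},
    {-11.0/54, 5.0/2, -70.0/27, 35.0/27, 0},
    {1631.0/55296, 175.0/512, 575.0/13824, 44275.0/110592, 253.0/4096}
};
static const double ck_c[6]  = {37.0/378, 0, 250.0/621, 125.0/594,
                                0, 512.0/1771};
static const double ck_dc[6] = {37.0/378 - 2825.0/27648, 0,
                                250.0/621 - 18575.0/48384,
                                125.0/594 - 13525.0/55296,
                                -277.0/14336, 512.0/1771 - 0.25};

/* integrate from x to steady state; returns Bcl2 steady value */
static double sm_steady(const sm_model *m, double tol)
{
    double x[NNODE] = {0, 0, 0, 0, 0};
    double k[6][NNODE], xt[NNODE], xe[NNODE], prod[NNODE];
    double t = 0.0, tmax, h, taumin = m->tau[0], taumax = m->tau[0];
    int i, s, conv, iter = 0, maxiter = 200000;

    for (i = 1; i < NNODE; i++) {
        if (m->tau[i] < taumin) taumin = m->tau[i];
        if (m->tau[i] > taumax) taumax = m->tau[i];
    }
    tmax = 10.0 * taumax;
    h = taumin / 10.0;

    while (t < tmax && iter++ < maxiter) {
        double err, sc;
        if (t + h > tmax) h = tmax - t;
        sm_rhs(m, x, k[0]);
        for (s = 1; s < 6; s++) {
            int j;
            for (i = 0; i < NNODE; i++) {
                double acc = 0.0;
                for (j = 0; j < s; j++) acc += ck_b[s][j] * k[j][i];
                xt[i] = x[i] + h * acc;
            }
            sm_rhs(m, xt, k[s]);
        }
        err = 0.0;
        for (i = 0; i < NNODE; i++) {
            double acc = 0.0, eacc = 0.0;
            for (s = 0; s < 6; s++) {
                acc += ck_c[s] * k[s][i];
                eacc += ck_dc[s] * k[s][i];
            }
            xt[i] = x[i] + h * acc;
            xe[i] = h * eacc;
            sc = 1e-8 + 1e-6 * fabs(xt[i]);
            if (fabs(xe[i]) / sc > err) err = fabs(xe[i]) / sc;
        }
        if (err <= 1.0) {
            t += h;
            for (i = 0; i < NNODE; i++) x[i] = xt[i] > 0 ? xt[i] : 0;
            /* convergence: production balances state on every node */
            sm_production(m, x, prod);
            conv = 1;
            for (i = 0; i < NNODE; i++)
                if (fabs(prod[i] - x[i]) > tol * (1.0 + fabs(x[i]))) {
                    conv = 0; break;
                }
            if (conv) return x[4];
        }
        h *= err > 0 ? 0.9 * R_pow(err, -0.2) : 5.0;
        if (h > taumin * 5.0) h = taumin * 5.0;
        if (h < 1e-10) h = 1e-10;
    }
    return x[4]; /* best effort at tmax (slowly converging cell) */
}

/* masks: integer matrix n_masks x 8; params: numeric matrix n_sets x 26;
 * doses: numeric vector of S values (a basal S = 0 column is prepended).
 * Returns numeric matrix (n_masks * n_sets) x (1 + n_doses), cell index
 * row-major in (mask, set): row = (i_mask - 1) * n_sets + i_set.         */
SEXP C_simplified_screen(SEXP s_masks, SEXP s_params, SEXP s_doses,
                         SEXP s_b0frac, SEXP s_tol)
{
    SEXP dim_m = getAttrib(s_masks, R_DimSymbol);
    SEXP dim_p = getAttrib(s_params, R_DimSymbol);
    int n_masks = INTEGER(dim_m)[0], n_sets = INTEGER(dim_p)[0];
    int n_doses = LENGTH(s_doses);
    int *masks = INTEGER(s_masks);
    double *par = REAL(s_params), *doses = REAL(s_doses);
    double b0frac = asReal(s_b0frac), tol = asReal(s_tol);
    SEXP ans = PROTECT(allocMatrix(REALSXP, n_masks * n_sets, 1 + n_doses));
    double *out = REAL(ans);
    int im, is, id, i;
    long nrow = (long) n_masks * n_sets;

    for (im = 0; im < n_masks; im++) {
        sm_model m;
        for (i = 0; i < NLINK; i++) m.on[i] = masks[im + (long) i * n_masks];
        for (is = 0; is < n_sets; is++) {
            long row = (long) im * n_sets + is;
            for (i = 0; i < NNODE; i++) {
                m.tau[i] = par[is + (long) i * n_sets];
                m.beta[i] = par[is + (long) (5 + i) * n_sets];
                m.b0[i] = b0frac * m.beta[i];
            }
            for (i = 0; i < NLINK; i++) {
                m.K[i] = par[is + (long) (10 + i) * n_sets];
                m.n[i] = par[is + (long) (18 + i) * n_sets];
            }
            m.S = 0.0;
            out[row] = sm_steady(&m, tol);
            for (id = 0; id < n_doses; id++) {
                m.S = doses[id];
                out[row + (long) (1 + id) * nrow] = sm_steady(&m, tol);
            }
        }
        R_CheckUserInterrupt();
    }
    UNPROTECT(1);
    return ans;
}
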