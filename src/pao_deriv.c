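/* Right-hand side of the anaerobic-aerobic PAO metabolic model.
 *
 * States (concentrations, C-mmol/l or P-mmol/l; CO2 is a bookkeeping pool):
 *   0 S_O2   1 S_HAc  2 S_HPr  3 S_PO4  4 X_PAO
 *   5 X_PHB  6 X_PHV  7 X_PH2MV  8 X_Gly  9 X_PP  10 CO2
 *
 * All stoichiometric entries arrive pre-resolved for the row's temperature
 * and pH (see resolve_parameters() on the R side), so this routine is a pure
 * function of the state and the 45-entry parameter vector.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 45
#define N_STATE 11

/* parameter vector layout (kept in step with .parm_layout in R/model.R) */
#define P_PHASE      0   /* 1 anaerobic, 2 aerobic */
#define P_VFA_GATE   1
#define P_QHAC       2
#define P_QHPR       3
#define P_MAN        4
#define P_QPHA       5
#define P_QGLY       6
#define P_QPP        7
#define P_MOX        8
#define P_KHAC       9
#define P_KHPR      10
#define P_KPO4      11
#define P_KPHA      12
#define P_KGLY      13
#define P_KFPHA     14
#define P_KPP       15
#define P_KO2       16
#define P_FGLYMAX   17
#define P_FPPMAX    18
#define P_YGLY_AC   19
#define P_YPHA_AC   20
#define P_CO2_AC    21
#define P_SPLIT_AC  22  /* 22,23,24: PHB, PHV, PH2MV */
#define P_YGLY_PR   25
#define P_YPHA_PR   26
#define P_CO2_PR    27
#define P_SPLIT_PR  28  /* 28,29,30 */
#define P_PREL_AC   31
#define P_PREL_PR   32
#define P_ATP_PHA   33
#define P_ATP_GLY   34
#define P_GLYATP_AN 35
#define P_ANM_GLYPHA 36
#define P_YPHA_GLY  37
#define P_EPS       38
#define P_K1        39
#define P_K2        40
#define P_KLA       41
#define P_O2SAT     42
#define P_O2CO2     43
#define P_KSW       44

static double parms[N_PARMS];

void pao_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double pos(double x) { return x > 0.0 ? x : 0.0; }
static double sat(double x, double k) { return x / (x + k); }

static void pao_rhs(const double *p, const double *y, double *dy)
{
    double so2  = pos(y[0]), shac = pos(y[1]), shpr = pos(y[2]);
    double spo4 = pos(y[3]), xpao = pos(y[4]);
    double xphb = pos(y[5]), xphv = pos(y[6]), xp2m = pos(y[7]);
    double xgly = pos(y[8]), xpp  = pos(y[9]);
    int i;
    int anaerobic = p[P_PHASE] < 1.5;
    int vfa_on = anaerobic || p[P_VFA_GATE] > 0.5;
    double ksw = p[P_KSW];

    for (i = 0; i < N_STATE; i++) dy[i] = 0.0;
    if (xpao <= 0.0) {
        if (!anaerobic)
            dy[0] = p[P_KLA] * (p[P_O2SAT] - so2);
        return;
    }

    double fgly = xgly / xpao;
    double fpp  = xpp / xpao;
    double pha  = xphb + xphv + xp2m;
    double fpha = pha / xpao;

    /* --- anaerobic VFA uptake (also aerobic when the gate is open) --- */
    if (vfa_on) {
        double gate_o2 = anaerobic ? 1.0 : sat(so2, p[P_KO2]);
        double avail = sat(fgly, p[P_KGLY]) * sat(fpp, p[P_KPP]);
        double r_ac = p[P_QHAC] * sat(shac, p[P_KHAC]) * avail * xpao * gate_o2;
        double r_pr = p[P_QHPR] * sat(shpr, p[P_KHPR]) * avail * xpao * gate_o2;
        dy[1] -= r_ac;
        dy[2] -= r_pr;
        dy[8] -= p[P_YGLY_AC] * r_ac + p[P_YGLY_PR] * r_pr;
        dy[5] += p[P_YPHA_AC] * p[P_SPLIT_AC]     * r_ac
               + p[P_YPHA_PR] * p[P_SPLIT_PR]     * r_pr;
        dy[6] += p[P_YPHA_AC] * p[P_SPLIT_AC + 1] * r_ac
               + p[P_YPHA_PR] * p[P_SPLIT_PR + 1] * r_pr;
        dy[7] += p[P_YPHA_AC] * p[P_SPLIT_AC + 2] * r_ac
               + p[P_YPHA_PR] * p[P_SPLIT_PR + 2] * r_pr;
        double prel = p[P_PREL_AC] * r_ac + p[P_PREL_PR] * r_pr;
        dy[3] += prel;
        dy[9] -= prel;
        dy[10] += p[P_CO2_AC] * r_ac + p[P_CO2_PR] * r_pr;
    }

    if (anaerobic) {
        /* sequential maintenance: poly-P first, then glycolysis to PHB */
        double a_pp = sat(xpp, ksw);
        double a_gly = sat(xgly, ksw);
        double m_pp = p[P_MAN] * xpao * a_pp;              /* ATP = P-mol */
        double m_gly_atp = p[P_MAN] * xpao * (1.0 - a_pp) * a_gly;
        double g = m_gly_atp / p[P_GLYATP_AN];             /* C-mol Gly */
        dy[3] += m_pp;
        dy[9] -= m_pp;
        dy[8] -= g;
        dy[5] += p[P_ANM_GLYPHA] * g;
        dy[10] += (1.0 - p[P_ANM_GLYPHA]) * g;
        /* no O2 dynamics, no growth anaerobically */
        return;
    }

    /* --- aerobic phase --- */
    double mo2 = sat(so2, p[P_KO2]);
    double r_deg = p[P_QPHA] * sat(fpha, p[P_KFPHA]) * mo2 * xpao;
    double inh_gly = pos(1.0 - fgly / p[P_FGLYMAX]);
    double r_gly = p[P_QGLY] * sat(fpha, p[P_KPHA]) * inh_gly * mo2 * xpao;
    double inh_pp = pos(1.0 - fpp / p[P_FPPMAX]);
    double r_pp = p[P_QPP] * sat(spo4, p[P_KPO4]) * sat(fpha, p[P_KPHA])
                * inh_pp * mo2 * xpao;

    /* sequential aerobic maintenance: PHA, then glycogen, then poly-P */
    double a1 = sat(pha, ksw);
    double a2 = sat(xgly, ksw);
    double a3 = sat(xpp, ksw);
    double m_atp = p[P_MOX] * xpao * mo2;
    double m_pha_atp = m_atp * a1;
    double m_gly_atp = m_atp * (1.0 - a1) * a2;
    double m_pp_atp  = m_atp * (1.0 - a1) * (1.0 - a2) * a3;

    double pha_gly = p[P_YPHA_GLY] * r_gly;
    double pha_pp  = p[P_EPS] / p[P_ATP_PHA] * r_pp;
    double pha_mnt = m_pha_atp / p[P_ATP_PHA];
    double gly_mnt = m_gly_atp / p[P_ATP_GLY];
    double pp_mnt  = m_pp_atp;                    /* 1 ATP per P-mol */

    /* growth on the PHA-degradation surplus */
    double r_gx = r_deg - pha_gly - pha_pp - pha_mnt;
    if (r_gx < 0.0) r_gx = 0.0;
    double k_eff = pha > 0.0
        ? (p[P_K1] * xphb + p[P_K2] * (xphv + xp2m)) / pha
        : p[P_K1];
    double y_gx = 1.0 / (1.0 + k_eff / p[P_ATP_PHA]);

    double cons = pha_gly + pha_pp + pha_mnt + r_gx;  /* total PHA sink */
    double xb = pha > 0.0 ? xphb / pha : 0.0;
    double xv = pha > 0.0 ? xphv / pha : 0.0;
    double xm = pha > 0.0 ? xp2m / pha : 0.0;

    double co2 = (1.0 - y_gx) * r_gx
               + (p[P_YPHA_GLY] - 1.0) * r_gly
               + pha_pp + pha_mnt + gly_mnt;

    dy[4] += y_gx * r_gx;
    dy[5] -= cons * xb;
    dy[6] -= cons * xv;
    dy[7] -= cons * xm;
    dy[8] += r_gly - gly_mnt;
    dy[9] += r_pp - pp_mnt;
    dy[3] += pp_mnt - r_pp;
    dy[10] += co2;
    dy[0] += p[P_KLA] * (p[P_O2SAT] - so2) - p[P_O2CO2] * co2;
}

/* deSolve entry point */
void pao_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    pao_rhs(parms, y, ydot);
}

/* direct evaluation for tests: derivative at (state, parameter vector) */
SEXP pao_eval_deriv(SEXP state, SEXP pvec)
{
    if (LENGTH(state) != N_STATE) error("state must have %d entries", N_STATE);
    if (LENGTH(pvec) != N_PARMS) error("parms must have %d entries", N_PARMS);
    SEXP out = PROTECT(allocVector(REALSXP, N_STATE));
    pao_rhs(REAL(pvec), REAL(state), REAL(out));
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"pao_eval_deriv", (DL_FUNC) &pao_eval_deriv, 2},
    {NULL, NULL, 0}
};

void R_init_paosens(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);  /* deSolve looks pao_derivs up by name */
}
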