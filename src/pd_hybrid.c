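/* Fast path: 5-state myelosuppression RHS with the 6-TGN level evaluated
 * analytically.  The PK cascade gut -> central -> 6-TGN is linear with
 * distinct first-order rates, so its response to impulse gut boluses is a
 * sum of three exponentials (Bateman cascade).  The slow clearance mode is
 * accumulated with prefix sums over doses; the two fast modes (k_a, k_20)
 * are summed explicitly over the few recent doses that still contribute
 * (terms below exp(-45) dropped).
 *
 * Dose data and PK rates are installed per simulation via mtanc_set_doses()
 * before the lsoda call; not thread-safe, matching deSolve usage.
 */
#include <R.h>
#include <math.h>

static int    nd = 0;           /* number of gut boluses              */
static double *dt_ = NULL;      /* bolus times (sorted ascending)     */
static double *db_ = NULL;      /* bolus gut amounts (already x F)    */
static double *Ss_ = NULL;      /* prefix sums of db * exp(cl * dt)   */
static double ka_, k20_, cl_, a3_;   /* a3 = FM3 * k_me                */
static double c0_, tgn0_, t00_;      /* initial central/6-TGN at t00_  */

void mtanc_set_doses(int *n, double *t, double *b,
                     double *rates, double *init)
{
    int i;
    if (dt_) { R_Free(dt_); R_Free(db_); R_Free(Ss_); dt_ = db_ = Ss_ = NULL; }
    nd = *n;
    ka_ = rates[0]; k20_ = rates[1]; cl_ = rates[2]; a3_ = rates[3];
    c0_ = init[0]; tgn0_ = init[1]; t00_ = init[2];
    if (nd > 0) {
        dt_ = R_Calloc(nd, double);
        db_ = R_Calloc(nd, double);
        Ss_ = R_Calloc(nd, double);
        for (i = 0; i < nd; i++) { dt_[i] = t[i]; db_[i] = b[i]; }
        Ss_[0] = db_[0] * exp(cl_ * dt_[0]);
        for (i = 1; i < nd; i++)
            Ss_[i] = Ss_[i - 1] + db_[i] * exp(cl_ * dt_[i]);
    }
}

/* analytic x_6tgn(t) */
static double tgn_at(double t)
{
    double val, d0 = t - t00_;
    int lo, hi, idx, j;

    /* initial-condition terms */
    val = tgn0_ * exp(-cl_ * d0);
    if (c0_ != 0.0)
        val += c0_ * a3_ * (exp(-k20_ * d0) - exp(-cl_ * d0)) / (cl_ - k20_);

    if (nd > 0 && t >= dt_[0]) {
        /* last bolus with time <= t */
        lo = 0; hi = nd - 1;
        while (lo < hi) {
            int mid = (lo + hi + 1) / 2;
            if (dt_[mid] <= t) lo = mid; else hi = mid - 1;
        }
        idx = lo;
        /* slow clearance mode, all boluses up to idx via prefix sum */
        val += a3_ * ka_ / ((ka_ - cl_) * (k20_ - cl_)) *
               exp(-cl_ * t) * Ss_[idx];
        /* fast modes: only recent boluses matter */
        for (j = idx; j >= 0; j--) {
            double d = t - dt_[j];
            if (k20_ * d > 45.0) break;
            val += a3_ * ka_ * db_[j] *
                   (exp(-ka_ * d) / ((k20_ - ka_) * (cl_ - ka_)) +
                    exp(-k20_ * d) / ((ka_ - k20_) * (cl_ - k20_)));
        }
    }
    return val > 0.0 ? val : 0.0;
}

static double pdparms[5];
#define P_KTR   pdparms[0]
#define P_GAMMA pdparms[1]
#define P_SLOPE pdparms[2]
#define P_BASE  pdparms[3]
#define P_KMA   pdparms[4]

void mtanc_pd_initparms(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, pdparms);
}

static int pd_rhs(double t, const double *y, double *ydot)
{
    double xpr = y[0], xtr1 = y[1], xtr2 = y[2], xtr3 = y[3], xma = y[4];
    double edrug, fb;

    if (xma <= 0.0) return 1;
    edrug = P_SLOPE * tgn_at(t);
    fb = pow(P_BASE / xma, P_GAMMA);
    ydot[0] = P_KTR * xpr * ((1.0 - edrug) * fb - 1.0);
    ydot[1] = P_KTR * (xpr - xtr1);
    ydot[2] = P_KTR * (xtr1 - xtr2);
    ydot[3] = P_KTR * (xtr2 - xtr3);
    ydot[4] = P_KTR * xtr3 - P_KMA * xma;
    return 0;
}

void mtanc_pd_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    int i;
    if (pd_rhs(*t, y, ydot))
        for (i = 0; i < 5; i++) ydot[i] = R_NaN;
}

/* Classical RK4 over a breakpoint grid.  Breakpoints contain all dose and
 * output times, so the RHS is smooth within every step.  `pos` marks
 * (1-based) breakpoints at which the state is written to `yout` (5 x nout,
 * column-major).  status: 0 ok, 1 state left the admissible region. */
void mtanc_pd_rk4(double *parms5, int *nbrk, double *brk, double *hmax,
                  int *nout, int *pos, double *y0, double *yout, int *status)
{
    double y[5], k1[5], k2[5], k3[5], k4[5], ytmp[5];
    int i, j, m, s, iout = 0;

    for (j = 0; j < 5; j++) { pdparms[j] = parms5[j]; y[j] = y0[j]; }
    *status = 0;

    if (iout < *nout && pos[iout] == 1) {
        for (j = 0; j < 5; j++) yout[5 * iout + j] = y[j];
        iout++;
    }
    for (i = 0; i < *nbrk - 1; i++) {
        double len = brk[i + 1] - brk[i];
        int nsub = (int) ceil(len / *hmax);
        double h = len / nsub;
        for (s = 0; s < nsub; s++) {
            double t = brk[i] + s * h;
            if (pd_rhs(t, y, k1)) { *status = 1; return; }
            for (j = 0; j < 5; j++) ytmp[j] = y[j] + 0.5 * h * k1[j];
            if (pd_rhs(t + 0.5 * h, ytmp, k2)) { *status = 1; return; }
            for (j = 0; j < 5; j++) ytmp[j] = y[j] + 0.5 * h * k2[j];
            if (pd_rhs(t + 0.5 * h, ytmp, k3)) { *status = 1; return; }
            for (j = 0; j < 5; j++) ytmp[j] = y[j] + h * k3[j];
            if (pd_rhs(t + h, ytmp, k4)) { *status = 1; return; }
            for (j = 0; j < 5; j++) {
                y[j] += h / 6.0 *
                        (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
                if (!R_FINITE(y[j])) { *status = 1; return; }
            }
            if (y[4] <= 0.0) { *status = 1; return; }
        }
        if (iout < *nout && pos[iout] == i + 2) {
            for (j = 0; j < 5; j++) yout[5 * iout + j] = y[j];
            iout++;
        }
    }
}

/* RK4 over the same breakpoint grid integrating the 5 PD states together
 * with forward sensitivities of all states to the four individual
 * parameters p = (Base, k_tr, gamma, slope).  Output per marked
 * breakpoint: x_ma and d x_ma / d p (5 doubles).  y layout: x[0..4],
 * then S[, Base], S[, k_tr], S[, gamma], S[, slope] (5 each; 25 total).
 */
static int pd_rhs_sens(double t, const double *y, double *ydot)
{
    double x1 = y[0], x2 = y[1], x3 = y[2], x4 = y[3], x5 = y[4];
    double tgn, E, fb, lnB, A, d11, d15, g1[4];
    int k;

    if (x5 <= 0.0) return 1;
    tgn = tgn_at(t);
    E = P_SLOPE * tgn;
    fb = pow(P_BASE / x5, P_GAMMA);
    lnB = log(P_BASE / x5);
    A = (1.0 - E) * fb;

    ydot[0] = P_KTR * x1 * (A - 1.0);
    ydot[1] = P_KTR * (x1 - x2);
    ydot[2] = P_KTR * (x2 - x3);
    ydot[3] = P_KTR * (x3 - x4);
    ydot[4] = P_KTR * x4 - P_KMA * x5;

    d11 = P_KTR * (A - 1.0);
    d15 = -P_KTR * x1 * (1.0 - E) * fb * P_GAMMA / x5;
    g1[0] = P_KTR * x1 * (1.0 - E) * fb * P_GAMMA / P_BASE;
    g1[1] = x1 * (A - 1.0);
    g1[2] = P_KTR * x1 * (1.0 - E) * fb * lnB;
    g1[3] = -P_KTR * x1 * tgn * fb;

    for (k = 0; k < 4; k++) {
        const double *S = y + 5 + 5 * k;
        double *Sd = ydot + 5 + 5 * k;
        Sd[0] = d11 * S[0] + d15 * S[4] + g1[k];
        Sd[1] = P_KTR * (S[0] - S[1]);
        Sd[2] = P_KTR * (S[1] - S[2]);
        Sd[3] = P_KTR * (S[2] - S[3]);
        Sd[4] = P_KTR * S[3] - P_KMA * S[4];
        if (k == 1) {                    /* direct k_tr dependence */
            Sd[1] += x1 - x2;
            Sd[2] += x2 - x3;
            Sd[3] += x3 - x4;
            Sd[4] += x4;
        }
    }
    return 0;
}

void mtanc_pd_rk4_sens(double *parms5, int *nbrk, double *brk, double *hmax,
                       int *nout, int *pos, double *yout, int *status)
{
    double y[25], k1[25], k2[25], k3[25], k4[25], ytmp[25];
    double Base, ktr, kma, a;
    int i, j, m, s, iout = 0;

    for (j = 0; j < 5; j++) pdparms[j] = parms5[j];
    ktr = parms5[0]; Base = parms5[3]; kma = parms5[4];
    a = Base * kma / ktr;

    for (j = 0; j < 25; j++) y[j] = 0.0;
    y[0] = y[1] = y[2] = y[3] = a; y[4] = Base;
    /* d x0 / d Base */
    y[5] = y[6] = y[7] = y[8] = a / Base; y[9] = 1.0;
    /* d x0 / d k_tr */
    y[10] = y[11] = y[12] = y[13] = -a / ktr;

    *status = 0;
    if (iout < *nout && pos[iout] == 1) {
        yout[5 * iout] = y[4];
        for (j = 0; j < 4; j++) yout[5 * iout + 1 + j] = y[9 + 5 * j];
        iout++;
    }
    for (i = 0; i < *nbrk - 1; i++) {
        double len = brk[i + 1] - brk[i];
        int nsub = (int) ceil(len / *hmax);
        double h = len / nsub;
        for (s = 0; s < nsub; s++) {
            double t = brk[i] + s * h;
            if (pd_rhs_sens(t, y, k1)) { *status = 1; return; }
            for (j = 0; j < 25; j++) ytmp[j] = y[j] + 0.5 * h * k1[j];
            if (pd_rhs_sens(t + 0.5 * h, ytmp, k2)) { *status = 1; return; }
            for (j = 0; j < 25; j++) ytmp[j] = y[j] + 0.5 * h * k2[j];
            if (pd_rhs_sens(t + 0.5 * h, ytmp, k3)) { *status = 1; return; }
            for (j = 0; j < 25; j++) ytmp[j] = y[j] + h * k3[j];
            if (pd_rhs_sens(t + h, ytmp, k4)) { *status = 1; return; }
            for (j = 0; j < 25; j++) {
                y[j] += h / 6.0 *
                        (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
                if (!R_FINITE(y[j])) { *status = 1; return; }
            }
            if (y[4] <= 0.0) { *status = 1; return; }
        }
        if (iout < *nout && pos[iout] == i + 2) {
            yout[5 * iout] = y[4];
            for (j = 0; j < 4; j++) yout[5 * iout + 1 + j] = y[9 + 5 * j];
            iout++;
        }
    }
}
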