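/* Double central-peripheral TMDD model with QSS approximation.
 *
 * States (nM): y[0] = CT  total drug, central
 *              y[1] = RTC total target, central
 *              y[2] = CPT total drug, peripheral (k12/k21 concentration convention)
 *              y[3] = RTP total target, peripheral
 *
 * Parameters (length 11, one column per parameter set in batch mode):
 *   CL, V1, Q, V2, R0C, KSSC, kintC, R0P, KSSP, kintP, kout
 *
 * Infusions enter as zero-order input In(t) = rate_mg_day * 1e6 / (MW * V1)
 * in nM/day. Integration restarts at every infusion start/stop and at every
 * requested output time, so dose boundaries are hard.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

typedef struct {
    double CL, V1, Q, V2, R0C, KSSC, kintC, R0P, KSSP, kintP, kout;
    double kinC, kinP;
    double inrate; /* nM/day, current segment */
} tmdd_par;

/* Non-negative root of C^2 + (RT + KSS - CT) C - KSS CT = 0, cancellation-safe. */
static double qss_root(double ct, double rt, double kss)
{
    double b, s, c;
    if (ct <= 0.0) return 0.0;
    if (rt <= 0.0 || kss <= 0.0) return ct;
    b = ct - rt - kss;
    s = sqrt(b * b + 4.0 * kss * ct);
    c = (b >= 0.0) ? 0.5 * (b + s) : (2.0 * kss * ct) / (s - b);
    if (c < 0.0) c = 0.0;
    if (c > ct) c = ct;
    return c;
}

static void tmdd_rhs(const double *y, const tmdd_par *p, double *dy)
{
    double C  = qss_root(y[0], y[1], p->KSSC);
    double CP = qss_root(y[2], y[3], p->KSSP);
    double cplxC = y[0] - C;
    double cplxP = y[2] - CP;

    dy[0] = p->inrate - (p->CL / p->V1) * C - (p->Q / p->V1) * C
            + (p->Q / p->V2) * CP - p->kintC * cplxC;
    dy[1] = p->kinC - p->kout * (y[1] - cplxC) - p->kintC * cplxC;
    dy[2] = (p->Q / p->V1) * C - (p->Q / p->V2) * CP - p->kintP * cplxP;
    dy[3] = p->kinP - p->kout * (y[3] - cplxP) - p->kintP * cplxP;
}

/* Dormand-Prince 5(4) coefficients */
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
static const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
                    A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
static const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
                    A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
                    A65 = -5103.0 / 18656.0;
static const double A71 = 35.0 / 384.0, A73 = 500.0 / 1113.0,
                    A74 = 125.0 / 192.0, A75 = -2187.0 / 6784.0,
                    A76 = 11.0 / 84.0;
static const double E1 = 71.0 / 57600.0, E3 = -71.0 / 16695.0,
                    E4 = 71.0 / 1920.0, E5 = -17253.0 / 339200.0,
                    E6 = 22.0 / 525.0, E7 = -1.0 / 40.0;

#define NSTATE 4

/* Integrate y over [t0, t1] with constant infusion rate; adaptive steps.
 * Returns 0 on success, 1 on failure (step underflow / step budget),
 * with *tfail the last successful time. h_io carries the step size across
 * segments. */
static int rk45_segment(double *y, double t0, double t1, const tmdd_par *p,
                        double rtol, double atol, double *h_io,
                        long *nstep, long maxstep, double *tfail)
{
    double t = t0, h = *h_io;
    double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
           k6[NSTATE], k7[NSTATE], yt[NSTATE], ynew[NSTATE];
    int i, have_k1 = 0;

    if (t1 <= t0) return 0;
    if (h <= 0.0 || h > (t1 - t0)) h = t1 - t0;

    while (t < t1) {
        double errn, sc, e;
        if (h > t1 - t) h = t1 - t;
        if (h < 1e-12 * (1.0 + fabs(t))) { *tfail = t; return 1; }
        if ((*nstep)++ > maxstep) { *tfail = t; return 1; }

        if (!have_k1) { tmdd_rhs(y, p, k1); have_k1 = 1; }

        for (i = 0; i < NSTATE; i++) yt[i] = y[i] + h * A21 * k1[i];
        tmdd_rhs(yt, p, k2);
        for (i = 0; i < NSTATE; i++)
            yt[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
        tmdd_rhs(yt, p, k3);
        for (i = 0; i < NSTATE; i++)
            yt[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
        tmdd_rhs(yt, p, k4);
        for (i = 0; i < NSTATE; i++)
            yt[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i]
                                + A54 * k4[i]);
        tmdd_rhs(yt, p, k5);
        for (i = 0; i < NSTATE; i++)
            yt[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i]
                                + A64 * k4[i] + A65 * k5[i]);
        tmdd_rhs(yt, p, k6);
        for (i = 0; i < NSTATE; i++)
            ynew[i] = y[i] + h * (A71 * k1[i] + A73 * k3[i] + A74 * k4[i]
                                  + A75 * k5[i] + A76 * k6[i]);
        tmdd_rhs(ynew, p, k7);

        errn = 0.0;
        for (i = 0; i < NSTATE; i++) {
            e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i]
                     + E6 * k6[i] + E7 * k7[i]);
            sc = atol + rtol * fmax(fabs(y[i]), fabs(ynew[i]));
            errn += (e / sc) * (e / sc);
        }
        errn = sqrt(errn / NSTATE);

        if (errn <= 1.0) {
            t += h;
            for (i = 0; i < NSTATE; i++) {
                y[i] = ynew[i];
                if (y[i] < 0.0 && y[i] > -atol * 100.0) y[i] = 0.0;
                k1[i] = k7[i]; /* FSAL */
            }
            have_k1 = 1;
            h *= fmin(5.0, fmax(0.2, 0.9 * pow(fmax(errn, 1e-10), -0.2)));
        } else {
            h *= fmax(0.2, 0.9 * pow(errn, -0.2));
            have_k1 = 1; /* k1 unchanged at current y */
        }
    }
    *h_io = h;
    return 0;
}

static double seg_inrate(const double *dstart, const double *ddur,
                         const double *drate, int ndose, double tmid,
                         double conv)
{
    double r = 0.0;
    int k;
    for (k = 0; k < ndose; k++)
        if (tmid >= dstart[k] && tmid < dstart[k] + ddur[k])
            r += drate[k] * conv;
    return r;
}

/* Entry point.
 *  spars:  11 x M matrix of parameter sets
 *  sdoses: ndose x 3 matrix (start day, duration day, rate mg/day)
 *  stimes: strictly increasing output times, >= 0
 *  smw:    molar mass g/mol
 *  sctrl:  c(rtol, atol, maxstep)
 *  sfull:  0 -> nt x M matrix of unbound central conc (nM)
 *          1 -> nt x 4 x M array of states
 */
SEXP C_tmdd_solve(SEXP spars, SEXP sdoses, SEXP stimes, SEXP smw, SEXP sctrl,
                  SEXP sfull)
{
    const double *pars = REAL(spars);
    int M = Rf_ncols(spars);
    const double *doses = REAL(sdoses);
    int ndose = Rf_nrows(sdoses);
    const double *times = REAL(stimes);
    int nt = LENGTH(stimes);
    double mw = Rf_asReal(smw);
    const double *ctrl = REAL(sctrl);
    double rtol = ctrl[0], atol = ctrl[1];
    long maxstep = (long) ctrl[2];
    int full = Rf_asInteger(sfull);
    const double *dstart = doses, *ddur = doses + ndose,
                 *drate = doses + 2 * ndose;

    /* checkpoints: 0, dose boundaries, output times (sorted, unique) */
    int ncp_max = 1 + 2 * ndose + nt, ncp = 0, i, k, m;
    double *cp = (double *) R_alloc(ncp_max, sizeof(double));
    cp[ncp++] = 0.0;
    for (k = 0; k < ndose; k++) {
        cp[ncp++] = dstart[k];
        cp[ncp++] = dstart[k] + ddur[k];
    }
    for (i = 0; i < nt; i++) cp[ncp++] = times[i];
    /* insertion sort (small n) + unique */
    for (i = 1; i < ncp; i++) {
        double v = cp[i];
        int j = i - 1;
        while (j >= 0 && cp[j] > v) { cp[j + 1] = cp[j]; j--; }
        cp[j + 1] = v;
    }
    {
        int u = 0;
        for (i = 0; i < ncp; i++)
            if (i == 0 || cp[i] > cp[u - 1] + 1e-12) cp[u++] = cp[i];
        ncp = u;
    }

    SEXP out;
    if (full) {
        out = PROTECT(Rf_alloc3DArray(REALSXP, nt, NSTATE, M));
    } else {
        out = PROTECT(Rf_allocMatrix(REALSXP, nt, M));
    }
    double *res = REAL(out);

    for (m = 0; m < M; m++) {
        tmdd_par p;
        const double *pm = pars + 11 * m;
        double y[NSTATE], h = 0.0, tfail = 0.0, conv;
        long nstep = 0;
        int iout = 0;

        p.CL = pm[0]; p.V1 = pm[1]; p.Q = pm[2]; p.V2 = pm[3];
        p.R0C = pm[4]; p.KSSC = pm[5]; p.kintC = pm[6];
        p.R0P = pm[7]; p.KSSP = pm[8]; p.kintP = pm[9];
        p.kout = pm[10];
        if (p.V1 <= 0.0 || p.V2 <= 0.0)
            Rf_error("volumes must be strictly positive");
        p.kinC = p.R0C * p.kout;
        p.kinP = p.R0P * p.kout;
        conv = 1e6 / (mw * p.V1); /* mg/day -> nM/day in V1 */

        y[0] = 0.0; y[1] = p.R0C; y[2] = 0.0; y[3] = p.R0P;

        /* output times at t = 0 (state before any infusion contribution) */
        while (iout < nt && times[iout] <= 1e-12) {
            if (full)
                for (i = 0; i < NSTATE; i++)
                    res[iout + nt * i + nt * NSTATE * m] = y[i];
            else
                res[iout + nt * m] = qss_root(y[0], y[1], p.KSSC);
            iout++;
        }

        for (k = 0; k + 1 < ncp; k++) {
            double t0 = cp[k], t1 = cp[k + 1];
            p.inrate = seg_inrate(dstart, ddur, drate, ndose,
                                  0.5 * (t0 + t1), conv);
            if (rk45_segment(y, t0, t1, &p, rtol, atol, &h, &nstep,
                             maxstep, &tfail))
                Rf_error("ODE integration failed at t = %g day (parameter set %d)",
                         tfail, m + 1);
            while (iout < nt && times[iout] <= t1 + 1e-12) {
                if (full)
                    for (i = 0; i < NSTATE; i++)
                        res[iout + nt * i + nt * NSTATE * m] = y[i];
                else
                    res[iout + nt * m] = qss_root(y[0], y[1], p.KSSC);
                iout++;
            }
        }
        if (iout < nt)
            Rf_error("output times extend beyond integration horizon");
    }

    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_tmdd_solve", (DL_FUNC) &C_tmdd_solve, 6},
    {NULL, NULL, 0}
};

void R_init_dtmdd(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
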