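/* Fast C path for Bayesian fitting: a Dormand-Prince 4(5) integrator over
 * the fermentation right-hand side, residual evaluation against observed
 * series, and the tempered differential-evolution Metropolis sampler with
 * slice-updated noise sd. The R-level deSolve route stays the reference
 * implementation; both are cross-checked in the test suite.
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <string.h>

#define NSTATE 8

/* shared with ferm_rhs.c convention: 43 parameters + 5 mechanism flags */
static void rhs_core(const double *p, const double *y, double *ydot)
{
    double Glc = y[0] > 0 ? y[0] : 0, Fru = y[1] > 0 ? y[1] : 0;
    double EtOH = y[2] > 0 ? y[2] : 0, LA = y[3] > 0 ? y[3] : 0;
    double Ac = y[4] > 0 ? y[4] : 0, Y = y[5] > 0 ? y[5] : 0;
    double LAB = y[6] > 0 ? y[6] : 0, AAB = y[7] > 0 ? y[7] : 0;
    double m1 = p[43], m2 = p[44], m3 = p[45], m4 = p[46], m5 = p[47];

    double v1  = (Glc > 0 && Y > 0)    ? p[0] * Glc / (Glc + p[8]) * Y : 0;
    double v2  = (Fru > 0 && Y > 0)    ? p[1] * Fru / (Fru + p[9]) * Y : 0;
    double v3  = (Glc > 0 && LAB > 0)  ? p[3] * Glc / (Glc + p[11]) * LAB : 0;
    double v4  = (EtOH > 0 && AAB > 0) ? p[5] * EtOH / (EtOH + p[13]) * AAB : 0;
    double v5  = (LA > 0 && AAB > 0)   ? p[6] * LA / (LA + p[14] * AAB) * AAB : 0;
    double v6  = p[16] * Y * EtOH;
    double v7  = p[17] * LAB * LA;
    double v8  = p[18] * AAB * Ac * Ac;
    double v9  = (m2 > 0 && Fru > 0 && LAB > 0) ? m2 * p[4] * Fru / (Fru + p[12]) * LAB : 0;
    double v10 = (m4 > 0 && LA > 0 && Y > 0)    ? m4 * p[2] * LA / (LA + p[10]) * Y : 0;
    double v11 = (m5 > 0 && Ac > 0 && AAB > 0)  ? m5 * p[7] * Ac / (Ac + p[15]) * AAB : 0;
    double d1  = m1 * p[40] * EtOH;
    double d2  = m1 * p[41] * LA;
    double d3  = m1 * p[42] * Ac;

    ydot[0] = -p[19] * v1 - p[20] * v3;
    ydot[1] = -p[21] * v2 - m2 * p[22] * v9;
    ydot[2] = p[23] * v1 + p[24] * v2 - p[28] * v4
              + m2 * (p[26] * v3 + p[27] * v9) + m4 * p[25] * v10 - d1;
    ydot[3] = p[29] * v3 - p[31] * v5 + m2 * p[30] * v9 - m4 * p[32] * v10 - d2;
    ydot[4] = p[33] * v3 + p[35] * v4 + p[36] * v5 + m2 * p[34] * v9
              + m3 * (p[37] * v1 + p[38] * v2) - m5 * p[39] * v11 - d3;
    ydot[5] = v1 + v2 - v6 + m4 * v10;
    ydot[6] = v3 - v7 + m2 * v9;
    ydot[7] = v4 + v5 - v8 + m5 * v11;
}

/* Dormand-Prince 4(5) coefficients */
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100,
                    e7 = -1.0 / 40;

/* Integrate y in place from t0 to t1. Returns number of steps used, or -1
 * on failure (step limit, non-finite state, step underflow). *steps_left
 * is the remaining global step budget. */
static int dp45_segment(const double *p, double *y, double t0, double t1,
                        double rtol, double atol, int *steps_left,
                        double *hguess)
{
    double t = t0, h = *hguess;
    double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
           k6[NSTATE], k7[NSTATE], yt[NSTATE], y5[NSTATE];
    if (h <= 0 || h > t1 - t0) h = t1 - t0;
    rhs_core(p, y, k1);
    while (t < t1 - 1e-12) {
        if (*steps_left <= 0) return -1;
        if (h > t1 - t) h = t1 - t;
        if (h < 1e-12) return -1;
        int j;
        for (j = 0; j < NSTATE; j++) yt[j] = y[j] + h * a21 * k1[j];
        rhs_core(p, yt, k2);
        for (j = 0; j < NSTATE; j++)
            yt[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
        rhs_core(p, yt, k3);
        for (j = 0; j < NSTATE; j++)
            yt[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
        rhs_core(p, yt, k4);
        for (j = 0; j < NSTATE; j++)
            yt[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                                a54 * k4[j]);
        rhs_core(p, yt, k5);
        for (j = 0; j < NSTATE; j++)
            yt[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                                a64 * k4[j] + a65 * k5[j]);
        rhs_core(p, yt, k6);
        for (j = 0; j < NSTATE; j++)
            y5[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                                b5 * k5[j] + b6 * k6[j]);
        rhs_core(p, y5, k7);
        double err = 0;
        for (j = 0; j < NSTATE; j++) {
            double e = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                            e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
            double ymax = fabs(y[j]) > fabs(y5[j]) ? fabs(y[j]) : fabs(y5[j]);
            double sc = atol + rtol * ymax;
            err += (e / sc) * (e / sc);
        }
        err = sqrt(err / NSTATE);
        (*steps_left)--;
        if (err <= 1.0) {
            t += h;
            for (j = 0; j < NSTATE; j++) {
                y[j] = y5[j];
                /* scaled states are O(1); a state beyond 1e2 is a
                 * diverging trajectory, treated as integration failure */
                if (!R_FINITE(y[j]) || fabs(y[j]) > 1e2) return -1;
                k1[j] = k7[j];          /* FSAL */
            }
        }
        double fac = err > 1e-30 ? 0.9 * pow(err, -0.2) : 5.0;
        if (fac < 0.2) fac = 0.2;
        if (fac > 5.0) fac = 5.0;
        h *= fac;
    }
    *hguess = h;
    return 0;
}

/* Integrate over all output times; out is ntimes x 8 (column-major,
 * time-fastest as an R matrix). Returns 0 on success. Output states that
 * undershoot zero by at most atol are clamped; worse undershoot fails. */
static int integrate_times(const double *p, const double *init,
                           const double *times, int ntimes,
                           double rtol, double atol, int maxsteps,
                           double *out)
{
    double y[NSTATE];
    int steps_left = maxsteps;
    double hguess = 0;
    memcpy(y, init, sizeof y);
    for (int j = 0; j < NSTATE; j++) out[0 + ntimes * j] = y[j];
    for (int i = 1; i < ntimes; i++) {
        if (dp45_segment(p, y, times[i - 1], times[i], rtol, atol,
                         &steps_left, &hguess) != 0)
            return -1;
        for (int j = 0; j < NSTATE; j++) {
            double v = y[j];
            if (v < 0) {
                if (v < -atol) return -1;
                v = 0;
            }
            out[i + ntimes * j] = v;
        }
    }
    return 0;
}

/* .Call: simulate a trajectory. Returns ntimes x 8 matrix or R_NilValue on
 * failure. */
SEXP ferm_simulate_c(SEXP parms, SEXP init, SEXP times, SEXP rtol,
                     SEXP atol, SEXP maxsteps)
{
    int ntimes = LENGTH(times);
    SEXP out = PROTECT(allocMatrix(REALSXP, ntimes, NSTATE));
    int ok = integrate_times(REAL(parms), REAL(init), REAL(times), ntimes,
                             asReal(rtol), asReal(atol),
                             (int) asReal(maxsteps), REAL(out));
    UNPROTECT(1);
    return ok == 0 ? out : R_NilValue;
}

/* residuals of observations given a full parameter vector; obs_series and
 * obs_time are 0-based indices into the state/time dimensions. Returns 0
 * on success. */
static int resid_eval(const double *p, const double *init,
                      const double *times, int ntimes,
                      const double *yobs, const int *obs_series,
                      const int *obs_time, int nobs,
                      double rtol, double atol, int maxsteps,
                      double *traj_buf, double *res)
{
    if (integrate_times(p, init, times, ntimes, rtol, atol, maxsteps,
                        traj_buf) != 0)
        return -1;
    for (int i = 0; i < nobs; i++)
        res[i] = yobs[i] - traj_buf[obs_time[i] + ntimes * obs_series[i]];
    return 0;
}

SEXP ferm_resid_c(SEXP parms, SEXP init, SEXP times, SEXP yobs,
                  SEXP obs_series, SEXP obs_time, SEXP rtol, SEXP atol,
                  SEXP maxsteps)
{
    int ntimes = LENGTH(times), nobs = LENGTH(yobs);
    SEXP out = PROTECT(allocVector(REALSXP, nobs));
    double *traj = (double *) R_alloc(ntimes * NSTATE, sizeof(double));
    int ok = resid_eval(REAL(parms), REAL(init), REAL(times), ntimes,
                        REAL(yobs), INTEGER(obs_series), INTEGER(obs_time),
                        nobs, asReal(rtol), asReal(atol),
                        (int) asReal(maxsteps), traj, REAL(out));
    UNPROTECT(1);
    return ok == 0 ? out : R_NilValue;
}

/* ---------------- sampler ---------------- */

typedef struct {
    const double *init, *times, *yobs;
    const int *obs_series, *obs_time;
    int ntimes, nobs, maxsteps;
    double rtol, atol;
    const int *active;   /* 0-based indices into the 43-slot table */
    int d;
    double flags[5];
    double prior_mean, prior_sd, cauchy_scale;
    double *parms;       /* 48-slot work vector */
    double *traj;        /* ntimes x 8 work buffer */
} lik_ctx;

/* fill residuals for psi (log parameters); returns 0 on success */
static int ctx_resid(lik_ctx *cx, const double *psi, double *res)
{
    for (int j = 0; j < cx->d; j++) {
        double th = exp(psi[j]);
        if (th > 25.0) return -1;   /* prior mass out there is nil */
        cx->parms[cx->active[j]] = th;
    }
    return resid_eval(cx->parms, cx->init, cx->times, cx->ntimes, cx->yobs,
                      cx->obs_series, cx->obs_time, cx->nobs, cx->rtol,
                      cx->atol, cx->maxsteps, cx->traj, res);
}

static double lprior_theta(lik_ctx *cx, const double *psi)
{
    double s = 0;
    for (int j = 0; j < cx->d; j++) {
        double th = exp(psi[j]);
        s += dnorm(th, cx->prior_mean, cx->prior_sd, 1) + psi[j];
    }
    return s;
}

/* log sigma is confined to a wide but proper support: observations are
 * max-scaled into [0, 1], so a noise sd beyond e^2 ~ 7.4 is physically
 * meaningless, and the lower cap keeps degenerate zero-residual data
 * (where sigma^-n alone would be improper) well-behaved */
#define LS_MIN (-18.0)
#define LS_MAX (2.0)

static double sigma_lp(lik_ctx *cx, double ls, double ssr, double beta)
{
    if (ls < LS_MIN || ls > LS_MAX) return R_NegInf;
    double quad = ssr > 0 ? ssr / (2 * exp(2 * ls)) : 0;
    return beta * (-cx->nobs * ls - quad) +
           dcauchy(exp(ls), 0, cx->cauchy_scale, 1) + ls;
}

/* slice sampler for log sigma */
static double slice_sigma(lik_ctx *cx, double sigma, double ssr, double beta)
{
    double ls = log(sigma);
    double y0 = sigma_lp(cx, ls, ssr, beta) - exp_rand();
    double lo = ls - 1, hi = ls + 1;
    while (lo > LS_MIN && sigma_lp(cx, lo, ssr, beta) > y0) lo -= 1;
    while (hi < LS_MAX && sigma_lp(cx, hi, ssr, beta) > y0) hi += 1;
    if (lo < LS_MIN) lo = LS_MIN;
    if (hi > LS_MAX) hi = LS_MAX;
    for (int guard = 0; guard < 1000; guard++) {
        double cand = lo + unif_rand() * (hi - lo);
        if (sigma_lp(cx, cand, ssr, beta) > y0) return exp(cand);
        if (cand < ls) lo = cand; else hi = cand;
    }
    return sigma;
}

/* One chain of the tempered DE-MCz sampler. Arguments:
 *   psi0:   d x ntemps start matrix
 *   sigma0: ntemps
 *   sd0:    d archive init sds
 * Returns list(draws, log_lik, lp, accept). Uses the R RNG. */
SEXP ferm_mcmc_c(SEXP parms_template, SEXP active_idx, SEXP init, SEXP times,
                 SEXP yobs, SEXP obs_series, SEXP obs_time,
                 SEXP solver_cfg, SEXP prior_cfg, SEXP temps,
                 SEXP iter_cfg, SEXP psi0, SEXP sigma0, SEXP sd0)
{
    lik_ctx cx;
    cx.ntimes = LENGTH(times);
    cx.nobs = LENGTH(yobs);
    cx.init = REAL(init); cx.times = REAL(times); cx.yobs = REAL(yobs);
    cx.obs_series = INTEGER(obs_series); cx.obs_time = INTEGER(obs_time);
    cx.rtol = REAL(solver_cfg)[0];
    cx.atol = REAL(solver_cfg)[1];
    cx.maxsteps = (int) REAL(solver_cfg)[2];
    cx.prior_mean = REAL(prior_cfg)[0];
    cx.prior_sd = REAL(prior_cfg)[1];
    cx.cauchy_scale = REAL(prior_cfg)[2];
    cx.active = INTEGER(active_idx);
    cx.d = LENGTH(active_idx);
    double parms_work[48];
    memcpy(parms_work, REAL(parms_template), sizeof parms_work);
    cx.parms = parms_work;
    cx.traj = (double *) R_alloc(cx.ntimes * NSTATE, sizeof(double));

    const double *betas = REAL(temps);
    int nt = LENGTH(temps);
    int iter = INTEGER(iter_cfg)[0], warmup = INTEGER(iter_cfg)[1],
        thin = INTEGER(iter_cfg)[2];
    int d = cx.d;
    int n_keep = (iter - warmup) / thin;

    SEXP draws = PROTECT(allocMatrix(REALSXP, n_keep, d + 1));
    SEXP loglik = PROTECT(allocMatrix(REALSXP, n_keep, cx.nobs));
    SEXP lpv = PROTECT(allocVector(REALSXP, n_keep));
    double *dr = REAL(draws), *ll = REAL(loglik), *lp_out = REAL(lpv);

    /* per-rung state */
    int arch_cap = (10 * d > 100 ? 10 * d : 100) + iter / 10 + 2;
    int arch_init = (10 * d > 100 ? 10 * d : 100);
    double *psi = (double *) R_alloc((size_t) nt * d, sizeof(double));
    double *res = (double *) R_alloc((size_t) nt * cx.nobs, sizeof(double));
    double *ssr = (double *) R_alloc(nt, sizeof(double));
    double *sig = (double *) R_alloc(nt, sizeof(double));
    double *lpr = (double *) R_alloc(nt, sizeof(double));
    double *scl = (double *) R_alloc(nt, sizeof(double));
    double **arch = (double **) R_alloc(nt, sizeof(double *));
    int *arch_n = (int *) R_alloc(nt, sizeof(int));
    double *prop = (double *) R_alloc(d, sizeof(double));
    double *rp = (double *) R_alloc(cx.nobs, sizeof(double));

    GetRNGstate();
    double gamma0 = 2.38 / sqrt(2.0 * d);
    int t, j, i;
    int failed = 0;
    for (t = 0; t < nt; t++) {
        memcpy(psi + (size_t) t * d, REAL(psi0) + (size_t) t * d,
               d * sizeof(double));
        sig[t] = REAL(sigma0)[t];
        scl[t] = 1.0;
        /* feasible start: jitter until the ODE solves */
        int tries = 0;
        while (ctx_resid(&cx, psi + (size_t) t * d, res + (size_t) t * cx.nobs)
               != 0 && tries++ < 100) {
            for (j = 0; j < d; j++)
                psi[(size_t) t * d + j] += 0.1 * norm_rand();
        }
        if (tries > 100) { failed = 1; break; }
        double s = 0;
        for (j = 0; j < cx.nobs; j++)
            s += res[(size_t) t * cx.nobs + j] * res[(size_t) t * cx.nobs + j];
        ssr[t] = s;
        lpr[t] = lprior_theta(&cx, psi + (size_t) t * d);
        arch[t] = (double *) R_alloc((size_t) arch_cap * d, sizeof(double));
        for (i = 0; i < arch_init; i++)
            for (j = 0; j < d; j++)
                arch[t][(size_t) i * d + j] =
                    psi[(size_t) t * d + j] + REAL(sd0)[j] * norm_rand();
        arch_n[t] = arch_init;
    }
    if (failed) {
        PutRNGstate();
        UNPROTECT(3);
        return R_NilValue;
    }

    long n_acc = 0;
    for (i = 1; i <= iter; i++) {
        for (t = 0; t < nt; t++) {
            double *pt = psi + (size_t) t * d;
            double *rt = res + (size_t) t * cx.nobs;
            /* DE-MCz proposal */
            int i1 = (int) (unif_rand() * arch_n[t]);
            int i2 = (int) (unif_rand() * arch_n[t]);
            double gamma = unif_rand() < 0.1 ? 1.0 :
                scl[t] * gamma0 * (0.6 + 0.8 * unif_rand());
            for (j = 0; j < d; j++)
                prop[j] = pt[j] + gamma * (arch[t][(size_t) i1 * d + j] -
                                           arch[t][(size_t) i2 * d + j]) +
                          1e-4 * norm_rand();
            int acc = 0;
            if (ctx_resid(&cx, prop, rp) == 0) {
                double sp = 0;
                for (j = 0; j < cx.nobs; j++) sp += rp[j] * rp[j];
                double lprp = lprior_theta(&cx, prop);
                double dssr = sp - ssr[t];
                double dlp = (lprp - lpr[t]) +
                    (dssr != 0 ?
                     betas[t] * (-dssr / (2 * sig[t] * sig[t])) : 0);
                if (log(unif_rand()) < dlp) {
                    memcpy(pt, prop, d * sizeof(double));
                    memcpy(rt, rp, cx.nobs * sizeof(double));
                    ssr[t] = sp; lpr[t] = lprp; acc = 1;
                    if (t == 0) n_acc++;
                }
            }
            if (i % 10 == 0 && arch_n[t] < arch_cap) {
                memcpy(arch[t] + (size_t) arch_n[t] * d, pt,
                       d * sizeof(double));
                arch_n[t]++;
            }
            sig[t] = slice_sigma(&cx, sig[t], ssr[t], betas[t]);
            if (i <= warmup)
                scl[t] *= exp((acc - 0.234) /
                              (pow(i, 0.55) > 5 ? pow(i, 0.55) : 5));
        }
        /* swap a random adjacent pair */
        if (nt > 1) {
            int t1 = (int) (unif_rand() * (nt - 1)), t2 = t1 + 1;
            double l1 = -cx.nobs * log(sig[t1]) -
                        ssr[t1] / (2 * sig[t1] * sig[t1]);
            double l2 = -cx.nobs * log(sig[t2]) -
                        ssr[t2] / (2 * sig[t2] * sig[t2]);
            if (log(unif_rand()) < (betas[t1] - betas[t2]) * (l2 - l1)) {
                for (j = 0; j < d; j++) {
                    double tmp = psi[(size_t) t1 * d + j];
                    psi[(size_t) t1 * d + j] = psi[(size_t) t2 * d + j];
                    psi[(size_t) t2 * d + j] = tmp;
                }
                for (j = 0; j < cx.nobs; j++) {
                    double tmp = res[(size_t) t1 * cx.nobs + j];
                    res[(size_t) t1 * cx.nobs + j] =
                        res[(size_t) t2 * cx.nobs + j];
                    res[(size_t) t2 * cx.nobs + j] = tmp;
                }
                double tmp = ssr[t1]; ssr[t1] = ssr[t2]; ssr[t2] = tmp;
                tmp = sig[t1]; sig[t1] = sig[t2]; sig[t2] = tmp;
                tmp = lpr[t1]; lpr[t1] = lpr[t2]; lpr[t2] = tmp;
            }
        }
        if (i > warmup && (i - warmup) % thin == 0) {
            int k = (i - warmup) / thin - 1;
            if (k < n_keep) {
                double lsum = 0;
                for (j = 0; j < d; j++)
                    dr[k + (size_t) n_keep * j] = exp(psi[j]);
                dr[k + (size_t) n_keep * d] = sig[0];
                for (j = 0; j < cx.nobs; j++) {
                    double pw = dnorm(res[j], 0, sig[0], 1);
                    ll[k + (size_t) n_keep * j] = pw;
                    lsum += pw;
                }
                lp_out[k] = lsum + lpr[0] +
                    dcauchy(sig[0], 0, cx.cauchy_scale, 1) + log(sig[0]);
            }
        }
    }
    PutRNGstate();

    SEXP ans = PROTECT(allocVector(VECSXP, 4));
    SET_VECTOR_ELT(ans, 0, draws);
    SET_VECTOR_ELT(ans, 1, loglik);
    SET_VECTOR_ELT(ans, 2, lpv);
    SET_VECTOR_ELT(ans, 3, ScalarReal((double) n_acc / iter));
    SEXP nm = PROTECT(allocVector(STRSXP, 4));
    SET_STRING_ELT(nm, 0, mkChar("draws"));
    SET_STRING_ELT(nm, 1, mkChar("log_lik"));
    SET_STRING_ELT(nm, 2, mkChar("lp"));
    SET_STRING_ELT(nm, 3, mkChar("accept"));
    setAttrib(ans, R_NamesSymbol, nm);
    UNPROTECT(5);
    return ans;
}
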