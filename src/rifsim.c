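/* Adaptive Dormand-Prince 5(4) integrator for the rifampicin population-PK
 * structural model: transit-compartment absorption (analytic gamma-pulse
 * forcing, superposed over doses), one-compartment disposition with
 * Michaelis-Menten elimination scaled by an enzyme turnover pool
 * (auto-induction), plus augmented states for cumulative AUC and cumulative
 * eliminated mass.
 *
 * States: y[0] depot amount (mg), y[1] central amount (mg),
 *         y[2] enzyme pool (relative, 1 = uninduced),
 *         y[3] cumulative integral of Cp (h*mg/L), y[4] eliminated mass (mg).
 *
 * Inter-occasion variability enters as per-day multipliers on km and ka and
 * as per-dose transit rate constants / input masses (MTT and F realisations
 * are attached to each dose by the R wrapper).
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <math.h>

#define NSTATE 5
#define MAX_STEPS 4000000

typedef struct {
    double Vmax, km, V, ka, Emax, EC50, kENZ, NN, lgN;
    int ndose;
    const double *dose_t;    /* h since first dose, ascending */
    const double *dose_mass; /* F * amount, mg */
    const double *dose_ktr;  /* (NN+1)/MTT_eff for that dose, 1/h */
    int nday;
    const double *km_mult;   /* exp(eta_iov_km) by day index */
    const double *ka_mult;   /* exp(eta_iov_ka) by day index */
} rifpar;

/* Total transit-chain input rate at time t: sum over past doses of
 * mass * ktr * (ktr dt)^NN exp(-ktr dt) / Gamma(NN+1), evaluated in log
 * space.  Doses are scanned newest-first; once a dose is past the pulse
 * (ktr dt > NN) and negligible, all older doses are too. */
static double input_rate(double t, const rifpar *p)
{
    double s = 0.0;
    for (int i = p->ndose - 1; i >= 0; i--) {
        double dt = t - p->dose_t[i];
        if (dt <= 0.0) continue;
        double x = p->dose_ktr[i] * dt;
        double lt = p->NN * log(x) - x - p->lgN;
        if (lt > -700.0)
            s += p->dose_mass[i] * p->dose_ktr[i] * exp(lt);
        else if (x > p->NN)
            break;
    }
    return s;
}

static void rif_rhs(double t, const double *y, double *dy, const rifpar *p)
{
    int d = (int)(t / 24.0);
    if (d < 0) d = 0;
    if (d >= p->nday) d = p->nday - 1;
    double km = p->km * p->km_mult[d];
    double ka = p->ka * p->ka_mult[d];
    double Cp = y[1] / p->V;
    if (Cp < 0.0) Cp = 0.0;
    double elim = p->Vmax * y[2] * Cp / (km + Cp);
    dy[0] = input_rate(t, p) - ka * y[0];
    dy[1] = ka * y[0] - elim;
    dy[2] = p->kENZ * (1.0 + p->Emax * Cp / (p->EC50 + Cp)) - p->kENZ * y[2];
    dy[3] = Cp;
    dy[4] = elim;
}

/* Dormand-Prince 5(4) coefficients */
static const double c2 = 1.0 / 5.0, c3 = 3.0 / 10.0, c4 = 4.0 / 5.0,
                    c5 = 8.0 / 9.0;
static const double a21 = 1.0 / 5.0;
static const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
static const double a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0;
static const double a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
                    a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0;
static const double a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0,
                    a63 = 46732.0 / 5247.0, a64 = 49.0 / 176.0,
                    a65 = -5103.0 / 18656.0;
static const double b1 = 35.0 / 384.0, b3 = 500.0 / 1113.0,
                    b4 = 125.0 / 192.0, b5 = -2187.0 / 6784.0,
                    b6 = 11.0 / 84.0;
static const double e1 = 71.0 / 57600.0, e3 = -71.0 / 16695.0,
                    e4 = 71.0 / 1920.0, e5 = -17253.0 / 339200.0,
                    e6 = 22.0 / 525.0, e7 = -1.0 / 40.0;

/* One embedded step from (t, y) with size h; y5 gets the 5th-order result,
 * k7 the FSAL derivative there; returns weighted RMS error. */
static double dp_step(double t, const double *y, double h, const double *k1,
                      double *y5, double *k7, double rtol, double atol,
                      const rifpar *p)
{
    double k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE], k6[NSTATE];
    double yt[NSTATE];
    int i;

    for (i = 0; i < NSTATE; i++) yt[i] = y[i] + h * a21 * k1[i];
    rif_rhs(t + c2 * h, yt, k2, p);
    for (i = 0; i < NSTATE; i++) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rif_rhs(t + c3 * h, yt, k3, p);
    for (i = 0; i < NSTATE; i++)
        yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rif_rhs(t + c4 * h, yt, k4, p);
    for (i = 0; i < NSTATE; i++)
        yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rif_rhs(t + c5 * h, yt, k5, p);
    for (i = 0; i < NSTATE; i++)
        yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rif_rhs(t + h, yt, k6, p);
    for (i = 0; i < NSTATE; i++)
        y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rif_rhs(t + h, y5, k7, p);

    double err = 0.0;
    for (i = 0; i < NSTATE; i++) {
        double ee = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                         e6 * k6[i] + e7 * k7[i]);
        double ay = fabs(y[i]), ay5 = fabs(y5[i]);
        double sc = atol + rtol * (ay > ay5 ? ay : ay5);
        double r = ee / sc;
        err += r * r;
    }
    return sqrt(err / NSTATE);
}

/* Integrate from stops[0] to stops[n-1], recording the state at every stop.
 * reset[j] != 0 forces a small restart step after stop j (dose events /
 * parameter discontinuities). */
SEXP C_rif_sim(SEXP stops_, SEXP reset_, SEXP y0_, SEXP theta_, SEXP dose_t_,
               SEXP dose_mass_, SEXP dose_ktr_, SEXP km_mult_, SEXP ka_mult_,
               SEXP tol_)
{
    rifpar p;
    const double *theta = REAL(theta_);
    p.Vmax = theta[0]; p.km = theta[1]; p.V = theta[2]; p.ka = theta[3];
    p.Emax = theta[4]; p.EC50 = theta[5]; p.kENZ = theta[6]; p.NN = theta[7];
    p.lgN = lgammafn(p.NN + 1.0);
    p.ndose = LENGTH(dose_t_);
    p.dose_t = REAL(dose_t_);
    p.dose_mass = REAL(dose_mass_);
    p.dose_ktr = REAL(dose_ktr_);
    p.nday = LENGTH(km_mult_);
    p.km_mult = REAL(km_mult_);
    p.ka_mult = REAL(ka_mult_);

    const double rtol = REAL(tol_)[0], atol = REAL(tol_)[1];
    const double *stops = REAL(stops_);
    const int *reset = INTEGER(reset_);
    const int nstop = LENGTH(stops_);

    SEXP out_ = PROTECT(allocMatrix(REALSXP, nstop, NSTATE));
    double *out = REAL(out_);

    double y[NSTATE], y5[NSTATE], k1[NSTATE], k7[NSTATE];
    for (int i = 0; i < NSTATE; i++) {
        y[i] = REAL(y0_)[i];
        out[0 + i * nstop] = y[i];
    }

    double t = stops[0];
    double h = 1e-3;
    long nsteps = 0;
    rif_rhs(t, y, k1, &p);

    for (int j = 1; j < nstop; j++) {
        double tend = stops[j];
        if (tend < t)
            error("simulation stop times must be non-decreasing");
        if (reset[j - 1]) {
            h = 1e-3;
            rif_rhs(t, y, k1, &p); /* rhs may be discontinuous at the stop */
        }
        while (t < tend) {
            if (h > tend - t) h = tend - t;
            if (h < 1e-12) { t = tend; break; }
            double err = dp_step(t, y, h, k1, y5, k7, rtol, atol, &p);
            if (++nsteps > MAX_STEPS)
                error("ODE step limit exceeded (t = %g)", t);
            if (!R_FINITE(err) || !R_FINITE(y5[0]) || !R_FINITE(y5[1]) ||
                !R_FINITE(y5[2])) {
                /* non-finite trial state: shrink hard */
                h *= 0.1;
                if (h < 1e-14)
                    error("ODE solver failure: non-finite state at t = %g", t);
                continue;
            }
            if (err <= 1.0) {
                t += h;
                for (int i = 0; i < NSTATE; i++) { y[i] = y5[i]; k1[i] = k7[i]; }
                double fac = 0.9 * pow(err > 1e-10 ? err : 1e-10, -0.2);
                if (fac > 5.0) fac = 5.0;
                h *= fac;
            } else {
                double fac = 0.9 * pow(err, -0.2);
                if (fac < 0.1) fac = 0.1;
                h *= fac;
            }
        }
        for (int i = 0; i < NSTATE; i++) out[j + i * nstop] = y[i];
    }
    UNPROTECT(1);
    return out_;
}
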