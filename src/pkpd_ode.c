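/* Combined ritonavir / oral paclitaxel / TSP-1 ODE system in the
 * deSolve compiled-model convention.
 *
 * Units: amounts ug, volumes L, concentrations ug/L (== ng/mL),
 * times h.  Parameters arrive through the fixed-size parms vector
 * (padded on the R side, see solve_pkpd()):
 *
 *   p[0]  nd   number of paclitaxel doses
 *   p[1]  nr   number of ritonavir doses
 *   p[2]  mode absorption: 1 = Weibull density as time-varying
 *              first-order rate on gut amount, 2 = direct density input
 *   p[3..9]    ritonavir: CL, Vc, Q, Vp, F, MAT, lambda (IG shape)
 *   p[10..18]  paclitaxel: QH, VH, fu, CLint0, Imax, KI, Vc, Q, Vp
 *   p[19..21]  TSP-1: kin0, kout, EC50
 *   p[24 + 4d] per paclitaxel dose d: time, alpha, beta, amount (ug,
 *              already scaled by relative gut bioavailability)
 *   p[24 + 4*nd + 2r] per ritonavir dose r: time, amount (ug)
 *
 * State: y[0] rtv central, y[1] rtv peripheral, y[2..2+nd-1] per-dose
 * gut amounts, then liver, central, peripheral, cumulative AUC of the
 * central concentration, TSP-1 concentration.
 */

#include <R.h>
#include <math.h>

#define PAX_NPARMS 4096

static double p[PAX_NPARMS];

void oralpkpd_initmod(void (*odeparms)(int *, double *))
{
    int n = PAX_NPARMS;
    odeparms(&n, p);
}

static double weib_ka(double tau, double alpha, double beta)
{
    double z, zb;
    if (tau <= 0.0)
        return 0.0;
    z = tau / alpha;
    zb = pow(z, beta);
    if (zb > 700.0)            /* exp underflow; avoids Inf * 0 */
        return 0.0;
    return (beta / alpha) * pow(z, beta - 1.0) * exp(-zb);
}

/* inverse-Gaussian density with mean mu and shape lambda */
static double ig_pdf(double t, double mu, double lambda)
{
    double d;
    if (t <= 0.0)
        return 0.0;
    d = t - mu;
    return sqrt(lambda / (2.0 * M_PI * t * t * t)) *
        exp(-lambda * d * d / (2.0 * mu * mu * t));
}

void oralpkpd_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    int nd = (int) p[0];
    int nr = (int) p[1];
    int mode = (int) p[2];

    double cl_r = p[3], vc_r = p[4], q_r = p[5], vp_r = p[6];
    double f_r = p[7], mat = p[8], lambda = p[9];
    double qh = p[10], vh = p[11], fu = p[12];
    double clint0 = p[13], imax = p[14], ki = p[15];
    double vc = p[16], q = p[17], vp = p[18];
    double kin0 = p[19], kout = p[20], ec50 = p[21];

    const int OFF = 24;
    int ig = 2;
    int il = 2 + nd, ic = 3 + nd, ipr = 4 + nd, ia = 5 + nd, it = 6 + nd;
    int d, r;
    double rin = 0.0, absin = 0.0;
    double c_rtv, clint, ch, cc, cp, stim;

    for (r = 0; r < nr; r++) {
        double tr = p[OFF + 4 * nd + 2 * r];
        double ar = p[OFF + 4 * nd + 2 * r + 1];
        rin += f_r * ar * ig_pdf(*t - tr, mat, lambda);
    }
    c_rtv = y[0] / vc_r;
    ydot[0] = rin - (cl_r / vc_r) * y[0] - (q_r / vc_r) * y[0]
        + (q_r / vp_r) * y[1];
    ydot[1] = (q_r / vc_r) * y[0] - (q_r / vp_r) * y[1];

    /* ritonavir-inhibited intrinsic clearance, floored at zero */
    clint = clint0 - imax * c_rtv / (ki + c_rtv);
    if (clint < 0.0)
        clint = 0.0;

    for (d = 0; d < nd; d++) {
        double td = p[OFF + 4 * d];
        double al = p[OFF + 4 * d + 1];
        double be = p[OFF + 4 * d + 2];
        double am = p[OFF + 4 * d + 3];
        double ka = weib_ka(*t - td, al, be);
        double rate = (mode == 2) ? am * ka : ka * y[ig + d];
        absin += rate;
        ydot[ig + d] = -rate;
    }

    ch = y[il] / vh;
    cc = y[ic] / vc;
    cp = y[ipr] / vp;

    ydot[il] = absin + qh * (cc - ch) - fu * clint * ch;
    ydot[ic] = qh * (ch - cc) - q * cc + q * cp;
    ydot[ipr] = q * (cc - cp);
    ydot[ia] = cc;

    stim = 1.0 + cc / (ec50 + cc);
    ydot[it] = kin0 * stim - kout * y[it];
}
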