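/* Right-hand side of the two-compartment soma-axon model, compiled for use
 * with deSolve's lsoda.  State vector: (V1, V2, h, w1, w2).
 *
 * Units throughout: mV, ms, nS, pA, pF (nS*mV = pA, pF*mV/ms = pA).
 *
 * Parameters arrive as a fixed-length padded double vector (deSolve's
 * initializer interface copies a declared number of doubles).  Layout:
 *   [0]  c1      [1]  c2      [2]  g1      [3]  g2      [4]  gc
 *   [5]  Elk     [6]  gNa     [7]  ENa     [8]  m_vhalf [9]  m_slope
 *   [10] na_corr (resting-current correction, pA)
 *   [11] gKLT1   [12] gKLT2   [13] EK      [14] z_rest
 *   [15] klt1_corr [16] klt2_corr         [17] Esyn
 *   [18] clamp_V1 flag (0/1)  [19] clamped V1 value
 *   [20] stim_type (0 none, 1 step, 2 ramp)
 *   [21..23] stimulus parameters:
 *        step: amplitude pA, onset ms, duration ms
 *        ramp: slope pA/ms, peak pA, onset ms (held at peak after the rise)
 *   [24] EPSG amplitude coefficient (nS)  [25] tau_decay ms  [26] tau_rise ms
 *   [27] n_events
 *   [28 + i]          event onset times (ms), i = 0..n_events-1
 *   [28 + MAXEV + i]  event scales (x unitary)
 */

#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define MAXEV 8192
#define PARMS_LEN (28 + 2 * MAXEV)
/* contributions older than this are below double precision for the
 * default kernel (tau_decay = 0.18 ms) */
#define EV_WINDOW 8.0

static double p[PARMS_LEN];

void somaxon_init(void (*odeparms)(int *, double *))
{
    int N = PARMS_LEN;
    odeparms(&N, p);
}

static double syn_conductance(double t)
{
    int n = (int) p[27];
    double gs = 0.0;
    for (int i = 0; i < n; i++) {
        double dt = t - p[28 + i];
        if (dt > 0.0 && dt < EV_WINDOW)
            gs += p[28 + MAXEV + i] * (exp(-dt / p[25]) - exp(-dt / p[26]));
    }
    return p[24] * gs;
}

static double injected_current(double t)
{
    int type = (int) p[20];
    if (type == 1) {            /* step */
        double amp = p[21], onset = p[22], dur = p[23];
        return (t >= onset && t < onset + dur) ? amp : 0.0;
    } else if (type == 2) {     /* ramp, then hold at peak */
        double slope = p[21], peak = p[22], onset = p[23];
        if (t < onset) return 0.0;
        double v = slope * (t - onset);
        return (v < peak) ? v : peak;
    }
    return 0.0;
}

void somaxon_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double V1 = y[0], V2 = y[1], h = y[2], w1 = y[3], w2 = y[4];

    double gs   = syn_conductance(*t);
    double Isyn = gs * (V1 - p[17]);
    double Iapp = injected_current(*t);

    double m = 1.0 / (1.0 + exp(-(V2 - p[8]) / p[9]));
    double INa = p[6] * m * m * m * h * (V2 - p[7]) - p[10];

    double IK1 = 0.0, IK2 = 0.0;
    if (p[11] > 0.0) {
        double w4 = w1 * w1 * w1 * w1;
        IK1 = p[11] * w4 * p[14] * (V1 - p[13]) - p[15];
    }
    if (p[12] > 0.0) {
        double w4 = w2 * w2 * w2 * w2;
        IK2 = p[12] * w4 * p[14] * (V2 - p[13]) - p[16];
    }

    ydot[0] = (-p[2] * (V1 - p[5]) - p[4] * (V1 - V2) - IK1 - Isyn + Iapp)
              / p[0];
    if (p[18] > 0.5) ydot[0] = 0.0;

    ydot[1] = (-p[3] * (V2 - p[5]) - p[4] * (V2 - V1) - IK2 - INa) / p[1];

    /* Na inactivation gate (axon compartment voltage) */
    {
        double hinf = 1.0 / (1.0 + exp((V2 + 65.0) / 6.0));
        double tauh = 0.24 * (100.0 / (7.0 * exp((V2 + 60.0) / 11.0)
                                       + 10.0 * exp(-(V2 + 60.0) / 25.0))
                              + 0.6);
        ydot[2] = (hinf - h) / tauh;
    }
    /* KLT activation gates, one per compartment */
    {
        double winf = 1.0 / (1.0 + exp(-(V1 + 65.0) / 6.0));
        double tauw = 0.46 * (100.0 / (6.0 * exp((V1 + 75.0) / 12.15)
                                       + 24.0 * exp(-(V1 + 75.0) / 25.0))
                              + 0.55);
        ydot[3] = (winf - w1) / tauw;
    }
    {
        double winf = 1.0 / (1.0 + exp(-(V2 + 65.0) / 6.0));
        double tauw = 0.46 * (100.0 / (6.0 * exp((V2 + 75.0) / 12.15)
                                       + 24.0 * exp(-(V2 + 75.0) / 25.0))
                              + 0.55);
        ydot[4] = (winf - w2) / tauw;
    }
}

static const R_CMethodDef CEntries[] = {
    {"somaxon_init",   (DL_FUNC) &somaxon_init,   1},
    {"somaxon_derivs", (DL_FUNC) &somaxon_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_somaxon(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
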