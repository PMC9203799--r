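// Conductance-based point-neuron model with slow extracellular potassium and
// intracellular sodium dynamics (Hodgkin-Huxley currents with instantaneous
// sodium activation, Na/K pump, glial potassium uptake, lateral potassium
// diffusion toward a bath value).  Units: mV, ms, mS/cm2, uA/cm2, mM.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout; must match .parsVector() on the R side.
enum ParIdx { P_KINF = 0, P_GNA, P_GK, P_GNAL, P_GKL, P_GCLL, P_PHI, P_RHO,
              P_GGLIA, P_EPSK, P_BETA, P_TAU, P_GAMMA, P_CM, P_NERNST,
              P_CLIN, P_CLOUT, P_NAOUTBASE, P_NAINREF, P_KINBASE, P_NPARS };

struct Deriv {
    double dv, dn, dh, dko, dnai, iion;
};

static inline double vtrap(double x, double y) {
    // x / (1 - exp(-x/y)) with a series fallback near zero
    double r = x / y;
    if (std::fabs(r) < 1e-6) return y * (1.0 + r / 2.0);
    return x / (1.0 - std::exp(-r));
}

static inline Deriv cressmanDeriv(double v, double n, double h, double ko,
                                  double nai, const double* p, double kinf,
                                  double iext) {
    const double nernst = p[P_NERNST];
    const double nao = p[P_NAOUTBASE] - p[P_BETA] * (nai - p[P_NAINREF]);
    const double ki = p[P_KINBASE] + (p[P_NAINREF] - nai);
    const double eNa = nernst * std::log(nao / nai);
    const double eK = nernst * std::log(ko / ki);
    const double eCl = nernst * std::log(p[P_CLIN] / p[P_CLOUT]);

    const double am = 0.1 * vtrap(v + 30.0, 10.0);
    const double bm = 4.0 * std::exp(-(v + 55.0) / 18.0);
    const double minf = am / (am + bm);
    const double an = 0.01 * vtrap(v + 34.0, 10.0);
    const double bn = 0.125 * std::exp(-(v + 44.0) / 80.0);
    const double ah = 0.07 * std::exp(-(v + 44.0) / 20.0);
    const double bh = 1.0 / (1.0 + std::exp(-0.1 * (v + 14.0)));

    const double iNa = p[P_GNA] * minf * minf * minf * h * (v - eNa) +
        p[P_GNAL] * (v - eNa);
    const double iK = (p[P_GK] * n * n * n * n + p[P_GKL]) * (v - eK);
    const double iCl = p[P_GCLL] * (v - eCl);

    const double ipump = (p[P_RHO] / (1.0 + std::exp((25.0 - nai) / 3.0))) /
        (1.0 + std::exp(5.5 - ko));
    const double iglia = p[P_GGLIA] / (1.0 + std::exp((18.0 - ko) / 2.5));
    const double idiff = p[P_EPSK] * (ko - kinf);

    Deriv d;
    d.iion = iNa + iK + iCl;
    d.dv = (-d.iion + iext) / p[P_CM];
    d.dn = p[P_PHI] * (an * (1.0 - n) - bn * n);
    d.dh = p[P_PHI] * (ah * (1.0 - h) - bh * h);
    d.dko = (p[P_GAMMA] * p[P_BETA] * iK - 2.0 * p[P_BETA] * ipump -
             iglia - idiff) / p[P_TAU];
    d.dnai = (-p[P_GAMMA] * iNa - 3.0 * ipump) / p[P_TAU];
    return d;
}

// [[Rcpp::export(name = ".cressmanRhsCpp")]]
List cressmanRhsCpp(NumericMatrix state, NumericVector pars,
                    NumericVector kinf, NumericVector iext) {
    const int m = state.nrow();
    if (state.ncol() != 5) stop("state must have 5 columns");
    NumericMatrix deriv(m, 5);
    NumericVector iion(m);
    const double* p = pars.begin();
    for (int i = 0; i < m; ++i) {
        const double ki = kinf.size() == m ? kinf[i] : p[P_KINF];
        const double ie = iext.size() == m ? iext[i] : 0.0;
        for (int k = 0; k < 5; ++k) {
            if (!std::isfinite(state(i, k))) {
                const char* nm[5] = {"v", "gateN", "gateH", "kOut", "naIn"};
                stop("non-finite state in field '%s' (neuron %d)", nm[k],
                     i + 1);
            }
        }
        Deriv d = cressmanDeriv(state(i, 0), state(i, 1), state(i, 2),
                                state(i, 3), state(i, 4), p, ki, ie);
        deriv(i, 0) = d.dv; deriv(i, 1) = d.dn; deriv(i, 2) = d.dh;
        deriv(i, 3) = d.dko; deriv(i, 4) = d.dnai;
        iion[i] = d.iion;
    }
    return List::create(_["iIon"] = iion, _["derivatives"] = deriv);
}

// Advance all neurons by nsteps forward-Euler steps of size dt, mutating
// `state` in place.  Gating variables leaving [0,1] by less than clampEps
// are clamped; larger excursions or non-finite updates raise an error
// naming dt.  Optionally records the membrane potential of one neuron
// (0-based recordNode) every recordStride steps (after the step).
// [[Rcpp::export(name = ".cressmanEulerCpp")]]
NumericVector cressmanEulerCpp(NumericMatrix state, NumericVector pars,
                               NumericVector kinf, double dt, int nsteps,
                               NumericVector iext, int recordStride,
                               int recordNode, double clampEps) {
    const int m = state.nrow();
    if (state.ncol() != 5) stop("state must have 5 columns");
    const double* p = pars.begin();
    const bool perNodeK = kinf.size() == m;
    const bool perNodeI = iext.size() == m;
    int nrec = 0;
    if (recordStride > 0 && recordNode >= 0) nrec = nsteps / recordStride;
    NumericVector trace(nrec);
    int ir = 0;
    for (int s = 0; s < nsteps; ++s) {
        for (int i = 0; i < m; ++i) {
            const double ki = perNodeK ? kinf[i] : p[P_KINF];
            const double ie = perNodeI ? iext[i] : 0.0;
            Deriv d = cressmanDeriv(state(i, 0), state(i, 1), state(i, 2),
                                    state(i, 3), state(i, 4), p, ki, ie);
            double v = state(i, 0) + dt * d.dv;
            double n = state(i, 1) + dt * d.dn;
            double h = state(i, 2) + dt * d.dh;
            double ko = state(i, 3) + dt * d.dko;
            double nai = state(i, 4) + dt * d.dnai;
            if (!std::isfinite(v) || !std::isfinite(ko) ||
                !std::isfinite(nai))
                stop("non-finite update at step %d; reduce dt = %g ms",
                     s + 1, dt);
            if (n < 0.0) { if (n < -clampEps)
                    stop("gating variable n left [0,1] by more than %g at dt = %g ms",
                         clampEps, dt); n = 0.0; }
            if (n > 1.0) { if (n > 1.0 + clampEps)
                    stop("gating variable n left [0,1] by more than %g at dt = %g ms",
                         clampEps, dt); n = 1.0; }
            if (h < 0.0) { if (h < -clampEps)
                    stop("gating variable h left [0,1] by more than %g at dt = %g ms",
                         clampEps, dt); h = 0.0; }
            if (h > 1.0) { if (h > 1.0 + clampEps)
                    stop("gating variable h left [0,1] by more than %g at dt = %g ms",
                         clampEps, dt); h = 1.0; }
            state(i, 0) = v; state(i, 1) = n; state(i, 2) = h;
            state(i, 3) = ko; state(i, 4) = nai;
        }
        if (nrec > 0 && (s + 1) % recordStride == 0 && ir < nrec)
            trace[ir++] = state(recordNode, 0);
    }
    return trace;
}
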