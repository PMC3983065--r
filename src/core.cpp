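#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Numerically stable softplus: log(1 + exp(x)) = x + log1p(exp(-x)) for x > 0.
static inline double softplus(double x) {
  return x > 0.0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// Steady-state threshold curve: two asymptotic slopes (alpha below the knee
// V_i, beta above), curvature set by k_a, offset at the lower asymptote.
static inline double ss_theta(double v, double vi, double off, double alpha,
                              double beta, double ka) {
  return off + alpha * (v - vi) + (beta - alpha) * ka * softplus((v - vi) / ka);
}

// [[Rcpp::export]]
NumericVector steady_state_threshold_cpp(NumericVector v, double vi, double off,
                                         double alpha, double beta, double ka) {
  R_xlen_t n = v.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = ss_theta(v[i], vi, off, alpha, beta, ka);
  return out;
}

// Exact exponential update of the first-order threshold ODE, V held constant
// over each sampling interval: theta[n+1] = s + (theta[n] - s) * exp(-dt/tau)
// with s = theta_inf(V[n]). Unconditionally stable for tau << dt.
// [[Rcpp::export]]
NumericVector integrate_threshold_cpp(NumericVector v, double dt, double tau,
                                      double vi, double off, double alpha,
                                      double beta, double ka, double theta0) {
  R_xlen_t n = v.size();
  NumericVector th(n);
  double a = std::exp(-dt / tau);
  double cur = theta0;
  th[0] = cur;
  for (R_xlen_t i = 1; i < n; ++i) {
    double s = ss_theta(v[i - 1], vi, off, alpha, beta, ka);
    cur = s + (cur - s) * a;
    th[i] = cur;
  }
  return th;
}

// Threshold integration plus spike prediction in one pass. A spike is emitted
// at a sample where V >= theta, provided the previous emitted spike is at
// least `refractory` ms in the past; theta keeps evolving through spikes and
// refractoriness (no reset). Returns 1-based spike sample indices and,
// optionally, the full threshold trace.
// [[Rcpp::export]]
List predict_spikes_cpp(NumericVector v, double dt, double tau, double vi,
                        double off, double alpha, double beta, double ka,
                        double theta0, double refractory, bool keep_theta) {
  R_xlen_t n = v.size();
  NumericVector th(keep_theta ? n : 0);
  std::vector<int> sp;
  double a = std::exp(-dt / tau);
  double cur = theta0;
  double last = -1e300;
  if (keep_theta) th[0] = cur;
  if (v[0] >= cur) {
    sp.push_back(1);
    last = 0.0;
  }
  for (R_xlen_t i = 1; i < n; ++i) {
    double s = ss_theta(v[i - 1], vi, off, alpha, beta, ka);
    cur = s + (cur - s) * a;
    if (keep_theta) th[i] = cur;
    if (v[i] >= cur) {
      double t = i * dt;
      if (t - last >= refractory) {
        sp.push_back(i + 1);
        last = t;
      }
    }
  }
  return List::create(_["spike_idx"] = wrap(sp), _["theta"] = th);
}

// Stylized action-potential upstroke template, written into the emitted
// trace from the logged initiation sample: the depolarization rate starts
// at the spike's own initiation dV/dt `va` (it varies spike to spike, as in
// recordings) and accelerates quadratically to reach `peak` at `T` ms, so
// the phase-plane derivative sweeps rapidly past any onset criterion in the
// 15-35 mV/ms range -- the kink-like sharp initiation seen in vivo.
static inline double wave_template(double t, double v_on, double peak,
                                   double T, double va) {
  double c = ((peak - v_on) - va * T) / (T * T);
  double w = v_on + va * t + c * t * t;
  return w > peak ? peak : w;
}

// Local maxima with topographic prominence >= min_prom (1-based indices).
// For each local maximum, walk outward until a strictly higher sample (or
// the trace edge) is reached on each side; prominence is the peak height
// minus the higher of the two intervening minima (edge sides with no higher
// sample do not cap prominence).
// [[Rcpp::export]]
IntegerVector find_peaks_cpp(NumericVector v, double min_prom) {
  R_xlen_t n = v.size();
  std::vector<int> out;
  for (R_xlen_t i = 1; i + 1 < n; ++i) {
    if (!(v[i] > v[i - 1] && v[i] >= v[i + 1])) continue;
    double lmin = v[i];
    R_xlen_t j = i;
    while (j > 0 && v[j - 1] <= v[i]) {
      --j;
      if (v[j] < lmin) lmin = v[j];
    }
    bool lbound = (j == 0);
    double rmin = v[i];
    R_xlen_t k = i;
    while (k + 1 < n && v[k + 1] <= v[i]) {
      ++k;
      if (v[k] < rmin) rmin = v[k];
    }
    bool rbound = (k + 1 == n);
    double base;
    if (lbound && rbound) base = std::min(lmin, rmin);
    else if (lbound) base = rmin;
    else if (rbound) base = lmin;
    else base = std::max(lmin, rmin);
    if (v[i] - base >= min_prom) out.push_back((int)i + 1);
  }
  return wrap(out);
}

// Exponential integrate-and-fire neuron with an explicit adaptive threshold.
// tau_m dV/dt = (E_L - V) + Delta_T exp((V - theta)/Delta_T) + R I, with theta
// following the first-order adaptation ODE (exact per-sample update). A spike
// is registered when V >= V_detect; V is reset and clamped for `refractory`
// ms while theta keeps evolving. A stylized upstroke (wave_ms to wave_peak
// mV, see wave_template) is written into the *emitted* trace from the logged
// initiation sample onward so onset detection is exercised on realistic
// waveforms; the internal dynamics and the ground-truth threshold are
// untouched by it. I in pA, R in MOhm (R*I*1e-3 -> mV).
// [[Rcpp::export]]
List simulate_eif_cpp(NumericVector I, double dt, double tau_m, double EL,
                      double DT, double R, double Vreset, double refractory,
                      double Vdetect, double tau, double vi, double off,
                      double alpha, double beta, double ka, double V0,
                      double wave_ms, double wave_peak, double criterion) {
  R_xlen_t n = I.size();
  NumericVector vout(n), thout(n);
  std::vector<double> sptimes;
  double a = std::exp(-dt / tau);
  double v = V0;
  double th = ss_theta(V0, vi, off, alpha, beta, ka);
  double refr_until = -1.0;  // time until which V is clamped at reset
  int wave_n = (int)std::lround(wave_ms / dt);
  if (wave_n < 1) wave_n = 1;
  R_xlen_t wave_end = -1;  // last emitted-waveform sample index
  double wave_from = V0;
  R_xlen_t wave_start = 0;
  // spike time is logged at initiation: the first suprathreshold sample whose
  // forward-difference dV/dt exceeds `criterion` (mV/ms) on the upstroke that
  // reaches V_detect; detection/reset bookkeeping stays at V_detect.
  R_xlen_t cand = -1;
  double cand_vdot = 0.0, wave_va = 30.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = i * dt;
    // emit
    if (i <= wave_end) {
      vout[i] = wave_template((i - wave_start) * dt, wave_from, wave_peak,
                              wave_ms, wave_va);
    } else {
      vout[i] = v;
    }
    thout[i] = th;
    // advance threshold (driven by internal V at this sample)
    double s = ss_theta(v, vi, off, alpha, beta, ka);
    double th_next = s + (th - s) * a;
    // advance voltage
    double v_next;
    if (t + dt <= refr_until) {
      v_next = Vreset;
    } else {
      double x = (v - th) / DT;
      if (x > 25.0) x = 25.0;  // divergence guard; spike detection follows
      double dv = (EL - v + DT * std::exp(x) + R * I[i] * 1e-3) / tau_m * dt;
      v_next = v + dv;
      if (!std::isfinite(v_next))
        stop("voltage diverged outside a spike at sample %d", (int)i + 1);
    }
    if (t + dt > refr_until) {
      if (v >= th) {
        if (cand < 0 && (v_next - v) / dt >= criterion) {
          cand = i;
          cand_vdot = (v_next - v) / dt;
        }
      } else {
        cand = -1;  // retreated below threshold: aborted upstroke
      }
    }
    if (v_next >= Vdetect && t + dt > refr_until) {
      // spike detected at sample i+1; initiation logged at `cand`; the
      // emitted waveform replaces everything from the initiation sample on
      // (retroactively for the samples already emitted this upstroke)
      if (i + 1 < n) {
        R_xlen_t on = cand >= 0 ? cand : i;
        sptimes.push_back(on * dt);
        wave_start = on;
        wave_from = vout[on];  // onset voltage
        wave_va = cand >= 0 ? cand_vdot : criterion;
        if (wave_va > 4 * criterion) wave_va = 4 * criterion;
        wave_end = std::min<R_xlen_t>(n - 1, on + wave_n);
        for (R_xlen_t j = on + 1; j <= std::min(i, wave_end); ++j)
          vout[j] = wave_template((j - on) * dt, wave_from, wave_peak,
                                  wave_ms, wave_va);
      }
      refr_until = (i + 1) * dt + refractory;
      v_next = Vreset;
      cand = -1;
    }
    v = v_next;
    th = th_next;
  }
  return List::create(_["v"] = vout, _["theta"] = thout,
                      _["spike_times"] = wrap(sptimes));
}
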