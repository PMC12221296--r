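#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the single-compartment current balance
//   C dVm/dt = g_leak (E_leak - Vm) + gi(t) (Ei - Vm) + ge(t) (Ee - Vm)
//              + I_inj(t) + I_noise(t)
// Units: C in pF, conductances in nS, potentials in mV, currents in pA,
// dt in s (pF/nS = ms, hence the dt * 1000 factor).
//
// Optional threshold-reset spiking: when Vm reaches `thresh` (pass NA to
// disable) the output is painted at `spike_amp` for `spike_width` samples
// and the state resets to `reset`.
// [[Rcpp::export]]
NumericVector euler_vm(NumericVector gi, NumericVector ge,
                       NumericVector iinj, NumericVector inoise,
                       double C, double g_leak, double E_leak,
                       double E_i, double E_e, double v_init, double dt,
                       double thresh, double reset, int spike_width,
                       double spike_amp) {
  const int n = gi.size();
  NumericVector out(n);
  const bool spiking = !NumericVector::is_na(thresh);
  const bool noisy = inoise.size() == n;
  const double k = dt * 1000.0 / C;  // ms / pF
  double v = v_init;
  int painted = 0;
  for (int i = 0; i < n; ++i) {
    if (painted > 0) {
      out[i] = spike_amp;
      --painted;
      continue;
    }
    double I = g_leak * (E_leak - v) + gi[i] * (E_i - v) +
               ge[i] * (E_e - v) + iinj[i];
    if (noisy) I += inoise[i];
    v += k * I;
    if (spiking && v >= thresh) {
      out[i] = spike_amp;
      painted = spike_width - 1;
      v = reset;
    } else {
      out[i] = v;
    }
  }
  return out;
}
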