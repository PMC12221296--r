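---
title: "Reconstructing synaptic conductance profiles from rhythmic intracellular recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing synaptic conductance profiles from rhythmic intracellular recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(syncond)
```

## The model and its assumptions

A neuron embedded in a rhythmically active network receives inhibitory and
excitatory synaptic input whose conductances vary with the phase of the
network cycle. `syncond` reconstructs those phase-resolved conductance
profiles from a single intracellular recording, starting from the passive
current-balance equation

$$C \frac{dV_m}{dt} = g_{leak}(E_{leak} - V_m) + g_i(t)(E_i - V_m) +
  g_e(t)(E_e - V_m) + I_{inj}(t).$$

Three assumptions make the inverse problem tractable:

1. **Quasi-static membrane.** The membrane time constant
   $\tau_m = C/g_{leak}$ is far shorter than the time scale of the synaptic
   drive, so $dV_m/dt \approx 0$ at every analysed sample. With a
   leak-to-capacitance ratio around 100 pS/pF, $\tau_m \approx 10$ ms —
   about 1/300 of a 3 s cycle — and this sets the method's time
   resolution.
2. **Passive operation.** Recordings are held at hyperpolarized potentials
   (by default only samples in $[-100, -60]$ mV are analysed) where
   voltage-gated channels are closed and the current–voltage relation is
   linear.
3. **Phase-locked input.** In a periodic network, $g_{i,e}(t) =
   g_{i,e}(\varphi(t))$, where the phase
   $\varphi(t) = (t - t_k)/(t_{k+1} - t_k)$ is piece-wise linear between
   consecutive reference-burst onsets $t_k$.

Under these assumptions, samples collected at the same phase but different
injected currents lie on a line $V_m = V_0(\varphi) + R(\varphi) I_{inj}$.
The cycle is divided into 100 phase bins; an ordinary least-squares fit per
bin yields the total resistance $R(\varphi)$ (slope) and effective resting
potential $V_0(\varphi)$ (intercept), with classical standard errors. The
total conductance is $G(\varphi) = 1/R(\varphi)$ with
$\delta G = \delta R / R^2$. Given the reversal potentials it splits as

$$G_i = G\,\frac{E_e - V_0}{E_e - E_i}, \qquad
  G_e = G\,\frac{V_0 - E_i}{E_e - E_i},$$

so that $G_i + G_e = G$ exactly. Dynamic components subtract each
component's minimum over the cycle,
$\Delta G_{i,e}(\varphi) = G_{i,e}(\varphi) - \min_\varphi G_{i,e}$, and
the sum of the two minima estimates the leak conductance — static synaptic
conductance and true leak are indistinguishable, which is also why the
"static" components below fold in a leak share. Because a dynamic
component is a difference of two measured bins, its standard error is
$\delta \Delta G(\varphi) = \sqrt{\delta G(\varphi)^2 +
\delta G(\varphi_m)^2}$ with $\varphi_m$ the minimizing phase, and each
bin is tested with a one-tailed z-test ($Z = \Delta G / \delta \Delta G$,
$p < 0.05$, no multiple-testing correction by default; Benjamini–Hochberg
optionally).

### Reversal potentials from the wedge diagram

On the plane of $(G, I_0)$ with $I_0(\varphi) = -G(\varphi) V_0(\varphi)$,
the cycle traces a closed trajectory bounded above by the *zero-excitation
line* $I_0 = -E_i G - G_e^0 (E_e - E_i)$ and below by the *zero-inhibition
line* $I_0 = -E_e G + G_i^0 (E_e - E_i)$, where $G_{i,e}^0$ are the static
components. When the neuron receives purely phase-dependent inhibition for
part of the cycle, the trajectory runs along the upper line, whose slope
gives $-E_i$; a pure-excitation interval likewise exposes $-E_e$ below.

The boundary-identification algorithm is an artifact design (no published
procedure exists): enumerate contiguous phase windows of at least 5 bins
(circularly, since pure-input intervals are contiguous in phase), fit each
by least squares, and accept the best window by the score
$\text{length} \times R^2$ subject to (i) $R^2 \ge 0.9$, (ii) a
*tightness* requirement — the window's residual scale must be at the
$I_0$ measurement-error scale (twice the median per-bin $I_0$ error, with
a 2%-of-range floor) — (iii) a *lever-arm* requirement — the window must
span at least a quarter of the trajectory's $G$ range, since a slope
fitted on a near-degenerate abscissa is not an identifiable reversal
estimate — and (iv) one-sided containment: every trajectory point must
lie on the correct side of the line within twice the residual scale.
Requirements (ii) and (iii) were added after the bare
length-times-$R^2$ score proved able to select over-long windows that
straddle the wedge interior, or short low-range fragments, both of which
bias the slope. A lower-line estimate is accepted only if the implied
$E_e$ lands in $[-30, 10]$ mV; otherwise the conventional default
$E_e = -10$ mV is used. No plausibility clamp is applied to $E_i$
(empirical estimates span roughly $-60$ to $-120$ mV). User-supplied
reversals always override estimation, and the wedge result is reported
alongside for comparison.

## Preprocessing choices

* **Spike removal**: a 0.1 s moving median on the measured channel,
  with shrinking windows at the trace ends rather than padding. The median
  filter is idempotent on locally monotone signals; near extrema it
  converges to a root signal after one pass, which is why the package
  treats a second application as a no-op check rather than a guarantee at
  the very edges.
* **Downsampling**: 12.5 kHz to 100 Hz by block averaging (the mean is
  preserved exactly and the averaging is an implicit anti-alias filter).
  Decimation would alias noise; averaging was chosen as the default.
* **Reference conditioning**: full-wave rectification and a first-order
  leaky integrator (`tau` = 0.05 s). Burst onsets are upward crossings of
  10% of burst amplitude above baseline, where the baseline is the 5th
  percentile and the amplitude the median of per-burst peaks (robust to a
  single large burst), iterated once from a provisional pass; crossing
  times are interpolated between samples and crossings closer than half
  the median period are suppressed.
* **Quality control**: an epoch is analysed only if the period CV is
  below 10%, at least three held steps each last at least five cycles
  (with a tenth-of-a-cycle tolerance for boundary sampling effects), and
  the inter-burst baseline drifts less than 1 mV/min (linear trend after
  removing per-step offsets; this operationalizes the informal
  "obvious recording instability" exclusion so that it is testable).
* **Per-bin fits**: at least 10 samples and 2 distinct current levels per
  bin; samples within 50 ms of a step change are excluded (the membrane
  must re-equilibrate); in voltage clamp the measured current is
  regressed on the commanded potential, keeping the regressor controlled
  in both modes. Rank-deficient or nonphysical ($R \le 0$) bins are
  flagged invalid and propagate as missing values — never interpolated,
  because interpolation would fabricate data the regression never saw.
* **Negative components** ($V_0$ outside $[E_i, E_e]$) are retained and
  flagged, not clipped: they are the signature of reversal-potential
  misspecification, in which part of the inhibitory conductance is
  mislabeled as excitatory, and clipping would hide it.

## The simulator: what it emulates and what it does not

`simulate_neuron()` integrates the current-balance equation with forward
Euler at the protocol sample rate (80 µs at 12.5 kHz, about 1/70 of the
shortest membrane time constant encountered; the step is checked against
$\tau_m/10$). Current clamp integrates $V_m$ under a stepwise current
protocol; voltage clamp computes the holding current algebraically.
Defaults represent the modeled preparation: 3 s cycle period, inspiratory
fraction 0.33, $C = 100$ pF, $g_{leak} = 10$ nS ($\tau_m = 10$ ms),
$E_{leak} = -65$ mV, $E_i = -90$ mV, $E_e = -10$ mV.

Design choices worth knowing:

* **Noise** is additive white current noise scaled so the steady-state
  membrane-potential fluctuation equals the requested mV-equivalent
  standard deviation (in voltage clamp, the clamp-current noise is scaled
  to the equivalent fluctuation after downsampling to 100 Hz). This
  matches the regression's residual term without committing to an
  unstated biological noise model; it has no slow (1/f) component, so
  fixtures understate real non-stationarity.
* **Spiking** is an optional threshold/reset add-on ($-45/-65$ mV). Its
  only role is to exercise the median filter; the method itself assumes
  hyperpolarized, non-spiking operation, and default protocols keep the
  membrane below threshold.
* **The synthetic nerve signal** is a burst envelope (square with 20 ms
  cosine edges) over the inspiratory window, amplitude-modulated by
  rectified white noise. The envelope is advanced by the numerically
  computed detector latency — the time for the rectified-integrated
  envelope to cross the 10% threshold — so that detected onsets coincide
  with protocol cycle starts and recovered profiles align with the ground
  truth phase grid. Real nerve signals offer no such alignment; with real
  data all phases are relative to the detected onset, which is the
  field-standard convention anyway.
* **The standard validation fixture** (`make_standard_fixture()`) drives
  the neuron with an inhibitory bell (1–8 nS over phases 0.33–0.88) and
  an excitatory bell (0.5–4 nS over 0.88–1.32, wrapping), under five
  hyperpolarizing current steps of ten 3 s cycles each. The waveforms are
  deliberately smooth and slow so the fixture satisfies the quasi-static
  assumption the method is premised on; each waveform is also constant
  over a contiguous phase interval, so both wedge boundary lines exist by
  construction. Recovery on abrupt waveforms is visibly worse in the bins
  straddling a discontinuity (the estimate lags by about $\tau_m$), which
  is the expected resolution limit, not a bug.

What passing the simulator-based tests does **not** show: robustness to
electrode drift and access-resistance changes, voltage-dependent
(h-current) contamination, space-clamp attenuation of distal synapses
(the known bias that makes measured reversal potentials more negative),
or non-phase-locked input. These are properties of real recordings that
the generator deliberately does not emulate.

## Statistical calibration and its limits

The z-test's type-I behavior is checked on known-null *pairs* of bins:
two bin regressions with identical true conductance run through the real
fit → error-propagation → test machinery (`simulate_null_bins()`), where
the significant fraction at $\alpha = 0.05$ is 5% as it should be. The
literal statistic $\Delta G = G(\varphi) - \min_\varphi G(\varphi)$ is
anticonservative under a global null, because the minimum is selected
from the same noisy bins (an order statistic): with 100 bins of pure
noise, many bins would clear the test. The published procedure ignores
this selection effect, and the package follows the published procedure;
the calibration harness therefore tests the difference statistic the
formula actually propagates errors for. In practice components near the
detection floor should be read with this in mind — which is one reason
the connectome stage applies a magnitude floor (below).

## Functional-connectome inference

Significant components are classified by phase window — inspiration
$[0, r)$, post-inspiration $[r, r+w)$, late expiration $[r+w, 1)$, with
$r$ from the fixture's known inspiratory fraction when available (else
the reference-burst duty cycle, which overestimates $r$ by roughly the
integrator decay time) and $w = (1-r)/2$, since the real post-I/E2 split
is physiological and not measured here. A window is labeled as receiving
input of a given sign when at least 25% of its bins are *material*:
statistically significant **and** at least 10% of that component's
cycle-wide peak. Both thresholds are artifact decisions (the published
rule is qualitative): the fraction keeps a single bin from asserting a
connection, and the magnitude floor keeps two artifacts out — leakage
from a slightly biased reversal estimate, and single transition bins
straddling an abrupt conductance change, both of which are statistically
significant yet minute.

Each labeled window is attributed to the canonical source population
(pre-I/I, ramp-I, early-I, late-I, post-I, aug-E) whose activity template
best matches: candidates must overlap the window's material bins, and the
score is that overlap times the correlation between the template and the
dynamic component over the union of the window and the template's
support. Scoring over the union lets a template whose activity extends
beyond the window (e.g. pre-I/I spanning late expiration *and*
inspiration) be distinguished from one confined to it. Ties within 0.05
are all reported, recurrent self-edges are allowed, and only the sign of
an input — never a transmitter identity — is asserted. The same template
functions parameterize the simulator's phenotype fixtures, so fixture
construction and inference share one source of truth and cannot drift
apart. One consequence of the shared-template design: the ramp-I
fixture's inspiratory excitation follows the pre-I/I source pattern
(rising through late expiration, sustained through inspiration) rather
than a literal inspiratory ramp, because attribution to the pre-I/I
population is the documented ground truth for that phenotype.

## Worked example

```{r example, eval = FALSE}
sim <- make_standard_fixture(seed = 1, noise_sd = 0.5)
fit <- syncond(sim$recording)
summary(fit)
plot(fit)                   # dynamic conductance profiles
plot(fit, which = "wedge")  # (G, I0) trajectory and boundary lines
```

Problem sizes used throughout the validation suite: the standard fixture
is 150 s at 12.5 kHz (1.875 million samples, 48 analysable cycles);
phenotype fixtures are 72 s (4 steps of 6 cycles); the z-test calibration
uses 1000 null bin pairs of 150 samples each. A full
simulate-reconstruct cycle takes about two seconds.

## Known limitations

* Static synaptic conductance is inseparable from leak; only dynamic
  components are interpretable.
* Reversal-potential estimates inherit the space-clamp bias of the
  recording itself; no electrotonic correction is attempted.
* The wedge lower boundary is rarely identifiable in practice (excitation
  is seldom the only input), so $E_e$ usually falls back to the $-10$ mV
  convention; the sensitivity scan over $E_e \in [-20, 0]$,
  $E_i \in [-110, -90]$ mV quantifies how little the profile *shapes*
  depend on this.
* Phase binning presumes strictly phase-locked input; slow modulation
  across cycles is averaged into the profile and inflates residuals
  rather than being modeled.
* HDF5 input is not supported; the exchange format is delimited text.
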