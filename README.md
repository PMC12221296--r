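# syncond

Phase-resolved reconstruction of excitatory and inhibitory synaptic
conductances from single-neuron intracellular recordings in rhythmically
active networks.

## The problem

Neurons in central pattern generators (respiratory, locomotor, and other
rhythmic circuits) receive superimposed excitatory and inhibitory synaptic
input that varies with the phase of the network cycle. Disentangling the
two from one intracellular recording is the key step between cellular
electrophysiology and circuit-level ("functional connectome") inference.
`syncond` is for electrophysiologists who record rhythmic neurons under
stepwise current- or voltage-clamp protocols together with a reference
rhythm signal (e.g. phrenic nerve activity), and want per-phase conductance
profiles with errors, significance, and a first-pass connectivity reading.

## The method

The package assumes a passive membrane in instantaneous equilibrium
(membrane time constant `τ_m = C/g_leak ≈ 10 ms`, far shorter than the
cycle period, so `dVm/dt ≈ 0`) and phase-locked synaptic drive
`g(t) = g(φ(t))`, with the phase piece-wise linear between reference-burst
onsets. The cycle is divided into 100 phase bins; in each bin the samples
collected at different injected currents are fit by least squares,

    Vm = V0(φ) + R(φ) · Iinj,

giving the total conductance `G(φ) = 1/R(φ)` and effective resting
potential `V0(φ)`. Given the reversal potentials the total splits exactly:

    Gi = G (Ee − V0)/(Ee − Ei),   Ge = G (V0 − Ei)/(Ee − Ei).

Dynamic components `ΔGi, ΔGe` subtract each component's cycle minimum; the
sum of the minima estimates the leak. Errors propagate as
`δG = δR/R²` and `δΔG(φ) = sqrt(δG(φ)² + δG(φ_m)²)`, and each bin gets a
one-tailed z-test of `ΔG = 0`. The inhibitory reversal potential is
estimated from the upper boundary of the `(G, I0 = −G·V0)` "wedge diagram"
(slope `−Ei`); the excitatory one from the lower boundary when
identifiable, else the conventional −10 mV. Significant components are
classified by respiratory phase window (I / post-I / E2) and matched
against canonical population activity templates (pre-I/I, ramp-I, early-I,
late-I, post-I, aug-E) to propose signed functional connections.

A built-in conductance-based neuron simulator (forward Euler on the same
current-balance equation, with a synthetic burst-shaped nerve signal,
stepwise protocols, optional spiking and noise) provides ground truth for
parameter-recovery validation, including fixtures emulating the six
canonical respiratory firing phenotypes.

## Worked example

```r
library(syncond)

sim <- make_standard_fixture(seed = 1, noise_sd = 0.5)  # 150 s recording
fit <- syncond(sim$recording)
summary(fit)
```

```
Phase-resolved synaptic conductance reconstruction
  100 phase bins (100 valid), 48 cycles, period CV 0.000, QC passed
  leak estimate 11.41 nS; Ei -91.6 mV, Ee -10.0 mV (wedge/wedge)
  peak dGi 6.95 nS (76% bins significant); peak dGe 3.47 nS (68% bins significant)
  inputs by phase window:
    I       excitatory peak 3.47 nS at phase 0.10
    post_I  inhibitory peak 6.95 nS at phase 0.61
    E2      inhibitory peak 5.70 nS at phase 0.69
```

The fixture's ground truth is an inhibitory bell peaking at 8 nS above a
1 nS floor in the post-inspiratory/expiratory window and an excitatory
bell peaking at 4 nS above 0.5 nS around inspiration, on a 10 nS leak:
the reconstruction recovers the dynamic ranges (6.95 ≈ 7, 3.47 ≈ 3.5 nS),
the leak plus static floors (11.41 ≈ 11.5 nS), and the true reversal
potentials (−90, −10 mV) from the wedge boundaries alone.
`plot(fit)` draws the two profiles with error bars;
`plot(fit, which = "wedge")` the wedge diagram.

Connectome inference on a phenotype fixture:

```r
ph  <- make_phenotype_fixture("ramp-I", seed = 1, noise_sd = 0.5)
w   <- phase_windows(ph$truth$protocol$inspiratory_fraction)
pfit <- syncond(ph$recording, phenotype = "ramp-I", windows = w)
pfit$motifs
```

```
<motif_report> target: ramp-I
  pre-I/I -> ramp-I  [E2+I, score 1.00]
  aug-E -| ramp-I  [E2, score 1.00]
  post-I -| ramp-I  [post_I, score 0.99]
```

— exactly the source populations the fixture was built from, with the
correct signs.

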