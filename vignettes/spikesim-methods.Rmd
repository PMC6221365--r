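---
title: "spikesim: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spikesim: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`spikesim` re-creates, in software, a microcontroller-based teaching neuron
and the analyses used in its classroom experiments. This vignette is the
package's own account of the science: the models it integrates, the
conventions it fixes where the hardware left them implicit, and the
reasoning behind the choices that were genuinely open.

## The neuron and its integration

Each unit is the two-variable Izhikevich model,

$$\frac{dv}{dt} = 0.04v^2 + 5v + 140 - u + I, \qquad
  \frac{du}{dt} = a(bv - u),$$

with a hard reset: when $v$ reaches the 30 mV cutoff the sample is recorded
as a spike and $v \leftarrow c$, $u \leftarrow u + d$. A step landing exactly
on 30 mV counts as a spike. Currents are in the dimensionless "model units"
of these mV-scaled equations; no physical pA mapping is claimed.

**Integration.** The classic scheme for this model — forward Euler with two
half-steps for $v$ per full step of $u$ — is applied on an *internal substep
grid* of 10 µs (`n_sub` substeps per sampling step `dt`, default
`dt = 1` ms). The hardware integrates once per loop iteration at its loop
rate; doing the same at a 1 ms sampling step biases spike counts
substantially, because the quadratic upswing of a spike is much faster than
1 ms, and the bias grows with firing rate. With 10 µs substeps the spike
count of every shipped preset under a 10-s constant-current step agrees with
an independently coded reference integration at a 10 µs step to within one
spike, and counts at `dt = 1` ms and `dt = 0.5` ms agree likewise (both are
asserted in the test suite). `n_sub = 1` restores device-like coarse
integration for anyone who wants to study its artefacts.

**Reset bookkeeping.** The reset is checked on the state entering each
substep, and $v$ is clamped at the cutoff after integration, so no logged
sample exceeds 30 mV. On samples where the reset fired, the *logged*
membrane potential is the 30 mV spike peak — as the device streams it —
while the integrator continues from the post-reset trajectory. This makes
voltage-threshold spike detection work on logs that carry no spike flags.

**Initial state.** Simulations start at the stable fixed point of the
subthreshold dynamics under the initial drive
($0.04v^2 + (5-b)v + 140 + I = 0$), or at the reset potential when the drive
is already suprathreshold. Starting at rest avoids spurious onset transients
in stimulus-aligned analyses; what remains of the initial transient decays
over the first trial (trials agree to $\sim 10^{-4}$ mV thereafter).

## The preset table

Five modes pair canonical firing parameter sets with a photoreceptor
configuration:

| # | label | a | b | c | d | photo | tau (ms) | baseline |
|---|-------|---|---|---|---|-------|---------|----------|
| 1 | ON slow (regular spiking) | 0.02 | 0.2 | -65 | 8 | ON | 500 | 0 |
| 2 | OFF transient (bursting) | 0.02 | 0.25 | -50 | 6 | OFF | 50 | 0 |
| 3 | OFF sustained (dark-active) | 0.02 | 0.2 | -65 | 8 | OFF | 10000 | 6 |
| 4 | ON fast (fast spiking) | 0.1 | 0.2 | -65 | 2 | ON | 50 | 0 |
| 5 | ON slow (low-threshold spiking) | 0.02 | 0.25 | -65 | 2 | ON | 500 | 0 |

Mode identity is behavioural, not numeric: mode 1 must adapt under a light
step (onset rate above late rate), mode 2 must stay quiet in steady light
and fire a rebound burst at light offset, mode 3 must fire in darkness and
be suppressed by light; fast spiking must outrate regular spiking at equal
drive, and the burster's interspike intervals must split into intra-burst
(< 20 ms) and inter-burst (> 50 ms) groups.

The mode-2 constants deserve a note. The textbook "chattering" set
(c = -50, d = 2) bursts nicely under constant current, but two such units
wired to mutually excite each other cannot sustain a rhythm: across a grid
of synaptic gains and time constants the pair either falls silent once the
synaptic tail decays or locks up in runaway tonic firing. A grid search over
(a, b, c, d, gain, tau) found a region around a = 0.02, b = 0.25, c = -50,
d = 6 where burst termination (via the larger d) balances recurrent
excitation, giving self-sustained rhythmic bursting in both units. That set also bursts
under constant current and gives the rebound-burst light response, so it
serves as mode 2 throughout.

## Input channels

**Photoreceptor.** A first-order adapting transducer: the adaptation state
$A$ relaxes toward the light level $L$ with time constant $\tau$, and the
current is $\mathrm{polarity} \cdot \mathrm{gain}\cdot(L - A) +
\mathrm{baseline}$. This one high-pass stage, with $\tau$ = 500 ms ("slow")
or 50 ms ("fast"), reproduces all three light phenotypes and the slow/fast
filter-shape change probed by reverse correlation. $A$ starts adapted to the
initial light level. Light units are arbitrary; protocols use a step of 20,
which drives the regular-spiking preset at ~45 Hz at onset.

**Synapses.** Presynaptic spikes arrive as discrete events (the device's TTL
pulses; pulse width is ignored). Each event adds an instantaneous jump of
the signed gain to the port's current, which decays exponentially with
`tau_syn` (default 10 ms — a minimal model that sums linearly and gives the
expected excitatory/inhibitory gain sweeps). In networks the jump lands one
sampling step after the presynaptic spike: the conduction delay is exactly
one step.

**Membrane noise.** Zero-mean i.i.d. Gaussian per sample with the dialled
SD — the standard membrane-noise surrogate for a single-amplitude noise
dial. Each unit's stream is derived from the master seed and the unit id, so
adding a unit to a network does not perturb the noise of the others.

**Stimulus generator.** Square pulses at the dialled rate with the high
phase starting each period (rising edge at t = 0) and a 50% default duty
cycle; or frame-wise binary noise at 50 frames/s by default, levels
$\pm$amplitude symmetric about 0 (shifted to $\{0,$ amplitude$\}$ when the
stimulus drives the light path, since light is non-negative). The generated
stimulus is routed either to the analog-in port (scaled by the shared input
gain dial) or to the photodiode.

## Recording logs

Logs mirror the device's serial stream: one row per sample with `t` (ms),
`v` (mV), `u`, a 0/1 spike flag, every current component and their sum
`i_total`, the stimulus value, and 0/1 incoming-synapse event flags per
port. CSVs are comma-separated, '.' decimal, header row, no quoting. Numbers
are written with the shortest decimal representation that parses back to the
identical double, so write → read → write is byte-identical — and with
seeded noise, identical configuration plus seed reproduces identical bytes
end to end. Readers tolerate column subsets (only `t` and `v` are
mandatory), reject non-uniform time grids naming the first offending row,
and warn (not fail) when `i_total` disagrees with the sum of its components.

## Analysis conventions

- **Spike detection**: logged flags are authoritative; the fallback for
  flag-less logs is upward 0 mV crossings with a 2 ms refractory merge.
- **Tuning metrics** per stimulus trial: spike count; instantaneous rate
  defined as 1/(first interspike interval); first-spike latency; jitter as
  the SD of latency across trials. A noise-free simulation has exactly zero
  jitter, which anchors the "noise distorts timing before counts" check.
- **Vector strength**: $|\sum_k e^{i\theta_k}|/N$ with phase 0 at the
  stimulus rising edge. Significance uses phase-shuffled surrogates (1000
  resamples of uniform phases at the observed spike count, seeded), not a
  parametric test.
- **Spike-triggered average**: mean stimulus segment preceding each spike,
  on the stimulus *frame* grid, lag axis most-recent-first (lag 0 = the
  frame containing the spike). Spikes earlier than one full window are
  excluded and counted. The STA is reported in stimulus units; the
  subthreshold filter is the cross-correlation of mean-subtracted `v` with a
  zero-mean stimulus normalised by stimulus variance, so an identity system
  yields a unit impulse.
- **Filter shape**: lobes below 30% of the peak magnitude are ignored when
  counting sign changes. The threshold sits between the two lobe classes the
  package produces: the slow photoreceptor's secondary lobe is well below
  it, the fast variant's well above (the protocol checks assert the
  resulting 0- vs 1-sign-change classification). The spike-level shape of the fast variant is reported but not asserted —
  its lobe structure depends on details the behavioural contracts do not
  pin down.

## Protocol settings and problem sizes

The scripted experiments use fixed, documented settings chosen once:
amplitude tuning sweeps gains 0–8 over ten 1-s pulses; volley coding drives
mode 1 at 30 Hz (amplitude 8) for 20 s, where it fires on half the cycles;
stochastic resonance uses a 4 Hz square of amplitude 2.5 — verified
subthreshold at zero noise — with noise SDs 0, 0.6, 1, 2, 4, 8 over 20 seeds
per level; the synaptic gain sweep covers -10 to +10 against a target held
at 6 units of static current; the CPG runs two mode-2 units with mutual
gain-4 excitation and a 60 ms synapse for 25 s after a 200 ms kick (the
slower synapse bridges the inter-burst gaps; at 10 ms the rhythm cannot
bridge them at any gain); reverse correlation records 300 s of 50 Hz binary
light noise, giving roughly 5000 spikes per variant. These sizes complete in
seconds on one CPU while leaving the measured statistics far from their
decision boundaries.

## What the simulator does and does not emulate

It emulates the device's logical behaviour: the model, the channel mix, the
dials, the stimulus generator, network wiring with a one-step delay, and the
log format. It does not emulate hardware loop-rate variability (a fixed `dt`
grid is assumed), photodiode optics or electrical voltage scales, real-time
execution, or audio/LED output. Passing tests therefore demonstrate the
computational phenomena — adaptation, tuning, phase locking, stochastic
resonance, CPG dynamics, filter estimation — not timing quirks of a
particular board; logs from a physical device can still be analysed, since
the analysis layer needs only `t` and `v` plus optional flags.

## Known limitations

- The noise dial is i.i.d. Gaussian per sample; its spectrum therefore
  depends on `dt` (white up to the Nyquist of the sampling grid).
- Synaptic currents are single-exponential with a shared `tau_syn` per
  simulation, not per edge.
- The stimulus generator occupies synapse port 1 exclusively; the hardware's
  reconfigurable port semantics are modelled as a mode switch.
- Spike times are quantised to the sampling grid (`dt`), which bounds
  vector-strength and latency resolution at fast stimulus rates.
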