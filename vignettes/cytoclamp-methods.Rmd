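---
title: "The equivalent-circuit model behind cytoclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The equivalent-circuit model behind cytoclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoclamp)
```

## The problem

Cytoplasmic microinjection of small adherent cells (neuroblastoma SHSY-5Y,
embryonic kidney HEK-293; under 30 µm across, under 10 µm thick) is hard to
monitor optically: the moment of membrane penetration and the success of the
delivery are not visible. `cytoclamp` implements an electrical view of the
procedure. The cell-pipette system under whole-cell voltage clamp is modelled
as an equivalent circuit, the injection as a battery that appears when the
injected solution mixes with the cytoplasm, and success as a permanent,
threshold-crossing drop in the holding current. The package is a forward
simulator of such recordings plus the measurement layer an automated
injection controller would need: test-pulse resistance estimation, drop
detection, viability classification and the threshold feedback loop.

## Electrochemistry

Solutions are given as salt recipes (mM of NaCl, KCl, KF, MgCl₂, CaCl₂).
`dissociate()` expands them stoichiometrically into free-ion concentrations;
solutes that contribute no free ions (glucose, HEPES, EGTA) are ignored with
a note, as are the unstated NaOH/KOH pH-adjustment additions. Full
dissociation is assumed; activity coefficients, ionic-strength corrections
and buffer binding are out of scope.

Each ion's equilibrium potential is the Nernst potential

$$E = \frac{RT}{ZF}\,\ln\frac{[\mathrm{ion}]_o}{[\mathrm{ion}]_i},$$

with $R = 8.314472$ J K⁻¹ mol⁻¹ and $F = 9.648533\times10^4$ C mol⁻¹ fixed
package-wide. The membrane battery is the plain *additive sum* of the
per-ion Nernst terms over a caller-chosen ion list — deliberately not a
conductance-weighted GHK potential; that is the model's own simplification,
and ions deemed negligible are excluded by the caller rather than silently
dropped. With the standard two-ion list (Na⁺, K⁺) and the shipped solution
recipes this gives the familiar −90 mV potassium and +60 mV sodium
batteries.

Injection mixes the injectate into the cytoplasm instantaneously and
conservatively: $c_\mathrm{new} = (c_\mathrm{cyto}V_\mathrm{cell} +
c_\mathrm{inj}V_\mathrm{inj})/(V_\mathrm{cell}+V_\mathrm{inj})$, with the
bath side untouched and no osmotic volume change. The injection battery is
the difference of the membrane battery after and before mixing
(`injection_potential()`). Temperature defaults to 298.15 K (room
temperature, configurable per composition); the default cell volume of
2.5 pL is an ellipsoid estimate for these cells and is only ever a default
argument, never hard-coded.

## The circuit

Units are fixed at mV / nA / MΩ / pF / µS / ms, which are mutually
consistent (mV/MΩ = nA, µS·mV = nA, MΩ·pF = µs) and match the scales of
every quantity in the model. The circuit has two nodes. The pipette node is
clamped to the piecewise-constant command (the source resistance defaults to
0 — an ideal clamp; no value is established for it). The membrane node obeys

$$C_M \frac{dV_m}{dt} = \frac{V_\mathrm{cmd} - V_m}{R_\mathrm{Access}}
 - \sum_\mathrm{branches} g(t)\,(V_m - E),$$

with Ohmic channel branches $I = (V_m - E)/R_\mathrm{ion}$. The seal path is
modelled as always present with a finite resistance (default 1000 MΩ) so the
gigaseal-test behaviour is simulable; setting it to `Inf` recovers the
idealisation in which the seal branch is an open circuit. The pipette
capacitance produces one-sample impulses at command edges
($I = C\,dV/dt$ is a delta under an ideal source); the
`compensate_pipette` option cancels them exactly, mirroring the amplifier's
capacitance-neutralisation setting.

**Gating.** The model only requires that the channel resistances vary with
channel activity, so the kinetics are a package design choice: a single
Boltzmann activation gate for the delayed-rectifier-like K⁺ branch
($V_{1/2} = -20$ mV, slope 10 mV, τ = 5 ms) and $m\cdot h$ for the Na⁺
branch (activation $V_{1/2} = -25$ mV, slope 6 mV, τ = 0.3 ms; inactivation
$V_{1/2} = -60$ mV, slope −7 mV so $h$ falls with depolarisation, τ = 3 ms).
These defaults reproduce the qualitative step-family signatures — a fast
transient inward Na⁺ current at intermediate depolarised steps and a
sustained, monotonically growing outward K⁺ current at the strongest steps
— and every constant is configurable. The "other ions" branch is a fixed
leak conductance, default 0. Maximal conductances in the shipped presets
(K 0.1 µS; Na 0.3 µS for SHSY-5Y, 0 for HEK-293, which shows
potassium-only activity) put the simulated currents on the nA scale of real
recordings.

**Injection branch.** Closing the injection switch contributes
$I_\mathrm{Injection} = E_\mathrm{Injection}/R_\mathrm{Access}$ as a
permanent offset superposed on the access current — exactly the model's
reading of the resting-state measurement, where all channel switches are
open and the measured current *is* the injection drop. Because the circuit
is linear, this superposition is exact and is also asserted as a test
invariant.

**Calibration.** `calibrate_access_pair()` inverts the drop relation:
given the observed mean accumulated drop (−11.9 nA for SHSY-5Y, −11.7 nA
for HEK-293) and the estimated −0.3 mV injection battery, it returns
$R_\mathrm{Access} \approx 0.025$ MΩ — far below the 4–8 MΩ pipette range
measured in the bath. The function warns about this tension rather than
resolving it; the shipped presets therefore keep a physiological 5 MΩ
access resistance for the circuit dynamics (giving realistic 0.15 ms
capacitive transients) and use the calibrated pair only to set the
injection-branch amplitude. The two are reconciled only by the data the
model was built from, and the package keeps both numbers visible.

## Numerics

The solver is an exponential integrator: over each sample step the
conductances are frozen, making the membrane equation linear with an exact
single-exponential solution, and the gates are then advanced by their own
exact first-order relaxation. Channels-closed responses are therefore exact
to machine precision at any admissible `dt`, and the gated error is
$O(\Delta t)$ in the conductance freeze only. `dt` must resolve the access
time constant ($dt \le R_\mathrm{Access} C_M / 10$, i.e. 0.015 ms for the
shipped whole-cell presets); the package default of 0.01 ms (100 kHz)
satisfies this bound for full experiments as well as single transients.
When no gated branch is active the simulator takes a vectorised closed-form
path per command segment, which keeps batch generation (hundreds of
episodes) at interactive speed.

Two numerical facts shape the test tolerances. First, the capacitive
current after a step falls as $e^{-t/\tau}$, so "the plateau" is taken from
$8\tau$ after an edge, where the envelope is below 0.1% of the peak (at
$5\tau$ it is still 0.67%). Second, the uncompensated pipette impulse
occupies exactly one sample and scales as $1/\Delta t$, like the physical
delta, so grid-convergence of traces is assessed with compensation on.

## The synthetic-experiment generator

`run_experiment()` turns a declarative script (stage timeline, injection
events, holding level, seal-test pulse, noise model, seed) into a recording
plus complete ground truth. It emulates:

- the five-stage procedure, with the bath pipette resistance drawn from
  4–8 MΩ, the approach increment from 3–5 MΩ, and the gigaseal at 1 GΩ;
- repeated 20 mV / 10 ms test pulses during the pre-whole-cell stages and a
  constant −70 mV holding level afterwards;
- injection events as permanent drops, each the preset's calibrated mean
  perturbed by a per-event amplitude noise (defaults 0.2 / 0.4 nA for the
  two cell presets, matching the observed episode-to-episode spread);
- Gaussian sample noise (default 0.05 nA, small enough that the event
  spread dominates), optional linear drift, and baseline zeroing at the
  start of whole-cell holding.

Randomness is split into named streams (stage draws, event amplitudes,
sample noise) derived from the one seed, so changing the noise level does
not move the event amplitudes. Identical scripts and seeds give identical
traces.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: electrode drift and offset instability, line
interference and 1/f noise, seal degradation over time, capacitance
compensation errors, the several-millisecond finite onset of real drops
(an optional exponential onset exists but the default is instantaneous),
pressure/suction fluidics, and any optical channel. The printed-number
round trips are consistency checks of the simulate → measure pipeline, not
physics validation: the presets are calibrated from the same printed means
the pipeline recovers.

## The measurement layer

**Resistance.** `estimate_resistance()` applies Ohm's law to the test
pulse: amplitude over the plateau current change, the plateau being the
last 20% of the pulse and the reference the settled pre-pulse level. When
the change is below a 3-standard-error noise floor the estimate is reported
as a lower bound instead of a point value.

**Drop detection.** The recordings behind the model were read by eye, so
the detector is a defined surrogate: leading/trailing moving-window means
(5 ms windows, 1 ms gap) around each candidate sample; a step is declared
when their difference exceeds 6 robust noise sds and persists for at least
10 ms. The noise sd is the median absolute deviation of the
first-difference signal divided by √2, which is insensitive to the very
steps being sought. Window lengths are defaults tuned to the generator's
event spacing and are all exposed as parameters. The accumulated drop is
final minus initial steady level, and "success" means the accumulated drop
is at or below the −11 nA threshold — "lower than the threshold" read as
more-negative-than, matching the downward sign of injection drops. Ties in
the window-difference maximum (exact in noise-free traces) resolve to the
centre of the flat maximum, which lands on the true transition.

**Viability.** `classify_viability()` reads a step family (−80 to +100 mV,
60 ms epochs, holding −70 mV). Per level it removes the known seal leak
(from trace metadata), re-references to the settled pre-step level,
excludes a capacitive window of $10 R_\mathrm{Access} C_M$ (else 2 ms)
after each edge, and measures a late-window mean (last 20 ms of the epoch)
and an early-window minimum (first 5 ms after exclusion). K⁺ activity
requires outward late currents above threshold at the three most
depolarised steps, growing monotonically with level; Na⁺ activity requires
an early inward peak below threshold at some depolarised step. The activity
threshold is 5 noise sds with the sd floored at 0.01 nA: channel currents
are nA-scale, and sub-0.05 nA offsets (rest-state leak re-referencing,
seal-correction residue) are below anything an operator would read as
channel activity. No multiple-testing correction is applied across levels —
the reading is deliberately the qualitative present/absent one. The verdict
is *viable* exactly when K⁺ is active: sustained potassium activity is the
viability signature, and sodium may legitimately disappear after the
injection redistributes intracellular Na⁺.

**Control loop.** `control_loop()` is the feedback strategy around the
injection: detect after each episode segment, accumulate the measured
drops, emit `retry` until the running total crosses the threshold, then
`success` and stop. The upstream visual positioning and automated patching
stages are represented as pre-satisfied steps.

## Problem sizes

The test-suite and acceptance computations use: 10 episodes per cell preset
for the mean-drop round trips (per-episode sds 0.2 / 0.4 nA, trace noise
0.05 nA); 500 noisy events (50 scripts × 10 events at 0.2 nA noise) for
detector recall/precision; 10-level step families at 0.01 ms sampling for
the viability grid; and single test pulses for the stage-resistance
checks. These sizes put every stochastic check comfortably inside its CLT
tolerance while keeping the whole suite around a minute of CPU.

## Known limitations

- The additive multi-ion battery is not a physical membrane potential
  model (no conductance weighting); it is implemented as specified by the
  equivalent-circuit model.
- The −0.3 mV battery / −11.9 nA drop pair implies an access resistance
  ~200× below the measured pipette range; the package surfaces the
  inconsistency (calibration warning) but cannot resolve it.
- Mixing arithmetic for the post-injection concentrations depends on the
  unstated pre-injection cytoplasm and cell volume; all of these are
  exposed as inputs and nothing is hard-coded to reproduce the printed
  −0.3 mV.
- The detector and classifier are surrogates for by-eye readings; their
  thresholds are calibrated against the generator, not against deposited
  recordings (none exist).
- No current clamp, action potentials, Markov channel models, temperature
  dependence of kinetics, or series-resistance compensation circuitry.
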