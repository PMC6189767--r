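# cytoclamp

Equivalent-circuit simulation and current-feedback analysis of cell
cytoplasmic microinjection under whole-cell voltage clamp.

## What it is for

Microinjecting small adherent cells (SHSY-5Y neuroblastoma, HEK-293
embryonic kidney; < 30 µm across) cannot be monitored visually: neither the
moment of penetration nor the success of the delivery is observable through
the microscope. An electrical route works instead: with the pipette in
whole-cell configuration and the membrane clamped at −70 mV, a successful
injection produces a *permanent drop* of the holding current (about −12 nA
for these cells), and post-injection viability can be read from the
ion-channel currents evoked by a voltage-step family. `cytoclamp` implements
this model end to end for people building or studying automated injection
systems: a forward simulator of the recordings, and the measurement layer a
current-feedback controller needs.

## The model

The cell-pipette system is an equivalent circuit: seal resistance
$R_\text{Seal}$, access resistance $R_\text{Access}$, membrane capacitance
$C_M$, pipette capacitance $C_\text{Pipette}$, and Ohmic channel branches
with batteries at the ionic equilibrium (Nernst) potentials

$$E = \frac{RT}{ZF}\ln\frac{[\text{ion}]_o}{[\text{ion}]_i},$$

giving $E_K \approx -90$ mV and $E_{Na} \approx +60$ mV for the standard
extracellular/intracellular solutions. The membrane battery is the additive
sum of Nernst terms over the dominant ions. Injecting intracellular
solution mixes conservatively into the cytoplasm, shifts that battery, and
the difference appears as an injection battery $E_\text{Injection}$; at
rest, with all channel switches open, the measured current is

$$I_m = I_\text{Injection} = \frac{E_\text{Injection}}{R_\text{Access}},$$

the permanent drop used as the success signal (threshold ≈ −11 nA). The
measured current decomposes as
$I_m = I_\text{Pipette} + I_\text{Seal} + I_C + I_\text{Access}$ with
$I_\text{Access} = I_{Na} + I_K + I_\text{Other} + I_\text{Injection}$,
and both identities hold sample-wise on every simulated trace. Channel
branches use Boltzmann gating (single activation gate for K⁺, activation ×
inactivation for Na⁺). See the methods vignette
(`vignettes/cytoclamp-methods.Rmd`) for the full account, including the
deliberate tension between the calibrated injection pair and the 4–8 MΩ
pipette resistance.

## Worked example

```r
library(cytoclamp)

# batteries from the shipped solution recipes
nernst_potential("K", 4.5, 149.6)    # -90.0 mV
nernst_potential("Na", 160, 15.48)   #  +60.0 mV

# one seeded injection episode with the SHSY-5Y preset
sx <- run_experiment(
  injection_episode_script(seed = 7, event_sd_nA = 0.2, noise_sd_nA = 0.05),
  circuit_preset("shsy5y"))
detect_injection_drops(sx$trace)
#> Injection detection: 1 event(s); accumulated drop -11.754 nA (threshold -11.0 nA) -> SUCCESS
#>   t = 99.79 ms, step -11.749 nA

# gigaseal check: 20 mV / 10 ms test pulse on a sealed-stage trace
sealed <- stage_parameters("SEALED", circuit_preset("shsy5y"))
estimate_resistance(
  simulate_voltage_clamp(sealed, test_pulse_protocol(), dt_ms = 0.01))
#> Total resistance: 1000 MOhm (dV = 20 mV, dI = 0.02 nA)
```

The detector reports the one scripted event: a permanent −11.75 nA step
(the preset's calibrated −11.9 nA mean perturbed by the 0.2 nA per-episode
noise) at the scripted time, which crosses the −11 nA threshold, so the
control loop would declare the injection successful. The sealed-stage
estimate reads back the 1 GΩ seal from the 0.02 nA pulse response.

A command-line surface wraps the same functions:

```sh
inst/exec/cytoclamp simulate --preset shsy5y --seed 1 --out trace.csv
inst/exec/cytoclamp detect --in trace.csv
inst/exec/cytoclamp nernst --ion K --out-mM 4.5 --in-mM 149.6
```

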