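# Intracellular (pipette / injectate) solution recipe.
# pH adjusted to 7.2-7.4 with KOH in the wet protocol; amount unstated,
# ignored here.
label: intracellular
temperature_K: 298.15
salts:
  KCl: 75
  NaCl: 10
  KF: 70
  MgCl2: 2
nondissociating:
  HEPES: 10
  EGTA: 10
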