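# Extracellular (bath) solution recipe.
# pH adjusted to 7.4 with NaOH in the wet protocol; the adjustment amount is
# unstated and contributes no tracked ions here.
label: extracellular
temperature_K: 298.15
salts:
  NaCl: 160
  KCl: 4.5
  MgCl2: 1
  CaCl2: 2
nondissociating:
  glucose: 5
  HEPES: 10
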