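# Whole-cell preset for SHSY-5Y neuroblastoma cells: both potassium and
# sodium channel branches available.  The calibration block records the
# observed mean accumulated injection drop and the estimated injection
# battery; the injection-branch access resistance is derived from them at
# load time.
label: shsy5y
r_seal_Mohm: 1000
r_access_Mohm: 5
c_m_pF: 30
c_pipette_pF: 4
r_opamp_Mohm: 0
e_k_mV: -90
e_na_mV: 60
e_other_mV: 0
gating:
  k:
    g_max_uS: 0.1
    v_half_mV: -20
    slope_mV: 10
    tau_ms: 5
  na:
    g_max_uS: 0.3
    v_half_mV: -25
    slope_mV: 6
    tau_act_ms: 0.3
    h_v_half_mV: -60
    h_slope_mV: -7
    tau_inact_ms: 3
  other:
    g_uS: 0
calibration:
  mean_drop_nA: -11.9
  e_injection_mV: -0.3
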