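# Shared fixtures: everything is generated in code at test time.

shsy5y <- circuit_preset("shsy5y")
hek293 <- circuit_preset("hek293")

extracellular <- dissociate(
  read_recipe(system.file("extdata", "extracellular.cfg",
                          package = "cytoclamp")), quiet = TRUE)
intracellular <- dissociate(
  read_recipe(system.file("extdata", "intracellular.cfg",
                          package = "cytoclamp")), quiet = TRUE)

# One injection episode (or several) simulated from a preset.
sim_episode <- function(seed, preset = shsy5y, n_events = 1,
                        event_sd = 0, noise_sd = 0, dt_ms = 0.01, ...) {
  run_experiment(
    injection_episode_script(seed = seed, n_events = n_events,
                             event_sd_nA = event_sd,
                             noise_sd_nA = noise_sd, ...),
    preset, dt_ms = dt_ms)
}

# Step-family responses for a given conductance combination.
sim_step_family <- function(g_k = 0.1, g_na = 0.3, base = shsy5y,
                            dt_ms = 0.01) {
  p <- base
  p$switch <- switch_state(s_k = "closed", s_na = "closed")
  p$gating$k$g_max_uS <- g_k
  p$gating$na$g_max_uS <- g_na
  lapply(step_family(), function(prot)
    simulate_voltage_clamp(p, prot, dt_ms = dt_ms))
}

# Closed-form single-exponential response of the channels-closed circuit to
# a command step: independent oracle for the simulator.
rc_step_oracle <- function(t_ms, dV_mV, r_access_Mohm, c_m_pF) {
  tau <- r_access_Mohm * c_m_pF / 1000
  (dV_mV / r_access_Mohm) * exp(-t_ms / tau)
}
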