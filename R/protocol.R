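#' Experimental stages of the microinjection procedure
#'
#' The five-step whole-cell microinjection procedure as a forward-only stage
#' sequence: pipette in the bath, approach and contact with the cell
#' surface, gigaseal formation, whole-cell holding at the clamp potential,
#' injection, and post-injection monitoring.
#' @export
protocol_stages <- c("BATH", "APPROACH", "SEALED", "WHOLE_CELL_HOLDING",
                     "INJECTING", "POST_INJECTION")

#' Piecewise-constant voltage-command protocol
#'
#' @param level_mV Command levels (mV), one per segment.
#' @param duration_ms Segment durations (ms), all > 0.
#' @param repeats Number of times the segment list is repeated.
#' @return An object of class `voltage_protocol` (a data frame with columns
#'   `level_mV`, `duration_ms`).
#' @examples
#' voltage_protocol(c(0, 20, 0), c(10, 10, 5))
#' @export
voltage_protocol <- function(level_mV, duration_ms, repeats = 1L) {
  stopifnot(length(level_mV) == length(duration_ms), length(level_mV) > 0)
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0))
    stop("protocol segment durations must be > 0", call. = FALSE)
  df <- data.frame(level_mV = rep(as.numeric(level_mV), repeats),
                   duration_ms = rep(as.numeric(duration_ms), repeats))
  class(df) <- c("voltage_protocol", "data.frame")
  df
}

#' Coerce to a voltage protocol
#' @param x A `voltage_protocol` or a data frame with `level_mV` and
#'   `duration_ms` columns.
#' @return A [voltage_protocol()].
#' @export
as_voltage_protocol <- function(x) {
  if (inherits(x, "voltage_protocol")) return(x)
  if (is.data.frame(x) && all(c("level_mV", "duration_ms") %in% names(x)))
    return(voltage_protocol(x$level_mV, x$duration_ms))
  stop("cannot interpret object as a voltage protocol", call. = FALSE)
}

#' Seal-test pulse protocol
#'
#' The standard membrane test: a square pulse (default 20 mV for 10 ms)
#' from a base level, with settle time before and after.
#'
#' @param amplitude_mV Pulse amplitude above `base_mV`.
#' @param duration_ms Pulse width (ms).
#' @param base_mV Level outside the pulse.
#' @param pre_ms,post_ms Settle segments before/after the pulse.
#' @return A [voltage_protocol()].
#' @export
test_pulse_protocol <- function(amplitude_mV = 20, duration_ms = 10,
                                base_mV = 0, pre_ms = 10, post_ms = 5) {
  voltage_protocol(c(base_mV, base_mV + amplitude_mV, base_mV),
                   c(pre_ms, duration_ms, post_ms))
}

#' Family of voltage-step protocols
#'
#' One protocol per step level from `start_mV` to `stop_mV`: a holding
#' pre-segment, the step held for `epoch_ms`, and a holding post-segment.
#' The default family (-80 to +100 mV in 20 mV increments, 60 ms epoch)
#' is the stimulus used to probe ion-channel activity.
#'
#' @param start_mV,stop_mV First and last step level (mV);
#'   `stop_mV >= start_mV`.
#' @param increment_mV Level spacing, > 0.
#' @param epoch_ms Step duration (ms).
#' @param holding_mV Holding level before and after the step.
#' @param pre_ms,post_ms Holding durations around the step.
#' @return A named list of [voltage_protocol()]s, one per level; names are
#'   the levels in mV.
#' @examples
#' length(step_family())   # 10 levels: -80, -60, ..., 100
#' @export
step_family <- function(start_mV = -80, stop_mV = 100, increment_mV = 20,
                        epoch_ms = 60, holding_mV = -70,
                        pre_ms = 20, post_ms = 20) {
  stopifnot(increment_mV > 0, stop_mV >= start_mV)
  levels <- seq(start_mV, stop_mV, by = increment_mV)
  out <- lapply(levels, function(lv)
    voltage_protocol(c(holding_mV, lv, holding_mV),
                     c(pre_ms, epoch_ms, post_ms)))
  names(out) <- levels
  out
}

#' Noise model for synthetic experiments
#'
#' @param gaussian_sd_nA Per-sample white-noise standard deviation (nA).
#' @param drift_nA_per_s Linear baseline drift rate (nA/s).
#' @param event_sd_nA Standard deviation of the per-event injection-drop
#'   amplitude (nA), emulating episode-to-episode spread.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd_nA = 0.05, drift_nA_per_s = 0,
                        event_sd_nA = 0) {
  if (gaussian_sd_nA < 0 || drift_nA_per_s < 0 || event_sd_nA < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(gaussian_sd_nA = gaussian_sd_nA,
                 drift_nA_per_s = drift_nA_per_s,
                 event_sd_nA = event_sd_nA), class = "noise_model")
}

# One named random stream per purpose so changing one draw set does not
# shift the others.  Stream ids: 1 stage resistances, 2 event amplitudes,
# 3 sample noise.
.stream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 7 + id * 1000003) %% 2147483647)
}

#' Stage-specific circuit parameters
#'
#' Maps a procedure stage onto circuit parameters: in the bath the pipette
#' sees only its own resistance (drawn from 4-8 MOhm); on approach the
#' total rises by a drawn 3-5 MOhm increment; after gigaseal formation the
#' total is the seal resistance (1 GOhm by default); from whole-cell access
#' onward the full circuit (access resistance and membrane capacitance) is
#' active.  Pre-whole-cell stages have no membrane branch (`c_m_pF = 0`).
#'
#' Draws use the current RNG state; seed via [set.seed()] or let
#' [run_experiment()] manage its stage stream.
#'
#' @param stage One of [protocol_stages].
#' @param base A [circuit_parameters()] object (the whole-cell parameters).
#' @param bath_Mohm Optional pre-drawn bath resistance, so APPROACH can be
#'   made consistent with a given BATH draw.
#' @return A [circuit_parameters()] object with extra fields `stage` and
#'   `stage_total_Mohm` (the ground-truth DC resistance of the stage).
#' @export
stage_parameters <- function(stage, base, bath_Mohm = NULL) {
  stage <- match.arg(stage, protocol_stages)
  stopifnot(inherits(base, "circuit_parameters"))
  params <- base
  if (stage %in% c("BATH", "APPROACH", "SEALED")) {
    total <- switch(stage,
      BATH = if (is.null(bath_Mohm)) stats::runif(1, 4, 8) else bath_Mohm,
      APPROACH = {
        b <- if (is.null(bath_Mohm)) stats::runif(1, 4, 8) else bath_Mohm
        b + stats::runif(1, 3, 5)
      },
      SEALED = base$r_seal_Mohm)
    params$r_seal_Mohm <- total
    params$c_m_pF <- 0
    params$switch <- switch_state()  # no cell access: channel branches open
  } else {
    total <- base$r_seal_Mohm
  }
  params$stage <- stage
  params$stage_total_Mohm <- total
  params
}

#' Script of a synthetic microinjection experiment
#'
#' A declarative description of one experiment: the stage timeline, the
#' injection events, the holding level, the seal-test pulse used in
#' pre-whole-cell stages, the noise model and the seed.  Pressure and
#' suction mechanics exist only as the stage transitions themselves.
#'
#' @param seed Integer seed; mandatory (every stochastic element derives
#'   from it through named streams).
#' @param stages Data frame with columns `stage` (values from
#'   [protocol_stages], in forward order) and `start_ms` (strictly
#'   increasing, first at 0).
#' @param duration_ms Total experiment length (ms).
#' @param injections Data frame with column `time_ms` (strictly increasing)
#'   and optional `volume_pL` (default 19); times must fall at or after the
#'   INJECTING stage start.
#' @param holding_mV Whole-cell holding level; default -70.
#' @param test_pulse List `amplitude_mV`, `duration_ms`, `period_ms` for the
#'   repeated seal-test pulse in BATH/APPROACH/SEALED stages.
#' @param noise A [noise_model()].
#' @param onset_tau_ms Time constant of the drop onset (ms); 0 (default)
#'   applies each drop instantaneously, a positive value ramps it in as
#'   `1 - exp(-t/tau)`, emulating the few-millisecond settling of real
#'   drops.
#' @param injection_source `"calibration"` (use the preset's calibrated
#'   injection pair) or a list with elements `outside`, `cytoplasm`,
#'   `injectate` ([ionic_composition()]s), `cell_volume_pL` and `ions`,
#'   in which case each event's battery is computed by mixing.
#' @return An object of class `experiment_script`.
#' @export
experiment_script <- function(seed,
                              stages = data.frame(
                                stage = c("WHOLE_CELL_HOLDING", "INJECTING"),
                                start_ms = c(0, 90)),
                              duration_ms = 300,
                              injections = data.frame(time_ms = 100),
                              holding_mV = -70,
                              test_pulse = list(amplitude_mV = 20,
                                                duration_ms = 10,
                                                period_ms = 25),
                              noise = noise_model(),
                              onset_tau_ms = 0,
                              injection_source = "calibration") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stages$stage <- as.character(stages$stage)
  if (!all(stages$stage %in% protocol_stages))
    stop("unknown stage name in timeline", call. = FALSE)
  ord <- match(stages$stage, protocol_stages)
  if (is.unsorted(ord, strictly = TRUE))
    stop("stages must appear in forward order without repeats", call. = FALSE)
  if (stages$start_ms[1] != 0 || is.unsorted(stages$start_ms, strictly = TRUE))
    stop("stage start times must begin at 0 and increase strictly",
         call. = FALSE)
  if (max(stages$start_ms) >= duration_ms)
    stop("duration_ms must extend past the last stage start", call. = FALSE)
  if (!is.null(injections) && nrow(injections)) {
    if (is.unsorted(injections$time_ms, strictly = TRUE))
      stop("injection event times must be strictly increasing", call. = FALSE)
    inj_start <- stages$start_ms[stages$stage == "INJECTING"]
    if (!length(inj_start))
      stop("injections scheduled but no INJECTING stage in the timeline",
           call. = FALSE)
    if (any(injections$time_ms < inj_start))
      stop("injection scheduled before whole-cell injection stage",
           call. = FALSE)
    if (is.null(injections$volume_pL)) injections$volume_pL <- 19
  }
  stopifnot(inherits(noise, "noise_model"), onset_tau_ms >= 0)
  structure(list(seed = as.integer(seed), stages = stages,
                 duration_ms = duration_ms, injections = injections,
                 holding_mV = holding_mV, test_pulse = test_pulse,
                 noise = noise, onset_tau_ms = onset_tau_ms,
                 injection_source = injection_source),
            class = "experiment_script")
}

#' Convenience script: one or more injection episodes at holding
#'
#' Whole-cell holding at `holding_mV` with `n_events` injection events,
#' used throughout the tests and the acceptance analysis.
#'
#' @param seed Integer seed.
#' @param n_events Number of injection events.
#' @param pre_ms Holding time before the first event.
#' @param spacing_ms Time between events.
#' @param post_ms Holding time after the last event.
#' @param event_sd_nA,noise_sd_nA Noise model shortcuts.
#' @param holding_mV Holding level (mV).
#' @return An [experiment_script()].
#' @export
injection_episode_script <- function(seed, n_events = 1, pre_ms = 100,
                                     spacing_ms = 100, post_ms = 100,
                                     event_sd_nA = 0, noise_sd_nA = 0,
                                     holding_mV = -70) {
  times <- pre_ms + (seq_len(n_events) - 1) * spacing_ms
  experiment_script(
    seed = seed,
    stages = data.frame(stage = c("WHOLE_CELL_HOLDING", "INJECTING"),
                        start_ms = c(0, max(pre_ms - 10, 1))),
    duration_ms = max(times) + post_ms,
    injections = data.frame(time_ms = times),
    holding_mV = holding_mV,
    noise = noise_model(gaussian_sd_nA = noise_sd_nA,
                        event_sd_nA = event_sd_nA))
}

# Protocol for one stage segment of a scripted experiment.
.stage_protocol <- function(stage, seg_ms, script) {
  if (stage %in% c("BATH", "APPROACH", "SEALED")) {
    tp <- script$test_pulse
    rest <- tp$period_ms - tp$duration_ms
    ncycle <- max(1L, floor(seg_ms / tp$period_ms))
    prot <- voltage_protocol(rep(c(0, tp$amplitude_mV), ncycle),
                             rep(c(rest, tp$duration_ms), ncycle))
    leftover <- seg_ms - ncycle * tp$period_ms
    if (leftover > 1e-9)
      prot <- voltage_protocol(c(prot$level_mV, 0),
                               c(prot$duration_ms, leftover))
    prot
  } else {
    voltage_protocol(script$holding_mV, seg_ms)
  }
}

#' Run a scripted synthetic experiment
#'
#' Simulates the scripted stage timeline with [simulate_voltage_clamp()]
#' under [stage_parameters()], applies each injection event as a permanent
#' current offset (battery over calibrated access resistance, perturbed by
#' the per-event amplitude noise), adds seeded Gaussian noise and drift,
#' zeroes the baseline at the start of whole-cell holding, and returns the
#' trace together with the complete generating ground truth.
#'
#' @param script An [experiment_script()].
#' @param base A [circuit_parameters()] object, typically a
#'   [circuit_preset()]; the preset's calibration supplies the injection
#'   pair when `injection_source = "calibration"`.
#' @param dt_ms Sample interval; the default 0.01 ms resolves the access
#'   transient of the shipped whole-cell presets.
#' @return An object of class `synthetic_experiment`: list with `trace`
#'   (a [current_trace()] with event annotations) and `truth` (stage table
#'   with per-stage total resistance, event times and true drop amplitudes,
#'   channel-activity flags, baseline offset, seed).
#' @examples
#' sx <- run_experiment(injection_episode_script(seed = 7),
#'                      circuit_preset("shsy5y"))
#' sx$truth$events
#' @export
run_experiment <- function(script, base, dt_ms = 0.01) {
  stopifnot(inherits(script, "experiment_script"),
            inherits(base, "circuit_parameters"))

  # stage segment boundaries
  st <- script$stages
  seg_start <- st$start_ms
  seg_end <- c(st$start_ms[-1], script$duration_ms)

  set.seed(.stream_seed(script$seed, 1L))
  bath <- stats::runif(1, 4, 8)
  stage_params <- lapply(seq_len(nrow(st)), function(i)
    stage_parameters(st$stage[i], base, bath_Mohm = bath))

  pieces <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    prot <- .stage_protocol(st$stage[i], seg_end[i] - seg_start[i], script)
    pieces[[i]] <- simulate_voltage_clamp(stage_params[[i]], prot,
                                          dt_ms = dt_ms)
  }
  current <- unlist(lapply(pieces, `[[`, "current_nA"))
  command <- unlist(lapply(pieces, `[[`, "command_mV"))
  n <- length(current)
  t <- (seq_len(n) - 1) * dt_ms

  # injection events: permanent superposed offsets
  events <- script$injections
  truth_events <- data.frame(time_ms = numeric(0), drop_nA = numeric(0))
  if (!is.null(events) && nrow(events)) {
    set.seed(.stream_seed(script$seed, 2L))
    n_ev <- nrow(events)
    if (identical(script$injection_source, "calibration")) {
      if (is.null(base$calibration))
        stop("injection_source = 'calibration' needs a preset with a ",
             "calibration block", call. = FALSE)
      base_drop <- rep(base$calibration$mean_drop_nA, n_ev)
    } else {
      src <- script$injection_source
      cyto <- src$cytoplasm
      base_drop <- numeric(n_ev)
      for (j in seq_len(n_ev)) {
        mixed <- mix_injection(cyto, src$cell_volume_pL, src$injectate,
                               events$volume_pL[j])
        e_inj <- injection_potential(src$outside, cyto, mixed, src$ions)
        base_drop[j] <- injection_current(e_inj, base$r_access_Mohm)
        cyto <- mixed
      }
    }
    drops <- base_drop + stats::rnorm(n_ev, 0, script$noise$event_sd_nA)
    tau_on <- if (is.null(script$onset_tau_ms)) 0 else script$onset_tau_ms
    for (j in seq_len(n_ev)) {
      on <- t >= events$time_ms[j]
      ramp <- if (tau_on > 0)
        1 - exp(-(t[on] - events$time_ms[j]) / tau_on) else 1
      current[on] <- current[on] + drops[j] * ramp
    }
    truth_events <- data.frame(time_ms = events$time_ms, drop_nA = drops)
  }

  # measurement noise and drift
  set.seed(.stream_seed(script$seed, 3L))
  if (script$noise$gaussian_sd_nA > 0)
    current <- current + stats::rnorm(n, 0, script$noise$gaussian_sd_nA)
  if (script$noise$drift_nA_per_s > 0)
    current <- current + script$noise$drift_nA_per_s * t / 1000

  # baseline zeroing at the start of whole-cell holding
  wc <- which(st$stage %in% c("WHOLE_CELL_HOLDING", "INJECTING",
                              "POST_INJECTION"))[1]
  baseline_offset <- 0
  if (!is.na(wc)) {
    w0 <- seg_start[wc] + 20
    w1 <- if (nrow(truth_events)) min(truth_events$time_ms) - 10
          else min(seg_end[wc], w0 + 80)
    w1 <- min(w1, w0 + 80)
    if (w1 > w0) {
      idx <- which(t >= w0 & t < w1)
      baseline_offset <- mean(current[idx])
      current <- current - baseline_offset
    }
  }

  truth <- list(
    stages = data.frame(stage = st$stage, start_ms = seg_start,
                        end_ms = seg_end,
                        total_Mohm = vapply(stage_params, `[[`, numeric(1),
                                            "stage_total_Mohm")),
    stage_params = stage_params,
    events = truth_events,
    channel_flags = c(
      k = base$switch$s_k == "closed" && base$gating$k$g_max_uS > 0,
      na = base$switch$s_na == "closed" && base$gating$na$g_max_uS > 0),
    baseline_offset_nA = baseline_offset,
    seed = script$seed)

  trace <- current_trace(
    dt_ms = dt_ms, current_nA = current, command_mV = command,
    annotations = if (nrow(truth_events)) truth_events else NULL,
    metadata = list(units = list(time = "ms", current = "nA",
                                 command = "mV"),
                    seed = script$seed, preset = base$label,
                    r_access_Mohm = base$r_access_Mohm,
                    c_m_pF = base$c_m_pF,
                    holding_mV = script$holding_mV,
                    stage_timeline = st))
  structure(list(trace = trace, truth = truth),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic microinjection experiment (seed", x$truth$seed, ")\n")
  cat("  stages:", paste(x$truth$stages$stage, collapse = " -> "), "\n")
  if (nrow(x$truth$events))
    cat(sprintf("  %d injection event(s), true drops: %s nA\n",
                nrow(x$truth$events),
                paste(sprintf("%.2f", x$truth$events$drop_nA),
                      collapse = ", ")))
  print(x$trace)
  invisible(x)
}
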