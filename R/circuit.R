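# Units are fixed package-wide: mV, nA, MOhm, pF, uS, ms.
# Identities used everywhere: mV / MOhm = nA; uS * mV = nA; MOhm * pF = us,
# so RC time constants in ms are R * C / 1000.

#' Switch states of the equivalent circuit
#'
#' Five switches gate the seal path, the injection battery and the three
#' channel branches.  At rest all channel switches are open (no stimulus, no
#' channel activity) and the seal switch is open in the idealised model
#' because the seal resistance dwarfs every other element; the simulator
#' keeps the seal path present with a finite resistance so seal tests can be
#' simulated, and an infinite `r_seal_Mohm` recovers the idealisation.
#' `s_injection` is driven by timed injection events, not set directly.
#'
#' @param s_seal,s_injection,s_k,s_na,s_other `"open"` or `"closed"`.
#' @return An object of class `switch_state`.
#' @export
switch_state <- function(s_seal = "open", s_injection = "open",
                         s_k = "open", s_na = "open", s_other = "open") {
  st <- list(s_seal = s_seal, s_injection = s_injection,
             s_k = s_k, s_na = s_na, s_other = s_other)
  ok <- vapply(st, function(x) x %in% c("open", "closed"), logical(1))
  if (!all(ok)) stop("switch states must be 'open' or 'closed'", call. = FALSE)
  structure(st, class = "switch_state")
}

#' Gating parameters of the channel branches
#'
#' Boltzmann steady-state activation with first-order kinetics.  The
#' potassium branch is a delayed-rectifier-like single activation gate; the
#' sodium branch is activation times inactivation (`m * h`), the inactivation
#' slope being negative so `h` falls with depolarisation.  The "other ions"
#' branch is a fixed leak conductance, default zero.
#'
#' @param k List: `g_max_uS`, `v_half_mV`, `slope_mV`, `tau_ms`.
#' @param na List: `g_max_uS`, `v_half_mV`, `slope_mV`, `tau_act_ms`,
#'   `h_v_half_mV`, `h_slope_mV` (negative), `tau_inact_ms`.
#' @param other List: `g_uS` fixed leak conductance.
#' @return An object of class `gating_parameters`.
#' @export
gating_parameters <- function(
    k = list(g_max_uS = 0.1, v_half_mV = -20, slope_mV = 10, tau_ms = 5),
    na = list(g_max_uS = 0.3, v_half_mV = -25, slope_mV = 6,
              tau_act_ms = 0.3, h_v_half_mV = -60, h_slope_mV = -7,
              tau_inact_ms = 3),
    other = list(g_uS = 0)) {
  defaults <- formals(gating_parameters)
  k <- utils::modifyList(eval(defaults$k), as.list(k))
  na <- utils::modifyList(eval(defaults$na), as.list(na))
  other <- utils::modifyList(eval(defaults$other), as.list(other))
  if (k$g_max_uS < 0 || na$g_max_uS < 0 || other$g_uS < 0)
    stop("maximal conductances must be >= 0", call. = FALSE)
  if (k$slope_mV == 0 || na$slope_mV == 0 || na$h_slope_mV == 0)
    stop("Boltzmann slopes must be nonzero", call. = FALSE)
  if (k$tau_ms <= 0 || na$tau_act_ms <= 0 || na$tau_inact_ms <= 0)
    stop("gating time constants must be > 0", call. = FALSE)
  structure(list(k = k, na = na, other = other),
            class = "gating_parameters")
}

#' Passive and active parameters of the equivalent circuit
#'
#' All elements of the cell-pipette equivalent model: the seal and access
#' resistances, membrane and pipette capacitances, the ionic batteries, the
#' injection battery, the (ideal by default) source resistance of the
#' clamping amplifier, switch states and channel gating.
#'
#' @param r_seal_Mohm Seal resistance (MOhm), > 0; may be `Inf`.
#' @param r_access_Mohm Access resistance (MOhm), > 0.
#' @param c_m_pF Membrane capacitance (pF), >= 0.
#' @param c_pipette_pF Pipette capacitance (pF), >= 0.
#' @param r_opamp_Mohm Source resistance of the voltage source; 0 = ideal
#'   clamp (the model never specifies a value, so ideal is the default).
#' @param e_k_mV,e_na_mV,e_other_mV Branch batteries (mV); defaults -90 and
#'   +60 are the standard potassium and sodium equilibrium potentials.
#' @param e_injection_mV Injection battery (mV), engaged by injection events.
#' @param switch A [switch_state()].
#' @param gating A [gating_parameters()].
#' @param compensate_pipette If `TRUE`, pipette-capacitance transients are
#'   cancelled exactly (the amplifier's capacitance-neutralisation setting).
#' @param label Optional label.
#' @return An object of class `circuit_parameters`.
#' @export
circuit_parameters <- function(r_seal_Mohm = 1000, r_access_Mohm = 5,
                               c_m_pF = 30, c_pipette_pF = 4,
                               r_opamp_Mohm = 0,
                               e_k_mV = -90, e_na_mV = 60, e_other_mV = 0,
                               e_injection_mV = 0,
                               switch = switch_state(),
                               gating = gating_parameters(),
                               compensate_pipette = FALSE,
                               label = NULL) {
  if (!(r_seal_Mohm > 0)) stop("r_seal_Mohm must be > 0", call. = FALSE)
  if (!is.finite(r_access_Mohm) || r_access_Mohm <= 0)
    stop("r_access_Mohm must be finite and > 0", call. = FALSE)
  if (c_m_pF < 0 || c_pipette_pF < 0)
    stop("capacitances must be >= 0", call. = FALSE)
  if (r_opamp_Mohm < 0) stop("r_opamp_Mohm must be >= 0", call. = FALSE)
  stopifnot(inherits(switch, "switch_state"),
            inherits(gating, "gating_parameters"))
  structure(list(r_seal_Mohm = r_seal_Mohm, r_access_Mohm = r_access_Mohm,
                 c_m_pF = c_m_pF, c_pipette_pF = c_pipette_pF,
                 r_opamp_Mohm = r_opamp_Mohm,
                 e_k_mV = e_k_mV, e_na_mV = e_na_mV,
                 e_other_mV = e_other_mV, e_injection_mV = e_injection_mV,
                 switch = switch, gating = gating,
                 compensate_pipette = compensate_pipette, label = label),
            class = "circuit_parameters")
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat("Circuit parameters", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat(sprintf("  R_Seal %g MOhm, R_Access %g MOhm, C_M %g pF, C_Pipette %g pF\n",
              x$r_seal_Mohm, x$r_access_Mohm, x$c_m_pF, x$c_pipette_pF))
  cat(sprintf("  E_K %g mV, E_Na %g mV, E_Other %g mV, E_Injection %g mV\n",
              x$e_k_mV, x$e_na_mV, x$e_other_mV, x$e_injection_mV))
  closed <- names(x$switch)[vapply(x$switch, identical, logical(1), "closed")]
  cat("  closed switches:", if (length(closed)) paste(closed, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Load a circuit preset shipped with the package
#'
#' Presets are YAML files under `inst/extdata`.  Two ship with the package:
#' `"shsy5y"` (neuroblastoma: potassium and sodium branches active) and
#' `"hek293"` (embryonic kidney: potassium only, `g_max,Na = 0`).  Each
#' carries a `calibration` block (mean holding-current drop and injection
#' battery) from which the injection-branch pair is derived with
#' [calibrate_access_pair()].
#'
#' @param name Preset name (`"shsy5y"`, `"hek293"`) or a path to a YAML file.
#' @return A [circuit_parameters()] object with an extra `calibration` field
#'   (`mean_drop_nA`, `e_injection_mV`, `r_access_injection_Mohm`).
#' @examples
#' circuit_preset("shsy5y")
#' @export
circuit_preset <- function(name) {
  path <- if (file.exists(name)) name
          else system.file("extdata", paste0(name, ".cfg"),
                           package = "cytoclamp")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown circuit preset: ", name, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  g <- cfg$gating
  params <- circuit_parameters(
    r_seal_Mohm = cfg$r_seal_Mohm, r_access_Mohm = cfg$r_access_Mohm,
    c_m_pF = cfg$c_m_pF, c_pipette_pF = cfg$c_pipette_pF,
    r_opamp_Mohm = if (is.null(cfg$r_opamp_Mohm)) 0 else cfg$r_opamp_Mohm,
    e_k_mV = cfg$e_k_mV, e_na_mV = cfg$e_na_mV,
    e_other_mV = if (is.null(cfg$e_other_mV)) 0 else cfg$e_other_mV,
    gating = gating_parameters(k = g$k, na = g$na, other = g$other),
    label = cfg$label)
  if (!is.null(cfg$calibration)) {
    cal <- cfg$calibration
    cal$r_access_injection_Mohm <- calibrate_access_pair(
      cal$mean_drop_nA, cal$e_injection_mV, warn = FALSE)
    params$calibration <- cal
    params$e_injection_mV <- cal$e_injection_mV
  }
  params
}

#' Ohmic current through a channel branch
#'
#' @param v_m Membrane potential (mV).
#' @param e_ion Branch battery (mV).
#' @param r_ion Branch resistance (MOhm), > 0.
#' @return Branch current in nA (mV / MOhm = nA); outward positive.
#' @examples
#' channel_current(100, -90, 20)   # 9.5 nA outward
#' @export
channel_current <- function(v_m, e_ion, r_ion) {
  if (any(!is.finite(r_ion)) || any(r_ion <= 0))
    stop("channel resistance must be finite and > 0", call. = FALSE)
  (v_m - e_ion) / r_ion
}

#' Steady injection current through the access path
#'
#' With the cell at rest (all channel switches open) the measured membrane
#' current equals the injection battery over the access resistance; this is
#' the permanent holding-current drop that signals an injection.
#'
#' @param e_injection_mV Injection battery (mV).
#' @param r_access_Mohm Access resistance (MOhm), > 0.
#' @return Current in nA.
#' @examples
#' injection_current(-0.3, 0.02521008)   # about -11.9 nA
#' @export
injection_current <- function(e_injection_mV, r_access_Mohm) {
  if (!is.finite(r_access_Mohm) || r_access_Mohm <= 0)
    stop("access resistance must be finite and > 0", call. = FALSE)
  e_injection_mV / r_access_Mohm
}

.boltzmann <- function(v, v_half, slope) 1 / (1 + exp(-(v - v_half) / slope))

#' Steady-state gating values at a fixed voltage
#'
#' @param v Membrane potential (mV).
#' @param params A [gating_parameters()].
#' @return A `gating_state`: list with `n` (K activation), `m` (Na
#'   activation) and `h` (Na inactivation), each in `[0, 1]`.
#' @export
gating_steady_state <- function(v, params) {
  stopifnot(inherits(params, "gating_parameters"))
  structure(list(
    n = .boltzmann(v, params$k$v_half_mV, params$k$slope_mV),
    m = .boltzmann(v, params$na$v_half_mV, params$na$slope_mV),
    h = .boltzmann(v, params$na$h_v_half_mV, params$na$h_slope_mV)),
    class = "gating_state")
}

#' Advance gating states over one time step
#'
#' First-order relaxation toward the steady state at `v`:
#' `x <- x_inf + (x - x_inf) exp(-dt / tau)`, exact for constant voltage
#' over the step.
#'
#' @param state A `gating_state` (see [gating_steady_state()]).
#' @param v Membrane potential held over the step (mV).
#' @param dt_ms Step length (ms), > 0.
#' @param params A [gating_parameters()].
#' @return The advanced `gating_state`.
#' @export
advance_gating <- function(state, v, dt_ms, params) {
  stopifnot(dt_ms > 0)
  inf <- gating_steady_state(v, params)
  relax <- function(x, xi, tau) xi + (x - xi) * exp(-dt_ms / tau)
  structure(list(
    n = relax(state$n, inf$n, params$k$tau_ms),
    m = relax(state$m, inf$m, params$na$tau_act_ms),
    h = relax(state$h, inf$h, params$na$tau_inact_ms)),
    class = "gating_state")
}

.branch_active <- function(params) {
  c(k = params$switch$s_k == "closed" && params$gating$k$g_max_uS > 0,
    na = params$switch$s_na == "closed" && params$gating$na$g_max_uS > 0,
    other = params$switch$s_other == "closed" && params$gating$other$g_uS > 0)
}

# Cumulative injection-current offset per sample from timed activations.
.injection_offsets <- function(injections, t, params) {
  offset <- numeric(length(t))
  e_vec <- rep(0, length(t))
  if (is.null(injections) || NROW(injections) == 0L)
    return(list(offset = offset, e = e_vec))
  injections <- as.data.frame(injections)
  if (is.null(injections$r_access_Mohm))
    injections$r_access_Mohm <- params$r_access_Mohm
  for (j in seq_len(nrow(injections))) {
    on <- t >= injections$time_ms[j]
    offset[on] <- offset[on] +
      injection_current(injections$e_injection_mV[j],
                        injections$r_access_Mohm[j])
    e_vec[on] <- e_vec[on] + injections$e_injection_mV[j]
  }
  list(offset = offset, e = e_vec)
}

#' Simulate a whole-cell voltage-clamp recording
#'
#' Integrates the two-node equivalent circuit under a piecewise-constant
#' command.  The pipette node is clamped to the command (ideal source); the
#' membrane node obeys
#' `C_M dV_mem/dt = (V_cmd - V_mem)/R_Access - sum_branches g(t) (V_mem - E)`.
#' The linear part is advanced by the exact exponential update per sample
#' (conductances frozen over one step, gating advanced by its own exact
#' first-order update), so channels-closed responses match the analytic RC
#' solution to machine precision.  The seal path contributes
#' `V_cmd / R_Seal`; pipette-capacitance spikes appear as one-sample
#' impulses at command edges unless compensation is on.  Injection events
#' superpose their steady branch current `E_Injection / R_Access` onto the
#' access path from their activation time onward.
#'
#' The reported sample-wise decomposition satisfies both circuit identities:
#' `I_m = I_Pipette + I_Seal + I_C + I_Access` and
#' `I_Access = I_Na + I_K + I_Other + I_Injection`.
#'
#' @param params A [circuit_parameters()].
#' @param protocol A [voltage_protocol()].
#' @param dt_ms Sample interval (ms); must satisfy
#'   `dt <= R_Access * C_M / 10` (in consistent units) so the access
#'   transient is resolved.
#' @param injections Optional data frame with columns `time_ms`,
#'   `e_injection_mV` and optionally `r_access_Mohm` (defaults to the
#'   circuit's access resistance): timed closures of the injection switch.
#' @param v_init Initial membrane potential (mV); default is the steady
#'   state under the first command level.
#' @return A `simulated_trace` (inherits `current_trace`): sample-wise
#'   `current_nA` (= I_m), `command_mV`, `v_mem_mV`, all branch currents,
#'   gating states, `dt_ms` and metadata.
#' @examples
#' prot <- voltage_protocol(level_mV = c(0, 20, 0),
#'                          duration_ms = c(5, 10, 5))
#' tr <- simulate_voltage_clamp(circuit_parameters(), prot, dt_ms = 0.01)
#' max(abs(tr$current_nA))
#' @export
simulate_voltage_clamp <- function(params, protocol, dt_ms = 0.01,
                                   injections = NULL, v_init = NULL) {
  stopifnot(inherits(params, "circuit_parameters"))
  protocol <- as_voltage_protocol(protocol)
  if (any(protocol$duration_ms <= 0))
    stop("protocol segment durations must be > 0", call. = FALSE)
  tau_access_ms <- params$r_access_Mohm * params$c_m_pF / 1000
  if (params$c_m_pF > 0 && dt_ms > tau_access_ms / 10)
    stop(sprintf(paste0("dt = %g ms too coarse: the access time constant ",
                        "R_Access*C_M = %g ms requires dt <= %g ms"),
                 dt_ms, tau_access_ms, tau_access_ms / 10), call. = FALSE)
  if (dt_ms <= 0) stop("dt_ms must be > 0", call. = FALSE)

  nseg <- pmax(1L, as.integer(round(protocol$duration_ms / dt_ms)))
  cmd <- rep(protocol$level_mV, nseg)
  n <- length(cmd)
  t <- (seq_len(n) - 1) * dt_ms

  active <- .branch_active(params)
  g_other <- if (active[["other"]]) params$gating$other$g_uS else 0
  ra <- params$r_access_Mohm
  cm <- params$c_m_pF

  steady_vm <- function(vc) {
    gt <- 1 / ra + g_other
    (vc / ra + g_other * params$e_other_mV) / gt
  }

  if (!any(active[c("k", "na")])) {
    # Linear time-invariant circuit: vectorised exact solution per segment.
    vm <- numeric(n)
    gtot <- 1 / ra + g_other
    vinf_of <- function(vc) (vc / ra + g_other * params$e_other_mV) / gtot
    vm[1] <- if (is.null(v_init)) vinf_of(cmd[1]) else v_init
    if (cm > 0) {
      tau <- cm / gtot / 1000
      seg_ends <- cumsum(nseg)
      seg_starts <- seg_ends - nseg + 1L
      v0 <- vm[1]
      for (s in seq_along(nseg)) {
        idx <- seg_starts[s]:seg_ends[s]
        vinf <- vinf_of(protocol$level_mV[s])
        rel <- t[idx] - t[idx[1]]
        vm[idx] <- vinf + (v0 - vinf) * exp(-rel / tau)
        # state entering the next segment: one more dt beyond the last sample
        v0 <- vinf + (v0 - vinf) * exp(-(rel[length(rel)] + dt_ms) / tau)
      }
    } else {
      vm <- vapply(cmd, vinf_of, numeric(1))
    }
    gate0 <- gating_steady_state(vm[1], params$gating)
    nn <- rep(gate0$n, n); mm <- rep(gate0$m, n); hh <- rep(gate0$h, n)
    g_k_t <- numeric(n); g_na_t <- numeric(n)
  } else {
    vm <- numeric(n)
    nn <- mm <- hh <- numeric(n)
    vm[1] <- if (is.null(v_init)) steady_vm(cmd[1]) else v_init
    gate <- gating_steady_state(vm[1], params$gating)
    nn[1] <- gate$n; mm[1] <- gate$m; hh[1] <- gate$h
    gk_max <- if (active[["k"]]) params$gating$k$g_max_uS else 0
    gna_max <- if (active[["na"]]) params$gating$na$g_max_uS else 0
    for (i in seq_len(n - 1L)) {
      gk <- gk_max * nn[i]
      gna <- gna_max * mm[i] * hh[i]
      gtot <- 1 / ra + gk + gna + g_other
      vinf <- (cmd[i] / ra + gk * params$e_k_mV + gna * params$e_na_mV +
                 g_other * params$e_other_mV) / gtot
      vm[i + 1L] <- if (cm > 0) {
        tau <- cm / gtot / 1000
        vinf + (vm[i] - vinf) * exp(-dt_ms / tau)
      } else vinf
      gate <- advance_gating(list(n = nn[i], m = mm[i], h = hh[i]),
                             vm[i], dt_ms, params$gating)
      nn[i + 1L] <- gate$n; mm[i + 1L] <- gate$m; hh[i + 1L] <- gate$h
    }
    g_k_t <- (if (active[["k"]]) params$gating$k$g_max_uS else 0) * nn
    g_na_t <- (if (active[["na"]]) params$gating$na$g_max_uS else 0) * mm * hh
  }

  i_k <- g_k_t * (vm - params$e_k_mV)
  i_na <- g_na_t * (vm - params$e_na_mV)
  i_other <- g_other * (vm - params$e_other_mV)
  i_access_res <- (cmd - vm) / ra
  i_c <- if (cm > 0) i_access_res - i_k - i_na - i_other else numeric(n)
  if (cm == 0) i_c <- rep(0, n)
  inj <- .injection_offsets(injections, t, params)
  i_injection <- inj$offset
  i_seal <- if (is.finite(params$r_seal_Mohm)) cmd / params$r_seal_Mohm
            else rep(0, n)
  i_pipette <- rep(0, n)
  if (!params$compensate_pipette && params$c_pipette_pF > 0) {
    dv <- c(0, diff(cmd))
    i_pipette <- params$c_pipette_pF * dv / dt_ms / 1000
  }
  i_access <- i_k + i_na + i_other + i_injection
  i_m <- i_pipette + i_seal + i_c + i_access

  tr <- current_trace(dt_ms = dt_ms, current_nA = i_m, command_mV = cmd,
                      metadata = list(
                        units = list(time = "ms", current = "nA",
                                     command = "mV"),
                        r_access_Mohm = ra, c_m_pF = cm,
                        r_seal_Mohm = params$r_seal_Mohm,
                        preset = params$label))
  tr$v_mem_mV <- vm
  tr$branches <- list(i_pipette = i_pipette, i_seal = i_seal, i_c = i_c,
                      i_k = i_k, i_na = i_na, i_other = i_other,
                      i_injection = i_injection, i_access = i_access)
  tr$gating <- list(n = nn, m = mm, h = hh)
  class(tr) <- c("simulated_trace", class(tr))
  tr
}

#' Branch-current decomposition of a simulated trace
#'
#' Returns all branch currents with the residuals of the two circuit
#' identities: the measured current against
#' `I_Pipette + I_Seal + I_C + I_Access`, and the access current against
#' `I_Na + I_K + I_Other + I_Injection`.
#'
#' @param trace A `simulated_trace` from [simulate_voltage_clamp()].
#' @return A list of class `current_decomposition`: data frame `currents`
#'   (time plus each branch), `max_residual_total_nA` and
#'   `max_residual_access_nA`.
#' @export
decompose_currents <- function(trace) {
  stopifnot(inherits(trace, "simulated_trace"))
  b <- trace$branches
  t <- (seq_along(trace$current_nA) - 1) * trace$dt_ms
  res5 <- trace$current_nA - (b$i_pipette + b$i_seal + b$i_c + b$i_access)
  res6 <- b$i_access - (b$i_na + b$i_k + b$i_other + b$i_injection)
  structure(list(
    currents = data.frame(time_ms = t, i_m = trace$current_nA,
                          i_pipette = b$i_pipette, i_seal = b$i_seal,
                          i_c = b$i_c, i_k = b$i_k, i_na = b$i_na,
                          i_other = b$i_other, i_injection = b$i_injection,
                          i_access = b$i_access),
    max_residual_total_nA = max(abs(res5)),
    max_residual_access_nA = max(abs(res6))),
    class = "current_decomposition")
}

#' @export
print.current_decomposition <- function(x, ...) {
  cat("Branch-current decomposition over", nrow(x$currents), "samples\n")
  cat(sprintf("  max |I_m - (I_Pipette+I_Seal+I_C+I_Access)| = %.3g nA\n",
              x$max_residual_total_nA))
  cat(sprintf("  max |I_Access - (I_Na+I_K+I_Other+I_Injection)| = %.3g nA\n",
              x$max_residual_access_nA))
  invisible(x)
}
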