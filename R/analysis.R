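# Robust per-sample noise sd: median absolute deviation of the first
# differences, divided by sqrt(2).  Resistant to the very steps being
# detected, which avoids a circular dependence between detection and noise
# estimation.
.robust_noise_sd <- function(x) {
  if (length(x) < 3) return(0)
  stats::mad(diff(x)) / sqrt(2)
}

.moving_mean <- function(x, w) {
  cs <- c(0, cumsum(x))
  n <- length(x)
  out <- rep(NA_real_, n)
  idx <- w:n
  out[idx] <- (cs[idx + 1] - cs[idx + 1 - w]) / w
  out  # out[i] = mean(x[(i-w+1):i])
}

#' Zero the baseline of a current trace
#'
#' Subtracts the mean current over a quiet window from the whole trace,
#' mirroring the operating habit of zeroing the holding current before an
#' injection so the injection drop is read against zero.
#'
#' @param trace A [current_trace()].
#' @param window_ms Length-2 numeric, `c(start, end)` in ms; must lie inside
#'   the trace and contain no commanded voltage step.
#' @return The trace with the window mean removed (recorded in metadata as
#'   `baseline_removed_nA`).
#' @export
zero_baseline <- function(trace, window_ms) {
  stopifnot(inherits(trace, "current_trace"),
            is.numeric(window_ms), length(window_ms) == 2L,
            window_ms[1] < window_ms[2])
  t <- trace_times(trace)
  idx <- which(t >= window_ms[1] & t < window_ms[2])
  if (!length(idx) || max(idx) >= length(t))
    stop("baseline window falls outside the trace", call. = FALSE)
  if (length(unique(trace$command_mV[idx])) != 1L)
    stop("baseline window overlaps a commanded voltage step", call. = FALSE)
  offset <- mean(trace$current_nA[idx])
  trace$current_nA <- trace$current_nA - offset
  trace$metadata$baseline_removed_nA <- offset
  trace
}

#' Estimate total resistance from a test pulse
#'
#' Ohm's law on the steady part of the membrane test: the pulse amplitude
#' over the plateau current change, where the plateau is the last 20% of the
#' pulse (excluding the capacitive transient) and the reference level is the
#' settled pre-pulse current.
#'
#' @param trace A [current_trace()] containing at least one full test pulse
#'   (the pulse is located from the command channel).
#' @param pulse_amplitude_mV Pulse amplitude; default is read from the
#'   command channel.  Must be nonzero.
#' @return An object of class `resistance_estimate`: `r_Mohm`,
#'   `lower_bound` (`TRUE` when the current change is below the noise floor
#'   and `r_Mohm` is only a lower bound), `delta_i_nA`, `amplitude_mV`,
#'   `noise_floor_nA`.
#' @export
estimate_resistance <- function(trace, pulse_amplitude_mV = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  cmd <- trace$command_mV
  base_level <- cmd[1]
  off <- which(cmd != base_level)
  if (!length(off))
    stop("no test pulse found in the command channel", call. = FALSE)
  p0 <- off[1]
  p1 <- p0
  while (p1 < length(cmd) && cmd[p1 + 1] == cmd[p0]) p1 <- p1 + 1
  amplitude <- if (is.null(pulse_amplitude_mV)) cmd[p0] - base_level
               else pulse_amplitude_mV
  if (!is.finite(amplitude) || amplitude == 0)
    stop("test pulse amplitude is zero: resistance undefined", call. = FALSE)

  npulse <- p1 - p0 + 1L
  plateau <- (p1 - max(1L, floor(0.2 * npulse)) + 1L):p1
  pre <- seq_len(p0 - 1L)
  pre <- pre[pre > p0 - 1L - max(10L, floor(0.5 * (p0 - 1L)))]  # settled half
  if (length(pre) < 2L)
    stop("no settled pre-pulse region before the test pulse", call. = FALSE)

  i_pre <- mean(trace$current_nA[pre])
  i_plat <- mean(trace$current_nA[plateau])
  delta_i <- i_plat - i_pre
  noise_sd <- .robust_noise_sd(trace$current_nA[pre])
  noise_floor <- max(3 * noise_sd / sqrt(length(plateau)), 1e-9)

  lower_bound <- abs(delta_i) < noise_floor
  r <- if (lower_bound) abs(amplitude) / noise_floor
       else amplitude / delta_i
  structure(list(r_Mohm = r, lower_bound = lower_bound,
                 delta_i_nA = delta_i, amplitude_mV = amplitude,
                 noise_floor_nA = noise_floor),
            class = "resistance_estimate")
}

#' @export
print.resistance_estimate <- function(x, ...) {
  if (x$lower_bound)
    cat(sprintf(
      "Total resistance >= %.4g MOhm (current change %.3g nA below the %.3g nA noise floor)\n",
      x$r_Mohm, x$delta_i_nA, x$noise_floor_nA))
  else
    cat(sprintf("Total resistance: %.4g MOhm (dV = %g mV, dI = %.4g nA)\n",
                x$r_Mohm, x$amplitude_mV, x$delta_i_nA))
  invisible(x)
}

#' Detect permanent injection current drops
#'
#' Finds permanent step changes in the holding current by comparing leading
#' and trailing moving-window means separated by a small gap.  A step is
#' declared where the window-mean difference exceeds `k_sigma` times the
#' trace's robust noise sd and the shift persists at least `persist_ms`
#' later.  The accumulated drop is the final steady level minus the initial
#' steady level; the episode is a success when the accumulated drop is at or
#' below (more negative than) the threshold.
#'
#' @param trace A baseline-zeroed [current_trace()]; the command must be
#'   constant over the trace.
#' @param threshold_nA Success threshold; default -11 nA, the drop level
#'   consistently observed on successful injections.
#' @param window_ms,gap_ms Moving-window mean length and half-gap around the
#'   candidate step.
#' @param persist_ms Minimum persistence of the shifted level.
#' @param k_sigma Detection threshold in robust noise sds.
#' @return An object of class `injection_detection`: `events` (data frame
#'   `time_ms`, `amplitude_nA`), `accumulated_nA`, `success`,
#'   `threshold_nA`, `noise_sd_nA`.
#' @export
detect_injection_drops <- function(trace, threshold_nA = -11,
                                   window_ms = 5, gap_ms = 1,
                                   persist_ms = 10, k_sigma = 6) {
  stopifnot(inherits(trace, "current_trace"))
  if (length(unique(trace$command_mV)) != 1L)
    stop("command is not constant over the analysed span; ",
         "drop detection needs a steady holding level", call. = FALSE)
  x <- trace$current_nA
  dt <- trace$dt_ms
  n <- length(x)
  w <- max(2L, as.integer(round(window_ms / dt)))
  g <- max(1L, as.integer(round(gap_ms / dt)))
  p <- max(1L, as.integer(round(persist_ms / dt)))
  if (n < 2 * (w + g) + 2L)
    stop("trace too short for the detection windows", call. = FALSE)

  sigma <- .robust_noise_sd(x)
  sigma_eff <- max(sigma, 1e-6)
  thr <- k_sigma * sigma_eff

  mm <- .moving_mean(x, w)              # mm[i] = mean over (i-w+1):i
  # candidate step between samples i-1 and i:
  #   trailing mean over (i-1-g-w+1):(i-1-g), leading over (i+g):(i+g+w-1)
  i_range <- (w + g + 1L):(n - g - w + 1L)
  trail <- mm[i_range - 1L - g]
  lead <- mm[i_range + g + w - 1L]
  d <- lead - trail

  hit <- which(abs(d) > thr)
  events <- data.frame(time_ms = numeric(0), amplitude_nA = numeric(0))
  if (length(hit)) {
    runs <- split(hit, cumsum(c(1L, diff(hit) > (w + g))))
    for (run in runs) {
      dmax <- max(abs(d[run]))
      # centre of the (possibly flat) maximum, so noise-free steps are
      # located at the true transition rather than the plateau edge
      at_max <- run[abs(d[run]) >= dmax * (1 - 1e-9)]
      k <- at_max[ceiling(length(at_max) / 2)]
      i <- i_range[k]
      # persistence: the shifted level must still be present persist_ms later
      j_hi <- min(n, i + p + w - 1L)
      j_lo <- min(n - 1L, i + p)
      later <- mean(x[j_lo:j_hi])
      shift <- later - trail[k]
      if (abs(shift) > thr && sign(shift) == sign(d[k])) {
        events <- rbind(events,
                        data.frame(time_ms = (i - 1L) * dt,
                                   amplitude_nA = d[k]))
      }
    }
  }
  accumulated <- mean(x[(n - w + 1L):n]) - mean(x[1:w])
  structure(list(events = events,
                 accumulated_nA = accumulated,
                 success = accumulated <= threshold_nA,
                 threshold_nA = threshold_nA,
                 noise_sd_nA = sigma),
            class = "injection_detection")
}

#' @export
print.injection_detection <- function(x, ...) {
  cat(sprintf("Injection detection: %d event(s); accumulated drop %.3f nA ",
              nrow(x$events), x$accumulated_nA))
  cat(sprintf("(threshold %.1f nA) -> %s\n", x$threshold_nA,
              if (x$success) "SUCCESS" else "no successful injection"))
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  t = %.2f ms, step %.3f nA\n",
                  x$events$time_ms[i], x$events$amplitude_nA[i]))
  }
  invisible(x)
}

#' Calibrate the injection battery / access resistance pair
#'
#' Inverts the steady injection-current relation: given the observed mean
#' accumulated drop and a hypothesised injection battery, returns the access
#' resistance that reproduces the drop.  A warning is raised when the result
#' falls outside the 4-8 MOhm pipette-resistance range, making explicit the
#' tension between the printed drop, the estimated battery and the measured
#' pipette resistances.
#'
#' @param mean_drop_nA Observed mean accumulated drop (nA), nonzero.
#' @param e_injection_mV Injection battery (mV), nonzero, same sign as the
#'   drop.
#' @param warn Emit the out-of-range warning.
#' @return Access resistance in MOhm.
#' @examples
#' suppressWarnings(calibrate_access_pair(-11.9, -0.3))  # 0.02521 MOhm
#' @export
calibrate_access_pair <- function(mean_drop_nA, e_injection_mV,
                                  warn = TRUE) {
  if (!is.finite(mean_drop_nA) || mean_drop_nA == 0 ||
      !is.finite(e_injection_mV) || e_injection_mV == 0)
    stop("calibration needs nonzero drop and battery", call. = FALSE)
  if (sign(mean_drop_nA) != sign(e_injection_mV))
    stop("drop and injection battery must have the same sign", call. = FALSE)
  r <- e_injection_mV / mean_drop_nA
  if (warn && (r < 4 || r > 8))
    warning(sprintf(paste0(
      "calibrated access resistance %.5g MOhm lies outside the 4-8 MOhm ",
      "pipette range implied by the bath-stage test pulse"), r),
      call. = FALSE)
  r
}

# Leak-correct a step trace using the known seal resistance, locate the step
# from the command channel, and return per-trace features.
.step_features <- function(trace, transient_excl_ms) {
  cmd <- trace$command_mV
  holding <- cmd[1]
  x <- trace$current_nA
  r_seal <- trace$metadata$r_seal_Mohm
  if (!is.null(r_seal) && is.finite(r_seal))
    x <- x - (cmd - holding) / r_seal
  off <- which(cmd != holding)
  if (!length(off)) return(NULL)
  p0 <- off[1]
  p1 <- p0
  while (p1 < length(cmd) && cmd[p1 + 1] == cmd[p0]) p1 <- p1 + 1
  dt <- trace$dt_ms
  t <- trace_times(trace)
  level <- cmd[p0]
  epoch_ms <- (p1 - p0 + 1L) * dt
  excl <- transient_excl_ms
  pre <- x[1:(p0 - 1L)]
  # reference to the settled pre-step holding level (baseline zeroing)
  settled <- pre[seq.int(max(1L, length(pre) %/% 2L), length(pre))]
  x <- x - mean(settled)
  pre <- pre - mean(settled)
  late0 <- max(t[p0] + epoch_ms - 20, t[p0] + excl)
  late_idx <- which(t >= late0 & t <= t[p1])
  early_idx <- which(t >= t[p0] + excl & t <= t[p0] + excl + 5 & t <= t[p1])
  list(level_mV = level,
       late_mean_nA = mean(x[late_idx]),
       early_min_nA = if (length(early_idx)) min(x[early_idx]) else NA_real_,
       noise_sd_nA = .robust_noise_sd(pre))
}

#' Classify post-injection cell viability from a step family
#'
#' Reads ion-channel activity off the current responses to a voltage-step
#' family (-80 to +100 mV style).  Sustained potassium activity shows as an
#' outward late-window current at the most depolarised steps, growing with
#' the step level; transient sodium activity shows as an early inward peak
#' at intermediate depolarised steps.  The cell is called viable exactly
#' when the potassium channels are active (sustained potassium activity is
#' the viability signature; sodium may legitimately disappear after the
#' injection redistributes intracellular sodium).
#'
#' @param step_traces List of [current_trace()]s, one per step level (e.g.
#'   from [simulate_voltage_clamp()] over [step_family()]); each must hold
#'   its level in the command channel.  At least 3 levels.
#' @param transient_excl_ms Capacitive-transient exclusion window after each
#'   step edge; default `10 * R_Access * C_M` from trace metadata when
#'   available, else 2 ms.
#' @param k_sigma Activity threshold in noise sds.
#' @return An object of class `viability_report`: `k_active`, `na_active`,
#'   `peak_outward_nA` (late mean at the most depolarised step),
#'   `peak_inward_nA` (most negative early current), `verdict`
#'   (`"viable"`/`"non-viable"`), and the per-level feature table.
#' @export
classify_viability <- function(step_traces, transient_excl_ms = NULL,
                               k_sigma = 5) {
  if (length(step_traces) < 3L)
    stop("need at least 3 step levels to assess monotonic growth",
         call. = FALSE)
  if (is.null(transient_excl_ms)) {
    md <- step_traces[[1]]$metadata
    transient_excl_ms <-
      if (!is.null(md$r_access_Mohm) && !is.null(md$c_m_pF))
        10 * md$r_access_Mohm * md$c_m_pF / 1000
      else 2
  }
  feats <- lapply(step_traces, .step_features, transient_excl_ms)
  feats <- feats[!vapply(feats, is.null, logical(1))]
  tab <- do.call(rbind, lapply(feats, as.data.frame))
  tab <- tab[order(tab$level_mV), ]
  # Floor the noise scale at 0.01 nA: channel currents are nA-scale, and
  # sub-0.05 nA late-window offsets (rest-state leak re-referencing, seal
  # correction residue) are below anything read as channel activity.
  sigma <- max(stats::median(tab$noise_sd_nA), 0.01)
  holding <- step_traces[[1]]$command_mV[1]

  top3 <- utils::tail(tab, 3L)
  k_active <- all(top3$late_mean_nA > k_sigma * sigma) &&
    !is.unsorted(top3$late_mean_nA, strictly = TRUE)

  depol <- tab[tab$level_mV > holding, ]
  na_active <- any(depol$early_min_nA < -k_sigma * sigma, na.rm = TRUE)

  structure(list(k_active = k_active, na_active = na_active,
                 peak_outward_nA = tab$late_mean_nA[nrow(tab)],
                 peak_inward_nA = min(tab$early_min_nA, na.rm = TRUE),
                 verdict = if (k_active) "viable" else "non-viable",
                 levels = tab, noise_sd_nA = sigma),
            class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  cat("Cell viability report\n")
  cat(sprintf("  K+  channels: %s (peak late outward %.3g nA)\n",
              if (x$k_active) "ACTIVE" else "inactive", x$peak_outward_nA))
  cat(sprintf("  Na+ channels: %s (peak early inward %.3g nA)\n",
              if (x$na_active) "ACTIVE" else "inactive", x$peak_inward_nA))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Threshold control loop over injection episodes
#'
#' The feedback strategy around the injection: after each recorded episode
#' segment the detector measures the accumulated drop; the running total is
#' compared against the success threshold, emitting `retry` until the
#' accumulated drop crosses it, then `success`, at which point the loop
#' terminates.  Upstream positioning and patching stages are assumed
#' already satisfied.
#'
#' @param segments List of baseline-zeroed [current_trace()] episode
#'   segments, in time order.
#' @param threshold_nA Success threshold (nA); default -11.
#' @param ... Passed to [detect_injection_drops()].
#' @return An object of class `control_log`: data frame with `segment`,
#'   `drop_nA`, `cumulative_nA`, `decision`; attribute `succeeded`.
#' @export
control_loop <- function(segments, threshold_nA = -11, ...) {
  log <- data.frame(segment = integer(0), drop_nA = numeric(0),
                    cumulative_nA = numeric(0), decision = character(0))
  cumulative <- 0
  for (i in seq_along(segments)) {
    det <- detect_injection_drops(segments[[i]],
                                  threshold_nA = threshold_nA, ...)
    cumulative <- cumulative + det$accumulated_nA
    decision <- if (cumulative <= threshold_nA) "success" else "retry"
    log <- rbind(log, data.frame(segment = i, drop_nA = det$accumulated_nA,
                                 cumulative_nA = cumulative,
                                 decision = decision))
    if (decision == "success") break
  }
  structure(log, class = c("control_log", "data.frame"),
            succeeded = any(log$decision == "success"),
            threshold_nA = threshold_nA)
}

#' @export
print.control_log <- function(x, ...) {
  cat("Injection control loop (threshold", attr(x, "threshold_nA"), "nA)\n")
  print.data.frame(x)
  cat("outcome:", if (isTRUE(attr(x, "succeeded"))) "success"
      else "no success", "\n")
  invisible(x)
}
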