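#' Uniformly sampled current trace
#'
#' The package's recording container: membrane current in nA sampled every
#' `dt_ms` milliseconds alongside the command voltage in mV, with optional
#' event annotations and free-form metadata (units, seed, preset,
#' provenance).
#'
#' @param dt_ms Sample interval (ms), > 0.
#' @param current_nA Numeric vector of membrane current samples (nA).
#' @param command_mV Numeric vector of command voltage samples (mV), same
#'   length as `current_nA`.
#' @param annotations Optional data frame of events (e.g. `time_ms`,
#'   `amplitude_nA`).
#' @param metadata Named list; a `units` sub-list of
#'   `list(time = "ms", current = "nA", command = "mV")` is added when
#'   absent.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(dt_ms, current_nA, command_mV,
                          annotations = NULL, metadata = list()) {
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || dt_ms <= 0)
    stop("dt_ms must be a single positive number", call. = FALSE)
  if (length(current_nA) != length(command_mV))
    stop("current and command channels must have the same length",
         call. = FALSE)
  if (any(!is.finite(current_nA)) || any(!is.finite(command_mV)))
    stop("trace samples must all be finite", call. = FALSE)
  if (is.null(metadata$units))
    metadata$units <- list(time = "ms", current = "nA", command = "mV")
  structure(list(dt_ms = dt_ms,
                 current_nA = as.numeric(current_nA),
                 command_mV = as.numeric(command_mV),
                 annotations = annotations, metadata = metadata),
            class = "current_trace")
}

#' Sample times of a trace
#' @param trace A `current_trace`.
#' @return Numeric vector of sample times (ms), starting at 0.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$current_nA) - 1) * trace$dt_ms
}

#' @export
print.current_trace <- function(x, ...) {
  n <- length(x$current_nA)
  cat(sprintf("%s: %d samples, dt = %g ms (%.4g ms total)\n",
              if (inherits(x, "simulated_trace")) "Simulated current trace"
              else "Current trace",
              n, x$dt_ms, n * x$dt_ms))
  cat(sprintf("  current range [%.4g, %.4g] nA; command range [%g, %g] mV\n",
              min(x$current_nA), max(x$current_nA),
              min(x$command_mV), max(x$command_mV)))
  if (!is.null(x$metadata$preset) && !is.null(x$metadata$preset))
    cat("  preset:", x$metadata$preset, "\n")
  if (!is.null(x$annotations) && nrow(x$annotations))
    cat("  annotations:", nrow(x$annotations), "event(s)\n")
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ..., main = "") {
  t <- trace_times(x)
  old <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::plot(t, x$current_nA, type = "l", xlab = "",
                 ylab = "I_m (nA)", main = main, ...)
  if (!is.null(x$annotations) && nrow(x$annotations))
    graphics::abline(v = x$annotations$time_ms, col = "red", lty = 3)
  graphics::plot(t, x$command_mV, type = "s", xlab = "time (ms)",
                 ylab = "V_cmd (mV)", ...)
  invisible(x)
}

#' @export
summary.current_trace <- function(object, ...) {
  cat("Trace summary\n")
  print(object)
  qs <- stats::quantile(object$current_nA, c(0, .25, .5, .75, 1))
  cat("  current quantiles (nA):",
      paste(sprintf("%.3g", qs), collapse = " "), "\n")
  invisible(object)
}
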