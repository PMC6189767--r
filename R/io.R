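# Trace file dialect, version 1: comma-delimited, period decimal separator,
# header row `time_ms,current_nA,command_mV`, no quoting.  Metadata lives in
# a YAML sidecar next to the table.

.trace_header <- c("time_ms", "current_nA", "command_mV")
.trace_format_version <- 1L

#' Sidecar metadata path of a trace file
#' @param path Trace file path.
#' @return The path of the paired metadata file (`<stem>.meta.yaml`).
#' @export
sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.yaml")
}

.trace_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cytoclamp_trace_error")))
}

#' Write a current trace and its metadata sidecar
#'
#' Values are written with 15 significant digits so a write/read round trip
#' preserves them to well under 1e-12 nA.
#'
#' @param trace A [current_trace()].
#' @param path Output CSV path; the sidecar goes to [sidecar_path()].
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  t <- trace_times(trace)
  lines <- c(paste(.trace_header, collapse = ","),
             sprintf("%.15g,%.15g,%.15g",
                     t, trace$current_nA, trace$command_mV))
  writeLines(lines, path)
  meta <- trace$metadata
  meta$dt_ms <- trace$dt_ms
  meta$format_version <- .trace_format_version
  meta$units <- list(time = "ms", current = "nA", command = "mV")
  if (!is.null(trace$annotations))
    meta$annotations <- lapply(
      seq_len(nrow(trace$annotations)),
      function(i) as.list(trace$annotations[i, , drop = FALSE]))
  if (!is.null(meta$stage_timeline) && is.data.frame(meta$stage_timeline))
    meta$stage_timeline <- lapply(
      seq_len(nrow(meta$stage_timeline)),
      function(i) as.list(meta$stage_timeline[i, , drop = FALSE]))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a current trace written by [write_trace()]
#'
#' Validates the header, the units recorded in the sidecar, and the time
#' base (strictly increasing, sample interval constant to within 1 ppm).
#' Failures raise distinct condition classes: `trace_header_error`,
#' `trace_unit_error`, `trace_dt_error`, `trace_malformed_error`.
#'
#' @param path Trace CSV path.
#' @return A [current_trace()] with metadata (and annotations, when
#'   present) restored from the sidecar.
#' @export
read_trace <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    .trace_error(paste0("empty or missing trace file: ", path),
                 "trace_malformed_error")
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   .trace_error(paste0("cannot parse trace file: ",
                                       conditionMessage(e)),
                                "trace_malformed_error"))
  if (!identical(names(df), .trace_header)) {
    bare <- c("time", "current", "command")
    if (any(bare %in% names(df)))
      .trace_error(paste0("trace header lacks units; expected ",
                          paste(.trace_header, collapse = ",")),
                   "trace_unit_error")
    .trace_error(paste0("malformed trace header: ",
                        paste(names(df), collapse = ",")),
                 "trace_header_error")
  }
  if (nrow(df) < 2)
    .trace_error("trace has fewer than 2 samples", "trace_malformed_error")
  dts <- diff(df$time_ms)
  if (any(dts <= 0))
    .trace_error("trace times are not strictly increasing",
                 "trace_dt_error")
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * dt)
    .trace_error("sample interval varies by more than 1 ppm",
                 "trace_dt_error")

  meta <- list()
  sp <- sidecar_path(path)
  annotations <- NULL
  if (file.exists(sp)) {
    meta <- yaml::read_yaml(sp)
    u <- meta$units
    if (!is.null(u) &&
        !(identical(u$time, "ms") && identical(u$current, "nA") &&
          identical(u$command, "mV")))
      .trace_error("sidecar units must be ms / nA / mV", "trace_unit_error")
    if (!is.null(meta$annotations)) {
      annotations <- do.call(rbind,
                             lapply(meta$annotations, as.data.frame))
      meta$annotations <- NULL
    }
    if (!is.null(meta$stage_timeline) && is.list(meta$stage_timeline))
      meta$stage_timeline <- do.call(rbind,
                                     lapply(meta$stage_timeline,
                                            as.data.frame))
  }
  current_trace(dt_ms = dt, current_nA = df$current_nA,
                command_mV = df$command_mV,
                annotations = annotations, metadata = meta)
}
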