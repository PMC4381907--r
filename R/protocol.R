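#' Piecewise-constant voltage-clamp protocol
#'
#' A protocol is an ordered list of constant-voltage segments applied after
#' (conceptually infinite) equilibration at the holding potential.  Times
#' are in milliseconds throughout; samples are taken every `sample_interval`
#' ms starting at t = 0 (the first sample reports the state at protocol
#' onset, before any relaxation).
#'
#' @param durations_ms segment durations, ms (all > 0).
#' @param voltages_mV segment command voltages, mV (same length).
#' @param sample_interval_ms sampling interval, ms (default 1, i.e. 1 kHz);
#'   must divide every segment duration.
#' @param holding_mV holding potential, mV (default -80).
#' @return object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(durations_ms, voltages_mV,
                             sample_interval_ms = 1,
                             holding_mV = -80) {
  stopifnot(length(durations_ms) == length(voltages_mV),
            length(durations_ms) >= 1,
            all(is.finite(durations_ms)), all(durations_ms > 0),
            all(is.finite(voltages_mV)),
            sample_interval_ms > 0)
  r <- durations_ms / sample_interval_ms
  if (any(abs(r - round(r)) > 1e-8))
    stop("sample_interval_ms must divide every segment duration")
  structure(list(durations = as.numeric(durations_ms),
                 voltages = as.numeric(voltages_mV),
                 dt = as.numeric(sample_interval_ms),
                 holding = as.numeric(holding_mV)),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("Voltage protocol: hold %g mV, sample every %g ms\n",
              x$holding, x$dt))
  for (i in seq_along(x$durations))
    cat(sprintf("  segment %d: %g ms at %+g mV\n",
                i, x$durations[i], x$voltages[i]))
  invisible(x)
}

## sample times (ms) and the command voltage at each sample
protocol_samples <- function(protocol) {
  total <- sum(protocol$durations)
  times <- seq(0, total, by = protocol$dt)
  ends <- cumsum(protocol$durations)
  ## a sample on a boundary reports the segment that starts there
  seg <- findInterval(times, c(0, ends))
  seg[seg > length(protocol$voltages)] <- length(protocol$voltages)
  list(times = times, voltage = protocol$voltages[seg], segment = seg)
}

#' Named voltage-protocol presets
#'
#' Step families used throughout the package, all from a -80 mV holding
#' potential with a 2 s pre-pulse holding segment (so fluorescence baselines
#' can be fitted) and 1 kHz sampling:
#'
#' * `"vcf_family"`: 4 s test pulse to `test_mV`, 1 s tail at +60 mV —
#'   the conductance/fluorescence-voltage family.
#' * `"permeability"`: 5 s at +60 mV, then 3 s tail at -60 mV — the
#'   ion-substitution tail-current protocol.
#' * `"xe991"`: 2 s test pulse to `test_mV` (default +40 mV), 1 s tail at
#'   -40 mV — the dose-inhibition protocol.
#'
#' @param name preset name.
#' @param test_mV test-pulse voltage, mV, where the preset takes one.
#' @param pre_ms duration of the pre-pulse holding segment, ms.
#' @return a [voltage_protocol()].
#' @export
protocol_preset <- function(name = c("vcf_family", "permeability", "xe991"),
                            test_mV = 40, pre_ms = 2500) {
  name <- match.arg(name)
  switch(name,
    vcf_family = voltage_protocol(
      durations_ms = c(pre_ms, 4000, 1000, 500),
      voltages_mV  = c(-80, test_mV, 60, -80)),
    permeability = voltage_protocol(
      durations_ms = c(pre_ms, 5000, 3000, 500),
      voltages_mV  = c(-80, 60, -60, -80)),
    xe991 = voltage_protocol(
      durations_ms = c(pre_ms, 2000, 1000, 500),
      voltages_mV  = c(-80, test_mV, -40, -80))
  )
}
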