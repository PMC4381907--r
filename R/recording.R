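#' Voltage-clamp-fluorometry recording
#'
#' Time-aligned command voltage, current and raw fluorescence intensity,
#' with acquisition metadata.  All series share one strictly increasing time
#' grid in milliseconds.
#'
#' @param times_ms sample times, ms.
#' @param voltage_mV command voltage per sample, mV.
#' @param current measured current (arbitrary units / uA).
#' @param fluorescence raw fluorescence intensity (arbitrary units).
#' @param meta named list of metadata; conventional keys: `ion`,
#'   `drug_conc_uM`, `seed`, `sample_rate_hz`, `test_mV`, `tail_start_ms`,
#'   `pulse_start_ms`, `params_digest`.
#' @return object of class `vcf_recording`.
#' @export
recording <- function(times_ms, voltage_mV, current, fluorescence,
                      meta = list()) {
  n <- length(times_ms)
  if (length(voltage_mV) != n || length(current) != n ||
      length(fluorescence) != n)
    stop("all series must have equal length")
  if (n >= 2 && any(diff(times_ms) <= 0))
    stop("times must be strictly increasing")
  if (!is.null(meta$sample_rate_hz)) {
    dt <- 1000 / meta$sample_rate_hz
    if (n >= 2 && max(abs(diff(times_ms) - dt)) > 1e-6)
      stop("time grid inconsistent with declared sample rate")
  }
  structure(list(times = as.numeric(times_ms),
                 voltage = as.numeric(voltage_mV),
                 current = as.numeric(current),
                 fluorescence = as.numeric(fluorescence),
                 meta = meta),
            class = "vcf_recording")
}

#' @export
print.vcf_recording <- function(x, ...) {
  cat(sprintf("VCF recording: %d samples, %.3g s", length(x$times),
              diff(range(x$times)) / 1000))
  if (!is.null(x$meta$ion)) cat(", ion", x$meta$ion)
  if (!is.null(x$meta$test_mV)) cat(sprintf(", test %+g mV", x$meta$test_mV))
  if (!is.null(x$meta$drug_conc_uM))
    cat(sprintf(", drug %g uM", x$meta$drug_conc_uM))
  cat("\n")
  invisible(x)
}

#' Write a recording as annotated CSV
#'
#' Metadata go in `# key: value` header lines, followed by a standard CSV
#' table with columns `time_ms`, `voltage_mV`, `current`, `fluorescence`.
#'
#' @param rec a [recording()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "vcf_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(rec$meta)) {
    v <- rec$meta[[k]]
    if (is.numeric(v)) v <- format(v, digits = 17)
    writeLines(sprintf("# %s: %s", k, paste(v, collapse = " ")), con)
  }
  df <- data.frame(time_ms = rec$times, voltage_mV = rec$voltage,
                   current = rec$current, fluorescence = rec$fluorescence)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path.
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"))
  recording(df$time_ms, df$voltage_mV, df$current, df$fluorescence, meta)
}
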