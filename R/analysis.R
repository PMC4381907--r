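## ---- voltage-clamp-fluorometry analysis ----------------------------------

#' Baseline-corrected fluorescence (delta-F/F)
#'
#' Fits a straight line to the raw fluorescence over the `baseline_ms`
#' (default 2 s) preceding the voltage pulse — capturing lamp drift and
#' photobleaching at the holding potential — extrapolates that baseline over
#' the whole sweep and returns
#' `dF/F(t) = (F(t) - baseline(t)) / baseline(t)`.
#'
#' @param rec a [recording()].
#' @param pulse_start_ms time at which the test pulse starts, ms; defaults
#'   to `rec$meta$pulse_start_ms`.
#' @param baseline_ms length of the pre-pulse window used for the fit
#'   (default 2000 ms; at least this much pre-pulse data must exist).
#' @return list with `dff` (numeric series), `times` (ms), `baseline`
#'   (extrapolated values) and `coef` (intercept, slope per ms).
#' @export
delta_f_over_f <- function(rec, pulse_start_ms = NULL, baseline_ms = 2000) {
  stopifnot(inherits(rec, "vcf_recording"))
  if (is.null(pulse_start_ms)) pulse_start_ms <- rec$meta$pulse_start_ms
  if (is.null(pulse_start_ms))
    stop("pulse_start_ms not given and not present in recording metadata")
  sel <- rec$times >= (pulse_start_ms - baseline_ms) &
    rec$times < pulse_start_ms
  if (sum(sel) < 10 ||
      (min(rec$times) > pulse_start_ms - baseline_ms + 1e-6))
    stop(sprintf("insufficient pre-pulse window: need %g ms before the pulse",
                 baseline_ms))
  fit <- stats::lm(f ~ t, data = data.frame(t = rec$times[sel],
                                            f = rec$fluorescence[sel]))
  base <- as.numeric(stats::predict(fit, newdata = data.frame(t = rec$times)))
  if (any(base <= 0))
    stop("extrapolated baseline reaches zero or negative values")
  list(dff = (rec$fluorescence - base) / base,
       times = rec$times,
       baseline = base,
       coef = stats::coef(fit))
}

#' Instantaneous tail amplitude by mono-exponential extrapolation
#'
#' Fits `y = C + A * exp(-(t - t0)/tau)` over a window after the tail step
#' and extrapolates to the step time `t0`; the instantaneous amplitude is
#' `C + A`, the value the relaxing tail had at the instant of the step.
#' The fit uses variable projection (linear solve for `C`, `A` at fixed
#' `tau`, 1-D profile optimisation over `tau`) followed by a
#' Levenberg-Marquardt polish, which is robust to poor starting guesses.
#' If everything fails, the first post-step sample is returned with
#' `converged = FALSE`.
#'
#' @param times_ms sample times, ms.
#' @param y trace values (typically current).
#' @param step_time_ms time of the voltage step into the tail, ms.
#' @param window_ms fit window relative to the step, ms (default 20-300;
#'   the first milliseconds are skipped to avoid fast settling artifacts).
#' @return list with `amplitude` (instantaneous value at the step),
#'   `tau_ms`, `offset`, `se` (standard error of the amplitude), and
#'   `converged`.
#' @export
tail_amplitude <- function(times_ms, y, step_time_ms,
                           window_ms = c(20, 300)) {
  sel <- times_ms >= step_time_ms + window_ms[1] &
    times_ms <= step_time_ms + window_ms[2]
  if (sum(sel) < 5) stop("tail window contains fewer than 5 samples")
  t <- times_ms[sel] - step_time_ms
  yy <- y[sel]
  span <- diff(range(t))
  ## variable projection: for fixed tau the offset and amplitude solve a
  ## linear least-squares problem, leaving a smooth 1-D profile over tau
  lin_fit <- function(tau) {
    X <- cbind(1, exp(-t / tau))
    cf <- tryCatch(stats::lm.fit(X, yy)$coefficients, error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(NULL)
    list(C = cf[1], A = cf[2], rss = sum((yy - X %*% cf)^2))
  }
  prof <- function(ltau) {
    f <- lin_fit(exp(ltau))
    if (is.null(f)) Inf else f$rss
  }
  opt <- stats::optimize(prof, log(c(span / 200, span * 20)), tol = 1e-10)
  tau0 <- exp(opt$minimum)
  lf <- lin_fit(tau0)
  if (is.null(lf)) {
    return(list(amplitude = y[which(times_ms >= step_time_ms)[1]],
                tau_ms = NA_real_, offset = NA_real_, se = NA_real_,
                converged = FALSE))
  }
  ## Levenberg-Marquardt polish from the projected optimum
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ C + A * exp(-t / tau),
                      start = list(C = unname(lf$C), A = unname(lf$A),
                                   tau = tau0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 100, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(amplitude = unname(lf$C + lf$A), tau_ms = tau0,
                offset = unname(lf$C), se = NA_real_, converged = TRUE))
  }
  cf <- stats::coef(fit)
  se <- tryCatch({
    s <- summary(fit)$coefficients
    sqrt(s["C", "Std. Error"]^2 + s["A", "Std. Error"]^2)
  }, error = function(e) NA_real_)
  list(amplitude = unname(cf["C"] + cf["A"]),
       tau_ms = unname(cf["tau"]), offset = unname(cf["C"]),
       se = se, converged = TRUE)
}

## locate the start of the tail segment of a recording
tail_start_of <- function(rec, tail_start_ms = NULL) {
  if (!is.null(tail_start_ms)) return(tail_start_ms)
  if (!is.null(rec$meta$tail_start_ms)) return(rec$meta$tail_start_ms)
  ch <- which(diff(rec$voltage) != 0)
  if (length(ch) < 2)
    stop("cannot locate the tail step; pass tail_start_ms explicitly")
  rec$times[ch[length(ch) - 1] + 1]
}

## test-pulse voltage of a recording (metadata, else the voltage just
## before the tail step)
test_voltage_of <- function(rec, tail_start_ms) {
  if (!is.null(rec$meta$test_mV)) return(rec$meta$test_mV)
  rec$voltage[max(which(rec$times < tail_start_ms))]
}

#' Extract a normalised conductance-voltage (GV) table from tail currents
#'
#' For each recording the instantaneous tail-current amplitude is estimated
#' by fitting a mono-exponential (plus offset) over `tail_window_ms` after
#' the tail step and extrapolating back to the step time; amplitudes are
#' normalised to the one following the highest-voltage test pulse.
#'
#' @param recordings list of [recording()] objects sharing the tail voltage.
#' @param tail_window_ms fit window relative to the tail step, ms
#'   (default 20-300).
#' @param tail_start_ms tail-step time, ms; taken from recording metadata
#'   (or detected from the voltage trace) when `NULL`.
#' @return data frame with columns `voltage_mV`, `raw`, `norm`, `tau_ms`,
#'   `converged` — one row per recording, sorted by test voltage.
#' @export
extract_gv <- function(recordings, tail_window_ms = c(20, 300),
                       tail_start_ms = NULL) {
  stopifnot(length(recordings) >= 1)
  rows <- lapply(recordings, function(rec) {
    t0 <- tail_start_of(rec, tail_start_ms)
    ta <- tail_amplitude(rec$times, rec$current, t0, tail_window_ms)
    if (!ta$converged)
      warning(sprintf("tail fit did not converge at %g mV; using first-sample amplitude",
                      test_voltage_of(rec, t0)))
    data.frame(voltage_mV = test_voltage_of(rec, t0),
               raw = ta$amplitude, tau_ms = ta$tau_ms,
               converged = ta$converged)
  })
  gv <- do.call(rbind, rows)
  gv <- gv[order(gv$voltage_mV), ]
  ref <- gv$raw[which.max(gv$voltage_mV)]
  if (abs(ref) < .Machine$double.eps)
    stop("tail amplitude at the highest test voltage is zero")
  gv$norm <- gv$raw / ref
  rownames(gv) <- NULL
  gv[, c("voltage_mV", "raw", "norm", "tau_ms", "converged")]
}

#' Extract a normalised fluorescence-voltage (FV) table
#'
#' The FV point for each recording is the baseline-corrected fluorescence
#' (`dF/F`, see [delta_f_over_f()]) averaged over the last `end_window_ms`
#' of the test pulse, normalised to the highest-voltage recording.
#'
#' @param recordings list of [recording()] objects.
#' @param pulse_start_ms,tail_start_ms pulse boundaries, ms; taken from
#'   metadata when `NULL`.
#' @param end_window_ms averaging window at the pulse end, ms (default 50).
#' @param baseline_ms pre-pulse baseline window, ms.
#' @return data frame with columns `voltage_mV`, `raw`, `norm`.
#' @export
extract_fv <- function(recordings, pulse_start_ms = NULL,
                       tail_start_ms = NULL, end_window_ms = 50,
                       baseline_ms = 2000) {
  rows <- lapply(recordings, function(rec) {
    t1 <- tail_start_of(rec, tail_start_ms)
    dff <- delta_f_over_f(rec, pulse_start_ms, baseline_ms)
    sel <- rec$times >= (t1 - end_window_ms) & rec$times < t1
    data.frame(voltage_mV = test_voltage_of(rec, t1),
               raw = mean(dff$dff[sel]))
  })
  fv <- do.call(rbind, rows)
  fv <- fv[order(fv$voltage_mV), ]
  ref <- fv$raw[which.max(fv$voltage_mV)]
  if (abs(ref) < .Machine$double.eps)
    stop("dF/F at the highest test voltage is zero")
  fv$norm <- fv$raw / ref
  rownames(fv) <- NULL
  fv
}

## Boltzmann component: 1 / (1 + exp(-z (V - Vh) / vt)), vt = RT/F in mV
boltz <- function(V, z, vhalf, vt) 1 / (1 + exp(-z * (V - vhalf) / vt))

#' Fit one or two Boltzmann components to a voltage curve
#'
#' Least-squares fit of `sum_i a_i / (1 + exp(-z_i F (V - Vhalf_i)/RT))`.
#' For two components the fit is repeated from 8 deterministic starting
#' points spread over the voltage range and valence decades, and the best
#' residual wins; the lower-`Vhalf` component is labelled `"main"` and the
#' higher `"high"` (the low- and high-voltage fluorescence components).
#'
#' @param voltage_mV test voltages, mV.
#' @param y curve values (approximately in \[0, 1\] for normalised curves).
#' @param components 1 or 2.
#' @param constants a [physical_constants()] object (sets RT/F).
#' @return object of class `boltzmann_fit`: list with `components` (data
#'   frame: component, amplitude, fraction, z, vhalf_mV, and standard
#'   errors), `n_components`, `resid_norm`, `fitted` (function of voltage).
#' @export
fit_boltzmann <- function(voltage_mV, y, components = 1,
                          constants = physical_constants()) {
  stopifnot(components %in% c(1, 2),
            length(voltage_mV) == length(y))
  if (length(voltage_mV) < 4 * components)
    stop("need at least 4 points per Boltzmann component")
  vt <- thermal_voltage_mV(constants)
  df <- data.frame(V = voltage_mV, y = y)
  vr <- range(voltage_mV)

  if (components == 1) {
    v0 <- voltage_mV[which.min(abs(y - max(y) / 2))]
    fit <- minpack.lm::nlsLM(
      y ~ a * boltz(V, z, vh, vt), data = df,
      start = list(a = max(y), z = 1, vh = v0),
      lower = c(a = 1e-6, z = 0.05, vh = vr[1] - 200),
      upper = c(a = 10 * max(abs(y)) + 1, z = 20, vh = vr[2] + 200),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    cf <- stats::coef(fit)
    ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                    error = function(e) rep(NA_real_, 3))
    comp <- data.frame(component = "main",
                       amplitude = unname(cf["a"]), fraction = 1,
                       z = unname(cf["z"]), vhalf_mV = unname(cf["vh"]),
                       z_se = unname(ses["z"]), vhalf_se = unname(ses["vh"]))
    best <- fit
  } else {
    q <- stats::quantile(voltage_mV, c(.1, .25, .4, .6, .75, .9))
    starts <- list(
      list(vh1 = q[[2]], vh2 = q[[5]], z1 = 1,   z2 = 1),
      list(vh1 = q[[1]], vh2 = q[[4]], z1 = 1,   z2 = 1),
      list(vh1 = q[[2]], vh2 = q[[6]], z1 = 2,   z2 = 2),
      list(vh1 = q[[3]], vh2 = q[[6]], z1 = 1,   z2 = 1),
      list(vh1 = q[[1]], vh2 = q[[5]], z1 = 0.7, z2 = 2),
      list(vh1 = q[[2]], vh2 = q[[5]], z1 = 2,   z2 = 0.7),
      list(vh1 = q[[1]], vh2 = q[[6]], z1 = 0.7, z2 = 0.7),
      list(vh1 = q[[3]], vh2 = q[[5]], z1 = 3,   z2 = 1))
    ymax <- max(abs(y))
    best <- NULL; best_rss <- Inf
    for (s in starts) {
      fit <- tryCatch(minpack.lm::nlsLM(
        y ~ a1 * boltz(V, z1, vh1, vt) + a2 * boltz(V, z2, vh2, vt),
        data = df,
        start = c(list(a1 = max(y) / 2, a2 = max(y) / 2), s),
        lower = c(a1 = 1e-8, a2 = 1e-8, vh1 = vr[1] - 250, vh2 = vr[1] - 250,
                  z1 = 0.05, z2 = 0.05),
        upper = c(a1 = 10 * ymax + 1, a2 = 10 * ymax + 1,
                  vh1 = vr[2] + 250, vh2 = vr[2] + 250, z1 = 20, z2 = 20),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss - 1e-15 ||
          (abs(rss - best_rss) <= 1e-15 && !is.null(best) &&
           min(stats::coef(fit)[c("vh1", "vh2")]) <
             min(stats::coef(best)[c("vh1", "vh2")]))) {
        best <- fit; best_rss <- rss
      }
    }
    if (is.null(best)) stop("two-component Boltzmann fit failed to converge")
    cf <- stats::coef(best)
    ses <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                    error = function(e) stats::setNames(rep(NA_real_, 6), names(cf)))
    ord <- order(c(cf["vh1"], cf["vh2"]))    # main = lower V1/2
    a <- c(cf["a1"], cf["a2"])[ord]
    z <- c(cf["z1"], cf["z2"])[ord]
    vh <- c(cf["vh1"], cf["vh2"])[ord]
    zse <- c(ses["z1"], ses["z2"])[ord]
    vse <- c(ses["vh1"], ses["vh2"])[ord]
    comp <- data.frame(component = c("main", "high"),
                       amplitude = unname(a),
                       fraction = unname(a / sum(a)),
                       z = unname(z), vhalf_mV = unname(vh),
                       z_se = unname(zse), vhalf_se = unname(vse))
  }
  fitted_fun <- local({
    comp_ <- comp; vt_ <- vt
    function(V) {
      out <- 0
      for (i in seq_len(nrow(comp_)))
        out <- out + comp_$amplitude[i] *
          boltz(V, comp_$z[i], comp_$vhalf_mV[i], vt_)
      out
    }
  })
  structure(list(components = comp, n_components = components,
                 resid_norm = sqrt(sum(stats::resid(best)^2)),
                 fitted = fitted_fun),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit (%d component%s), residual norm %.3g\n",
              x$n_components, if (x$n_components > 1) "s" else "",
              x$resid_norm))
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit single- or bi-exponential kinetics
#'
#' Onset form `y = y0 + sum_i a_i (1 - exp(-t / tau_i))`, decay form
#' `y = y0 + sum_i a_i exp(-t / tau_i)`; `t` is measured from the first
#' sample of the segment.  Bi-exponential fits are started from several
#' deterministic tau pairs; components are reported fast-first.  A trace
#' with (numerically) no signal is returned with zero amplitudes and
#' `degenerate = TRUE`; a fitted tau exceeding the segment length sets
#' `tau_flagged`.
#'
#' @param times_ms sample times, ms (the segment must start at the event).
#' @param y trace values.
#' @param components 1 or 2.
#' @param form `"onset"` or `"decay"`.
#' @return object of class `exponential_fit`: list with `components` (data
#'   frame: amplitude, tau_ms, tau_se), `y0`, `resid_norm`, `degenerate`,
#'   `tau_flagged`, `fitted`.
#' @export
fit_exponentials <- function(times_ms, y, components = 1,
                             form = c("onset", "decay")) {
  form <- match.arg(form)
  stopifnot(components %in% c(1, 2), length(times_ms) == length(y))
  t <- times_ms - times_ms[1]
  span <- max(t)
  if (length(t) < 10 * components)
    stop("need at least 10 samples per exponential component")
  amp_scale <- diff(range(y))
  if (amp_scale < 1e-12 * max(abs(y), 1e-300) || amp_scale == 0) {
    comp <- data.frame(amplitude = rep(0, components),
                       tau_ms = rep(NA_real_, components),
                       tau_se = rep(NA_real_, components))
    return(structure(list(components = comp, y0 = mean(y), resid_norm = 0,
                          degenerate = TRUE, tau_flagged = FALSE,
                          fitted = function(tt) rep(mean(y), length(tt))),
                     class = "exponential_fit"))
  }
  df <- data.frame(t = t, y = y)
  sgn <- if (form == "onset") (y[length(y)] - y[1]) else (y[1] - y[length(y)])
  a0 <- abs(sgn) * sign(sgn)
  model1 <- if (form == "onset") y ~ y0 + a1 * (1 - exp(-t / tau1))
            else y ~ y0 + a1 * exp(-t / tau1)
  model2 <- if (form == "onset")
    y ~ y0 + a1 * (1 - exp(-t / tau1)) + a2 * (1 - exp(-t / tau2))
  else y ~ y0 + a1 * exp(-t / tau1) + a2 * exp(-t / tau2)

  best <- NULL; best_rss <- Inf
  if (components == 1) {
    taus <- span / c(3, 10, 30, 100)
    for (tau0 in taus) {
      st <- list(y0 = if (form == "onset") y[1] else y[length(y)],
                 a1 = a0, tau1 = tau0)
      fit <- tryCatch(minpack.lm::nlsLM(model1, df, start = st,
               lower = c(y0 = -Inf, a1 = -Inf, tau1 = span * 1e-4),
               control = minpack.lm::nls.lm.control(maxiter = 300)),
               error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (rss < best_rss) { best <- fit; best_rss <- rss }
      }
    }
  } else {
    pairs <- list(c(100, 2), c(30, 3), c(50, 1.5), c(200, 5),
                  c(20, 1.2), c(10, 2))
    for (p in pairs) {
      st <- list(y0 = if (form == "onset") y[1] else y[length(y)],
                 a1 = a0 / 2, tau1 = span / p[1],
                 a2 = a0 / 2, tau2 = span / p[2])
      fit <- tryCatch(minpack.lm::nlsLM(model2, df, start = st,
               lower = c(y0 = -Inf, a1 = -Inf, tau1 = span * 1e-4,
                         a2 = -Inf, tau2 = span * 1e-4),
               control = minpack.lm::nls.lm.control(maxiter = 400)),
               error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (rss < best_rss) { best <- fit; best_rss <- rss }
      }
    }
  }
  if (is.null(best)) stop("exponential fit failed to converge")
  cf <- stats::coef(best)
  ses <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                  error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                      names(cf)))
  if (components == 1) {
    comp <- data.frame(amplitude = unname(cf["a1"]),
                       tau_ms = unname(cf["tau1"]),
                       tau_se = unname(ses["tau1"]))
  } else {
    ord <- order(c(cf["tau1"], cf["tau2"]))   # fast first
    comp <- data.frame(amplitude = unname(c(cf["a1"], cf["a2"])[ord]),
                       tau_ms = unname(c(cf["tau1"], cf["tau2"])[ord]),
                       tau_se = unname(c(ses["tau1"], ses["tau2"])[ord]))
  }
  fitted_fun <- local({
    comp_ <- comp; y0_ <- unname(cf["y0"]); form_ <- form
    function(tt) {
      out <- rep(y0_, length(tt))
      for (i in seq_len(nrow(comp_)))
        out <- out + if (form_ == "onset")
          comp_$amplitude[i] * (1 - exp(-tt / comp_$tau_ms[i]))
        else comp_$amplitude[i] * exp(-tt / comp_$tau_ms[i])
      out
    }
  })
  structure(list(components = comp, y0 = unname(cf["y0"]),
                 resid_norm = sqrt(best_rss),
                 degenerate = all(abs(comp$amplitude) <
                                    1e-6 * max(abs(y), 1e-300)),
                 tau_flagged = any(comp$tau_ms > span, na.rm = TRUE),
                 fitted = fitted_fun),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential fit (%d component%s), residual norm %.3g%s\n",
              nrow(x$components), if (nrow(x$components) > 1) "s" else "",
              x$resid_norm,
              if (x$degenerate) " [degenerate]" else ""))
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare mono- vs bi-exponential fits by F-test
#'
#' Fits both models to the segment and selects the bi-exponential one when
#' the extra-sum-of-squares F-test rejects the mono-exponential at `alpha`.
#'
#' @inheritParams fit_exponentials
#' @param alpha significance level (default 0.01).
#' @return list with `fit` (the selected `exponential_fit`), `selected`
#'   (1 or 2), `p_value`, `f_statistic`.
#' @export
select_exponential <- function(times_ms, y, form = c("onset", "decay"),
                               alpha = 0.01) {
  form <- match.arg(form)
  f1 <- fit_exponentials(times_ms, y, 1, form)
  f2 <- fit_exponentials(times_ms, y, 2, form)
  n <- length(y)
  rss1 <- f1$resid_norm^2; rss2 <- f2$resid_norm^2
  df1 <- n - 3; df2 <- n - 5
  fstat <- if (rss2 <= 0) Inf else ((rss1 - rss2) / (df1 - df2)) / (rss2 / df2)
  p <- stats::pf(fstat, df1 - df2, df2, lower.tail = FALSE)
  if (is.finite(fstat) && p < alpha)
    list(fit = f2, selected = 2L, p_value = p, f_statistic = fstat)
  else
    list(fit = f1, selected = 1L, p_value = p, f_statistic = fstat)
}

#' Rb+/K+ tail-current amplitude ratio
#'
#' Estimates the instantaneous tail amplitude in each ion condition (as in
#' [extract_gv()]) on the shared protocol and returns their ratio
#' (Rb over K).  This is a tail-amplitude ratio — the experimental proxy for
#' relative permeability — not a flux-equation permeability.
#'
#' @param rec_K,rec_Rb [recording()]s in K+- and Rb+-based external
#'   solutions on the same protocol.
#' @param tail_window_ms fit window after the tail step, ms.
#' @param tail_start_ms tail-step time, ms (metadata/auto when `NULL`).
#' @return object of class `permeability_result`: list with `ratio`,
#'   `amplitude_K`, `amplitude_Rb`, `se`.
#' @export
permeability_ratio <- function(rec_K, rec_Rb, tail_window_ms = c(20, 300),
                               tail_start_ms = NULL) {
  if (length(rec_K$times) != length(rec_Rb$times) ||
      max(abs(rec_K$voltage - rec_Rb$voltage)) > 1e-9)
    stop("recordings do not share the same voltage protocol")
  t0 <- tail_start_of(rec_K, tail_start_ms)
  aK <- tail_amplitude(rec_K$times, rec_K$current, t0, tail_window_ms)
  aRb <- tail_amplitude(rec_Rb$times, rec_Rb$current, t0, tail_window_ms)
  if (abs(aK$amplitude) < 1e-12)
    stop("K+ tail amplitude is (near) zero; ratio undefined")
  ratio <- aRb$amplitude / aK$amplitude
  se <- if (is.finite(aK$se) && is.finite(aRb$se))
    abs(ratio) * sqrt((aRb$se / aRb$amplitude)^2 + (aK$se / aK$amplitude)^2)
  else NA_real_
  structure(list(ratio = ratio, amplitude_K = aK$amplitude,
                 amplitude_Rb = aRb$amplitude, se = se),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("Rb+/K+ tail-amplitude ratio: %.4g (K: %.4g, Rb: %.4g)\n",
              x$ratio, x$amplitude_K, x$amplitude_Rb))
  invisible(x)
}

#' Fraction-inhibited time series from paired control/drug recordings
#'
#' @param rec_ctl,rec_drug paired [recording()]s on the same protocol.
#' @param eps currents smaller than `eps` times the maximum control current
#'   are masked (`NA`) to avoid dividing by noise.
#' @return numeric series `1 - I_drug(t) / I_ctl(t)`.
#' @export
fraction_inhibited <- function(rec_ctl, rec_drug, eps = 1e-3) {
  if (length(rec_ctl$times) != length(rec_drug$times))
    stop("recordings differ in length")
  out <- 1 - rec_drug$current / rec_ctl$current
  out[abs(rec_ctl$current) < eps * max(abs(rec_ctl$current))] <- NA_real_
  out
}

#' Hill fit (coefficient fixed at 1) of a dose-inhibition table
#'
#' Fits `f = f_max * c / (c + IC50)` to fractions inhibited versus
#' inhibitor concentration.
#'
#' @param conc_uM concentrations, uM (strictly positive, >= 3 values).
#' @param fraction fractions inhibited, in \[0, 1\].
#' @return object of class `dose_response_fit`: list with `ic50_uM`,
#'   `f_max`, `hill` (always 1), `resid_norm`, `ic50_se`.
#' @export
dose_response <- function(conc_uM, fraction) {
  stopifnot(length(conc_uM) == length(fraction))
  if (length(conc_uM) < 3) stop("need at least 3 concentrations")
  if (any(conc_uM <= 0)) stop("concentrations must be strictly positive")
  if (any(fraction < -0.05 | fraction > 1.05))
    stop("fractions inhibited must lie in [0, 1]")
  if (all(abs(fraction) < 1e-12)) stop("all-zero inhibition; IC50 undefined")
  df <- data.frame(c = conc_uM, f = fraction)
  fit <- minpack.lm::nlsLM(f ~ fmax * c / (c + ic50), data = df,
                           start = list(fmax = max(fraction),
                                        ic50 = stats::median(conc_uM)),
                           lower = c(fmax = 1e-6, ic50 = 1e-9),
                           upper = c(fmax = 1.2, ic50 = Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) c(fmax = NA_real_, ic50 = NA_real_))
  structure(list(ic50_uM = unname(cf["ic50"]), f_max = unname(cf["fmax"]),
                 hill = 1, resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 ic50_se = unname(ses["ic50"])),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Hill fit (n = 1): IC50 = %.4g uM, max inhibition = %.4g\n",
              x$ic50_uM, x$f_max))
  invisible(x)
}
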