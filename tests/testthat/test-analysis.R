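## small builder for hand-constructed recordings
make_rec <- function(times, fluor = NULL, current = NULL, voltage = NULL,
                     meta = list()) {
  n <- length(times)
  recording(times,
            if (is.null(voltage)) rep(-80, n) else voltage,
            if (is.null(current)) numeric(n) else current,
            if (is.null(fluor)) rep(1000, n) else fluor,
            meta)
}

test_that("delta-F/F recovers a doubling over a constant baseline", {
  t <- seq(0, 4000)
  f <- ifelse(t < 2500, 1000, 2000)
  dff <- delta_f_over_f(make_rec(t, fluor = f), pulse_start_ms = 2500)
  expect_equal(dff$dff[t >= 2500], rep(1, sum(t >= 2500)), tolerance = 1e-12)
  expect_equal(dff$dff[t < 2500], rep(0, sum(t < 2500)), tolerance = 1e-12)
})

test_that("a pure linear drift is removed entirely", {
  t <- seq(0, 6000)
  f <- 800 - 0.02 * t
  dff <- delta_f_over_f(make_rec(t, fluor = f), pulse_start_ms = 3000)
  expect_lt(max(abs(dff$dff)), 1e-12)
})

test_that("delta-F/F inverts a constructed drift-times-signal trace", {
  t <- seq(0, 7000)
  s <- ifelse(t < 2500, 0, 0.08 * (1 - exp(-(t - 2500) / 400)))
  f <- (900 - 0.015 * t) * (1 + s)
  dff <- delta_f_over_f(make_rec(t, fluor = f), pulse_start_ms = 2500)
  expect_lt(max(abs(dff$dff - s)), 1e-6)
})

test_that("delta-F/F demands a full pre-pulse baseline window", {
  t <- seq(0, 3000)
  expect_error(delta_f_over_f(make_rec(t), pulse_start_ms = 1000),
               "insufficient")
  expect_error(delta_f_over_f(make_rec(t)), "pulse_start_ms")
})

test_that("tail extrapolation is exact on noiseless mono-exponential tails", {
  t <- seq(0, 1000)
  for (A in c(2.5, -1.2)) {
    y <- ifelse(t < 100, 0, A * exp(-(t - 100) / 150))
    ta <- tail_amplitude(t, y, step_time_ms = 100)
    expect_true(ta$converged)
    expect_equal(ta$amplitude, A, tolerance = 1e-9)
    expect_equal(ta$tau_ms, 150, tolerance = 1e-6)
  }
  ## with a steady offset the instantaneous value is offset + amplitude
  y2 <- ifelse(t < 100, 0, 0.4 + 1.8 * exp(-(t - 100) / 90))
  expect_equal(tail_amplitude(t, y2, 100)$amplitude, 2.2, tolerance = 1e-9)
})

test_that("identical recordings give a flat normalised GV", {
  t <- seq(0, 8000)
  v <- ifelse(t < 2500, -80, ifelse(t < 6500, 20, ifelse(t < 7500, 60, -80)))
  cur <- ifelse(t < 6500, 0, 3 * exp(-(t - 6500) / 200))
  recs <- lapply(c(-40, 0, 40), function(tv)
    make_rec(t, current = cur, voltage = v,
             meta = list(test_mV = tv, tail_start_ms = 6500)))
  gv <- extract_gv(recs)
  expect_equal(gv$norm, rep(1, 3), tolerance = 1e-9)
})

test_that("GV recovered from noisy synthetic recordings matches model truth", {
  p <- default_kcnq1()
  volts <- seq(-80, 60, by = 20)
  acq <- acquisition_spec(current_noise_sd = 0.005, fluor_noise_sd = 0.005,
                          seed = 71)
  recs <- generate_experiment(
    experiment_design("vcf_family", test_voltages = volts), p, acq)$recordings
  gv <- extract_gv(recs)
  truth <- steady_state_curves(p, volts, method = "pulse")$gv
  expect_lt(max(abs(gv$norm - truth$norm)), 0.01)
})

test_that("single-Boltzmann fits are exact on their own model family", {
  vt <- 1000 * 8.31446 * 298.15 / 96485.332
  V <- seq(-80, 40, by = 10)
  y <- 1 / (1 + exp(-2 * (V - (-20)) / vt))
  fit <- fit_boltzmann(V, y, 1)
  expect_equal(fit$components$z, 2, tolerance = 1e-3)
  expect_equal(fit$components$vhalf_mV, -20, tolerance = 1e-3)
  ## the fitted midpoint sits where the curve crosses half its amplitude
  expect_equal(fit$fitted(fit$components$vhalf_mV),
               fit$components$amplitude / 2, tolerance = 1e-9)
})

test_that("two well-separated Boltzmann components are recovered under noise", {
  vt <- 1000 * 8.31446 * 298.15 / 96485.332
  V <- seq(-120, 120, by = 5)
  clean <- 0.5 / (1 + exp(-2 * (V + 40) / vt)) +
    0.5 / (1 + exp(-2 * (V - 40) / vt))
  y <- withr::with_seed(73, clean + stats::rnorm(length(V), 0, 0.01))
  fit <- fit_boltzmann(V, y, 2)
  comp <- fit$components
  expect_equal(comp$component, c("main", "high"))
  expect_equal(comp$vhalf_mV[1], -40, tolerance = 0.02)
  expect_equal(comp$vhalf_mV[2], 40, tolerance = 0.02)
  expect_equal(comp$z, c(2, 2), tolerance = 0.1)
  expect_equal(comp$fraction, c(0.5, 0.5), tolerance = 0.05)
})

test_that("two-component fits are exact on noiseless mixtures", {
  vt <- 1000 * 8.31446 * 298.15 / 96485.332
  V <- seq(-120, 120, by = 10)
  clean <- 0.6 / (1 + exp(-1.8 * (V + 45) / vt)) +
    0.4 / (1 + exp(-1.2 * (V - 30) / vt))
  comp <- fit_boltzmann(V, clean, 2)$components
  expect_equal(comp$vhalf_mV, c(-45, 30), tolerance = 1e-3)
  expect_equal(comp$z, c(1.8, 1.2), tolerance = 1e-3)
  expect_equal(comp$fraction, c(0.6, 0.4), tolerance = 1e-3)
})

test_that("exponential onset fits recover their generating kinetics", {
  t <- seq(0, 1500)
  y1 <- 2 * (1 - exp(-t / 150))
  f1 <- fit_exponentials(t, y1, 1)
  expect_equal(f1$components$tau_ms, 150, tolerance = 5e-3)
  expect_equal(f1$components$amplitude, 2, tolerance = 5e-3)

  t2 <- seq(0, 4000)
  clean <- 1 * (1 - exp(-t2 / 50)) + 1 * (1 - exp(-t2 / 1000))
  y2 <- withr::with_seed(79, clean + stats::rnorm(length(t2), 0, 0.02))
  f2 <- fit_exponentials(t2, y2, 2)
  expect_equal(f2$components$tau_ms, c(50, 1000), tolerance = 0.05)
  expect_equal(f2$components$amplitude, c(1, 1), tolerance = 0.05)
})

test_that("a constant trace yields a degenerate exponential fit", {
  f <- fit_exponentials(seq(0, 500), rep(3.2, 501), 1)
  expect_true(f$degenerate)
  expect_equal(f$components$amplitude, 0)
})

test_that("tail-amplitude ratios behave like the permeability proxy", {
  t <- seq(0, 9000)
  v <- ifelse(t < 2500, -80, ifelse(t < 7500, 60, -60))
  tail_cur <- function(scale)
    ifelse(t < 7500, 1, scale * 2 * exp(-(t - 7500) / 250))
  meta <- list(tail_start_ms = 7500)
  rK <- make_rec(t, current = tail_cur(1), voltage = v, meta = meta)
  ## identical recordings: ratio 1
  expect_equal(permeability_ratio(rK, rK)$ratio, 1, tolerance = 1e-9)
  ## doubling the Rb tail doubles the ratio
  r2 <- make_rec(t, current = tail_cur(2), voltage = v, meta = meta)
  expect_equal(permeability_ratio(rK, r2)$ratio, 2, tolerance = 1e-9)
})

test_that("permeability round-trip recovers the configured conductance ratio", {
  p <- default_kcnq1()
  acq <- acquisition_spec(current_noise_sd = 0.005, fluor_noise_sd = 0.005,
                          seed = 83)
  ex <- generate_experiment(experiment_design("permeability", g_ratio = 0.7),
                            p, acq)
  pr <- permeability_ratio(ex$recordings$K, ex$recordings$Rb)
  expect_equal(pr$ratio, ex$manifest$g_ratio, tolerance = 0.01)
})

test_that("mismatched protocols are rejected for permeability ratios", {
  t <- seq(0, 1000)
  a <- make_rec(t, current = exp(-t / 100), voltage = rep(-60, length(t)))
  b <- make_rec(t, current = exp(-t / 100), voltage = rep(-40, length(t)))
  expect_error(permeability_ratio(a, b), "protocol")
})

test_that("the Hill fit (n = 1) recovers dose-response parameters", {
  conc <- c(0.2, 0.7, 2, 7, 20)
  f <- 0.9 * conc / (conc + 2)
  fit <- dose_response(conc, f)
  expect_equal(fit$ic50_uM, 2, tolerance = 0.02)
  expect_equal(fit$f_max, 0.9, tolerance = 0.02)
  ## half-maximal inhibition at the fitted IC50 by construction
  expect_equal(fit$f_max * fit$ic50_uM / (fit$ic50_uM + fit$ic50_uM),
               fit$f_max / 2)
})

test_that("dose-response input validation catches degenerate tables", {
  expect_error(dose_response(c(1, 2, 4), rep(0, 3)), "all-zero")
  expect_error(dose_response(c(-1, 2, 4), c(0.1, 0.3, 0.5)), "positive")
  expect_error(dose_response(c(1, 2), c(0.1, 0.2)), "at least 3")
})

test_that("no drug means zero inhibition throughout", {
  t <- seq(0, 1000)
  r <- make_rec(t, current = 1 + t / 1000)
  fi <- fraction_inhibited(r, r)
  expect_equal(fi, rep(0, length(t)), tolerance = 1e-12)
})

test_that("recording CSV round-trips losslessly", {
  p <- default_kcnq1()
  rec <- generate_recording(p, voltage_protocol(c(100, 100), c(-80, 20)),
                            acquisition_spec(current_noise_sd = 0.01,
                                             fluor_noise_sd = 0.01,
                                             seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$current, rec$current)
  expect_equal(back$fluorescence, rec$fluorescence)
  expect_equal(back$meta$seed, rec$meta$seed)
  expect_equal(back$meta$ion, rec$meta$ion)
})
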