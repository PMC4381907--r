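test_that("zero noise and Nyquist cutoff reproduce the simulator exactly", {
  p <- default_kcnq1()
  proto <- voltage_protocol(c(200, 300), c(-80, 20))
  acq <- quiet_acq()                       # cutoff = Nyquist, no noise
  rec <- generate_recording(p, proto, acq)
  obs <- observables(simulate_protocol(p, proto), p, "K")
  expect_equal(rec$current, obs$current, tolerance = 1e-12)
  ## fluorescence is the model signal mapped through the intensity model
  expected_f <- acq$baseline_intensity *
    (1 + acq$bleach_per_s * obs$time_ms / 1000) +
    acq$baseline_intensity * acq$dff_max * obs$fluor_raw
  expect_equal(rec$fluorescence, expected_f, tolerance = 1e-12)
})

test_that("generation is bit-reproducible under a fixed seed", {
  p <- default_kcnq1()
  proto <- voltage_protocol(c(100, 200), c(-80, 0))
  acq <- acquisition_spec(current_noise_sd = 0.02, fluor_noise_sd = 0.02,
                          seed = 99)
  r1 <- generate_recording(p, proto, acq)
  r2 <- generate_recording(p, proto, acq)
  expect_identical(r1$current, r2$current)
  expect_identical(r1$fluorescence, r2$fluorescence)
  ## and the global RNG stream is untouched
  s1 <- withr::with_seed(1, stats::runif(1))
  invisible(generate_recording(p, proto, acq))
  expect_identical(s1, withr::with_seed(1, stats::runif(1)))
})

test_that("added current noise has the configured standard deviation", {
  p <- default_kcnq1()
  proto <- voltage_protocol(c(2000, 4000), c(-80, 40))
  clean <- generate_recording(p, proto, quiet_acq())
  noisy <- generate_recording(p, proto,
                              acquisition_spec(current_noise_sd = 0.01,
                                               fluor_noise_sd = 0,
                                               f_cutoff_hz = 500, seed = 17))
  resid <- noisy$current - clean$current
  expect_gt(length(resid), 5000)
  expect_equal(stats::sd(resid), 0.01 * max(abs(clean$current)),
               tolerance = 0.05)
})

test_that("the low-pass filter slows fluorescence but conserves its plateau", {
  p <- default_kcnq1()
  proto <- voltage_protocol(c(2000, 2000), c(-80, 40))
  raw <- generate_recording(p, proto, quiet_acq())
  filt <- generate_recording(p, proto, quiet_acq(f_cutoff_hz = 200))
  expect_false(isTRUE(all.equal(raw$fluorescence, filt$fluorescence)))
  n <- length(raw$fluorescence)
  expect_equal(filt$fluorescence[n], raw$fluorescence[n], tolerance = 1e-4)
})

test_that("the VCF family emits one consistent recording per test voltage", {
  p <- default_kcnq1()
  volts <- seq(-120, 120, by = 20)
  ex <- generate_experiment(experiment_design("vcf_family",
                                              test_voltages = volts),
                            p, acquisition_spec(seed = 3))
  expect_length(ex$recordings, 13)
  expect_equal(unname(vapply(ex$recordings, function(r) r$meta$test_mV,
                             numeric(1))), volts)
  expect_equal(ex$manifest$test_voltages, volts)
  seeds <- vapply(ex$recordings, function(r) r$meta$seed, numeric(1))
  expect_false(any(duplicated(seeds)))
})

test_that("noiseless dose-response inhibition follows the Hill curve by construction", {
  des <- experiment_design("dose_response", ic50_uM = 2,
                           concentrations_uM = c(0.5, 2, 8))
  p <- default_kcnq1()
  ex <- generate_experiment(des, p, quiet_acq())
  expect_equal(ex$manifest$fraction_at_conc,
               0.9 * c(0.5, 2, 8) / (c(0.5, 2, 8) + 2))
  ## measured inhibition at 2 s of depolarisation reaches f(c)*(1-exp(-2000/tau))
  ctl <- ex$recordings$control
  drug <- ex$recordings[["xe991_2uM"]]
  fi <- fraction_inhibited(ctl, drug)
  i2s <- which(ctl$times == ctl$meta$pulse_start_ms + 2000)
  expect_equal(fi[i2s], 0.45 * (1 - exp(-2000 / des$tau_block_ms)),
               tolerance = 1e-6)
})

test_that("dose-response round-trip recovers the generating IC50", {
  des <- experiment_design("dose_response", ic50_uM = 2)
  p <- default_kcnq1()
  ex <- generate_experiment(des, p, acquisition_spec(seed = 21))
  ctl <- ex$recordings$control
  t_meas <- ctl$meta$pulse_start_ms + 2000
  idx <- which.min(abs(ctl$times - t_meas))
  win <- (idx - 25):(idx - 1)        # average a short window against noise
  fr <- vapply(des$concentrations_uM, function(cc) {
    drug <- ex$recordings[[sprintf("xe991_%guM", cc)]]
    mean(fraction_inhibited(ctl, drug)[win])
  }, numeric(1))
  fit <- dose_response(des$concentrations_uM, fr)
  expect_equal(fit$ic50_uM, des$ic50_uM, tolerance = 0.05)
})

test_that("kcne1_pair designs carry their perturbation in the manifest", {
  p <- default_kcnq1()
  ex <- generate_experiment(
    experiment_design("kcne1_pair", test_voltages = c(-40, 40),
                      perturbation = kcne1_perturbation()),
    p, acquisition_spec(seed = 8))
  expect_named(ex$recordings, c("baseline", "perturbed"))
  expect_equal(ex$manifest$factors$IC, 20)
  expect_equal(ex$manifest$factors$AO, 5)
  expect_length(ex$recordings$baseline, 2)
})

test_that("acquisition specs are validated", {
  expect_error(acquisition_spec(f_cutoff_hz = 900), "Nyquist")
  expect_error(acquisition_spec(current_noise_sd = 0.01), "seed")
  expect_error(experiment_design("dose_response",
                                 concentrations_uM = c(-1, 2)), "positive")
})
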