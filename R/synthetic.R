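#' Acquisition settings for synthetic recordings
#'
#' Emulates two-electrode voltage-clamp plus fluorometry acquisition:
#' current sampled at `sample_rate_hz`, fluorescence low-pass filtered at
#' `f_cutoff_hz` (zero-phase second-order Butterworth — the digital
#' stand-in for the rig's analog filter) and independent additive Gaussian
#' noise on each channel.  Fluorescence is emitted as a raw intensity:
#' `baseline_intensity` scaled by a slow linear bleach plus the
#' physiological signal scaled to a maximal relative change of `dff_max`.
#'
#' Noise magnitudes are calibration choices of this package, not measured
#' values: 1% of the maximal current and 2% of the maximal fluorescence
#' deflection are typical of clean oocyte recordings.
#'
#' @param sample_rate_hz samples per second (default 1000).
#' @param f_cutoff_hz fluorescence low-pass cutoff, Hz (default 200); must
#'   not exceed Nyquist, and filtering is skipped when equal to Nyquist.
#' @param current_noise_sd Gaussian noise sd, as a fraction of max `|I|`.
#' @param fluor_noise_sd Gaussian noise sd, as a fraction of the maximal
#'   fluorescence deflection from baseline.
#' @param seed integer seed; mandatory whenever a noise sd is non-zero.
#' @param baseline_intensity resting fluorescence intensity (arbitrary).
#' @param bleach_per_s linear baseline drift rate, per second (fractional).
#' @param dff_max maximal relative fluorescence change of the label.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sample_rate_hz = 1000, f_cutoff_hz = 200,
                             current_noise_sd = 0.01, fluor_noise_sd = 0.02,
                             seed = NULL,
                             baseline_intensity = 1000,
                             bleach_per_s = -0.005, dff_max = 0.1) {
  stopifnot(sample_rate_hz > 0, f_cutoff_hz > 0,
            current_noise_sd >= 0, fluor_noise_sd >= 0,
            baseline_intensity > 0, dff_max > 0)
  if (f_cutoff_hz > sample_rate_hz / 2)
    stop("fluorescence cutoff exceeds the Nyquist frequency")
  if ((current_noise_sd > 0 || fluor_noise_sd > 0) && is.null(seed))
    stop("a seed is mandatory when noise is added")
  structure(list(sample_rate_hz = sample_rate_hz, f_cutoff_hz = f_cutoff_hz,
                 current_noise_sd = current_noise_sd,
                 fluor_noise_sd = fluor_noise_sd,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 baseline_intensity = baseline_intensity,
                 bleach_per_s = bleach_per_s, dff_max = dff_max),
            class = "acquisition_spec")
}

## zero-phase 2nd-order Butterworth low-pass; skipped at the Nyquist limit.
## The trace is extended by odd reflection at both ends before filtering so
## the filter's startup transient does not distort the trace boundaries.
lowpass <- function(x, cutoff_hz, sample_rate_hz) {
  if (cutoff_hz >= sample_rate_hz / 2) return(x)
  bf <- signal::butter(2, cutoff_hz / (sample_rate_hz / 2), type = "low")
  n <- length(x)
  np <- min(n - 1, max(50, ceiling(6 * sample_rate_hz / cutoff_hz)))
  xp <- c(2 * x[1] - x[(np + 1):2],
          x,
          2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1):(np + n)]
}

#' Generate one synthetic VCF recording
#'
#' Simulates noiseless observables with [simulate_protocol()] /
#' [observables()], converts the model fluorescence into a raw intensity
#' with a bleaching baseline, applies the acquisition low-pass filter to
#' the fluorescence signal, adds seeded Gaussian noise to both channels and
#' stamps full provenance in the metadata.  Bit-reproducible for identical
#' `(params, protocol, acq)`.
#'
#' @param params a [gating_parameters()] object.
#' @param protocol a [voltage_protocol()]; its sampling interval must match
#'   the acquisition sample rate.
#' @param acq an [acquisition_spec()].
#' @param ion ion condition (default `"K"`).
#' @param current_scale extra multiplicative factor on the current channel
#'   (used e.g. for drug-block emulation).
#' @return a [recording()].
#' @export
generate_recording <- function(params, protocol, acq, ion = "K",
                               current_scale = 1) {
  stopifnot(inherits(acq, "acquisition_spec"))
  if (abs(protocol$dt - 1000 / acq$sample_rate_hz) > 1e-9)
    stop("protocol sampling interval does not match acquisition sample rate")
  traj <- simulate_protocol(params, protocol)
  obs <- observables(traj, params, ion)
  current <- obs$current * current_scale

  t_s <- obs$time_ms / 1000
  base <- acq$baseline_intensity * (1 + acq$bleach_per_s * t_s)
  sig <- acq$baseline_intensity * acq$dff_max *
    lowpass(obs$fluor_raw, acq$f_cutoff_hz, acq$sample_rate_hz)
  fluor <- base + sig

  if (acq$current_noise_sd > 0 || acq$fluor_noise_sd > 0) {
    noise <- withr::with_seed(acq$seed, {
      list(i = stats::rnorm(length(current), 0,
                            acq$current_noise_sd * max(abs(current), 1e-300)),
           f = stats::rnorm(length(fluor), 0,
                            acq$fluor_noise_sd * max(abs(sig), 1e-300)))
    })
    current <- current + noise$i
    fluor <- fluor + noise$f
  }
  ## convention for the shipped presets: segment 1 = pre-pulse holding,
  ## segment 2 = test pulse, segment 3 = tail
  seg_ends <- cumsum(protocol$durations)
  nseg <- length(seg_ends)
  meta <- list(ion = ion, seed = acq$seed,
               sample_rate_hz = acq$sample_rate_hz,
               params_digest = params_digest(params))
  if (nseg >= 2) {
    meta$pulse_start_ms <- seg_ends[1]
    meta$test_mV <- protocol$voltages[2]
  }
  if (nseg >= 3) meta$tail_start_ms <- seg_ends[2]
  recording(obs$time_ms, obs$voltage_mV, current, fluor, meta = meta)
}

#' Experiment design for synthetic data families
#'
#' @param kind one of `"vcf_family"`, `"permeability"`, `"dose_response"`,
#'   `"kcne1_pair"`.
#' @param test_voltages test voltages, mV (`vcf_family`, `kcne1_pair`).
#' @param g_ratio Rb/K conductance ratio (`permeability`).
#' @param E_rev_mV reversal potential in the high-external-K+/Rb+ tail
#'   solutions, mV (`permeability`; default 0, reflecting ~100 mM external
#'   permeant ion against a similar internal concentration).
#' @param concentrations_uM inhibitor concentrations, uM (`dose_response`).
#' @param ic50_uM,f_max,tau_block_ms phenomenological block parameters
#'   (`dose_response`): the drug trace's current is the control current
#'   scaled by `1 - f(c) * (1 - exp(-t/tau_block))` with
#'   `f(c) = f_max * c / (c + ic50)`.
#' @param perturbation a [perturbation()] (`kcne1_pair`).
#' @param test_mV single test voltage for `dose_response` pulses, mV.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(kind = c("vcf_family", "permeability",
                                       "dose_response", "kcne1_pair"),
                              test_voltages = seq(-120, 120, by = 20),
                              g_ratio = 0.7, E_rev_mV = 0,
                              concentrations_uM = c(0.2, 0.7, 2, 7, 20),
                              ic50_uM = 2, f_max = 0.9, tau_block_ms = 700,
                              perturbation = kcne1_perturbation(),
                              test_mV = 40) {
  kind <- match.arg(kind)
  if (kind == "dose_response" && any(concentrations_uM <= 0))
    stop("concentrations must be strictly positive")
  if (kind == "permeability" && g_ratio <= 0)
    stop("conductance ratio must be positive")
  structure(list(kind = kind, test_voltages = test_voltages,
                 g_ratio = g_ratio, E_rev_mV = E_rev_mV,
                 concentrations_uM = concentrations_uM,
                 ic50_uM = ic50_uM, f_max = f_max,
                 tau_block_ms = tau_block_ms,
                 perturbation = perturbation, test_mV = test_mV),
            class = "experiment_design")
}

#' Generate a full synthetic experiment
#'
#' Emits the recording family for the chosen design plus a ground-truth
#' manifest listing every generating value a downstream analysis should
#' recover.  Per-recording seeds are derived deterministically from the
#' acquisition seed.
#'
#' * `vcf_family`: one recording per test voltage on the VCF protocol
#'   (4 s pulses, +60 mV tails).
#' * `permeability`: K+ and Rb+ recordings on the +60 mV / -60 mV tail
#'   protocol, with `g_Rb = g_ratio * g_K`.
#' * `dose_response`: a control plus one recording per concentration, the
#'   drug current scaled by the phenomenological slow-block factor.
#' * `kcne1_pair`: baseline and coupling-perturbed VCF families.
#'
#' @param design an [experiment_design()].
#' @param params a [gating_parameters()] object.
#' @param acq an [acquisition_spec()] (its seed seeds the whole family).
#' @return list with `recordings` (named list) and `manifest` (list of
#'   generating values).
#' @export
generate_experiment <- function(design, params, acq) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(acq, "acquisition_spec"))
  base_seed <- if (is.na(acq$seed)) 0L else acq$seed
  acq_k <- function(k) {
    a <- acq
    a$seed <- as.integer((base_seed + k) %% .Machine$integer.max)
    a
  }
  if (design$kind == "vcf_family") {
    recs <- lapply(seq_along(design$test_voltages), function(i) {
      generate_recording(params,
                         protocol_preset("vcf_family",
                                         test_mV = design$test_voltages[i]),
                         acq_k(i))
    })
    names(recs) <- sprintf("v_%+04d", design$test_voltages)
    manifest <- list(kind = "vcf_family",
                     test_voltages = design$test_voltages,
                     params_digest = params_digest(params))
  } else if (design$kind == "permeability") {
    ## high external K+/Rb+ tail solutions: shifted reversal potential
    params_k <- params
    params_k$E_rev[["K"]] <- design$E_rev_mV
    params_rb <- params
    params_rb$g[["Rb"]] <- design$g_ratio * params$g[["K"]]
    params_rb$E_rev[["Rb"]] <- design$E_rev_mV
    proto <- protocol_preset("permeability")
    recs <- list(K = generate_recording(params_k, proto, acq_k(1), ion = "K"),
                 Rb = generate_recording(params_rb, proto, acq_k(2),
                                         ion = "Rb"))
    manifest <- list(kind = "permeability", g_ratio = design$g_ratio,
                     params_digest = params_digest(params))
  } else if (design$kind == "dose_response") {
    proto <- protocol_preset("xe991", test_mV = design$test_mV)
    ctl <- generate_recording(params, proto, acq_k(1))
    pulse_start <- proto$durations[1]
    recs <- list(control = ctl)
    fr <- design$f_max * design$concentrations_uM /
      (design$concentrations_uM + design$ic50_uM)
    for (i in seq_along(design$concentrations_uM)) {
      ## noiseless control, scaled by the developing block, then noised
      clean <- generate_recording(params, proto, acquisition_spec(
        sample_rate_hz = acq$sample_rate_hz, f_cutoff_hz = acq$f_cutoff_hz,
        current_noise_sd = 0, fluor_noise_sd = 0,
        baseline_intensity = acq$baseline_intensity,
        bleach_per_s = acq$bleach_per_s, dff_max = acq$dff_max))
      t_rel <- pmax(clean$times - pulse_start, 0)
      block <- 1 - fr[i] * (1 - exp(-t_rel / design$tau_block_ms))
      a <- acq_k(1 + i)
      cur <- clean$current * block
      flr <- clean$fluorescence
      if (a$current_noise_sd > 0 || a$fluor_noise_sd > 0) {
        sig_amp <- max(abs(flr - stats::median(flr)), 1e-300)
        noise <- withr::with_seed(a$seed, {
          list(i = stats::rnorm(length(cur), 0,
                                a$current_noise_sd * max(abs(cur), 1e-300)),
               f = stats::rnorm(length(flr), 0, a$fluor_noise_sd * sig_amp))
        })
        cur <- cur + noise$i
        flr <- flr + noise$f
      }
      meta <- clean$meta
      meta$drug_conc_uM <- design$concentrations_uM[i]
      meta$seed <- a$seed
      recs[[sprintf("xe991_%guM", design$concentrations_uM[i])]] <-
        recording(clean$times, clean$voltage, cur, flr, meta)
    }
    manifest <- list(kind = "dose_response",
                     concentrations_uM = design$concentrations_uM,
                     ic50_uM = design$ic50_uM, f_max = design$f_max,
                     tau_block_ms = design$tau_block_ms,
                     fraction_at_conc = fr,
                     params_digest = params_digest(params))
  } else {  # kcne1_pair
    perturbed <- apply_perturbation(params, design$perturbation)
    fam <- function(p, off) {
      recs <- lapply(seq_along(design$test_voltages), function(i) {
        generate_recording(p, protocol_preset("vcf_family",
                                              test_mV = design$test_voltages[i]),
                           acq_k(off + i))
      })
      names(recs) <- sprintf("v_%+04d", design$test_voltages)
      recs
    }
    recs <- list(baseline = fam(params, 0),
                 perturbed = fam(perturbed, 100))
    manifest <- list(kind = "kcne1_pair",
                     factors = unclass(design$perturbation),
                     test_voltages = design$test_voltages,
                     params_digest = params_digest(params))
  }
  list(recordings = recs, manifest = manifest)
}
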