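## random but physically plausible parameter draws (call under a fixed seed)
random_params <- function(theta_random = TRUE) {
  th <- if (theta_random) stats::rlnorm(6, 0, 0.8) else rep(1, 6)
  gating_parameters(
    kRI = rate_law(stats::rlnorm(1, log(30), 0.8), stats::runif(1, 0.2, 1.2)),
    kIR = rate_law(stats::rlnorm(1, log(8), 0.8), stats::runif(1, -1.2, -0.2)),
    kIA = rate_law(stats::rlnorm(1, log(2), 0.8), stats::runif(1, 0.1, 0.8)),
    kAI = rate_law(stats::rlnorm(1, log(3), 0.8), stats::runif(1, -0.8, -0.1)),
    kCO = stats::rlnorm(1, log(10), 0.8),
    kOC = stats::rlnorm(1, log(60), 0.8),
    theta_RC = th[1], theta_IC = th[2], theta_AC = th[3],
    theta_RO = th[4], theta_IO = th[5], theta_AO = th[6]
  )
}

## noiseless acquisition (pass-through apart from the fluorescence filter)
quiet_acq <- function(sample_rate_hz = 1000, f_cutoff_hz = sample_rate_hz / 2)
  acquisition_spec(sample_rate_hz = sample_rate_hz,
                   f_cutoff_hz = f_cutoff_hz,
                   current_noise_sd = 0, fluor_noise_sd = 0)
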