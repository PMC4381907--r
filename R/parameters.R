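#' Physical constants
#'
#' Faraday constant, gas constant and absolute temperature used in the
#' voltage dependence of VSD transition rates.  Defaults correspond to room
#' temperature (25 C).
#'
#' @param F_const Faraday constant, C/mol.
#' @param R_const gas constant, J/(mol K).
#' @param T_kelvin absolute temperature, K.
#' @return object of class `physical_constants`.
#' @export
physical_constants <- function(F_const = 96485.332,
                               R_const = 8.31446,
                               T_kelvin = 298.15) {
  stopifnot(F_const > 0, R_const > 0, T_kelvin > 0)
  structure(list(F = F_const, R = R_const, T = T_kelvin),
            class = "physical_constants")
}

## RT/F in millivolts (thermal voltage); ~25.693 mV at 298.15 K
thermal_voltage_mV <- function(constants = physical_constants()) {
  1000 * constants$R * constants$T / constants$F
}

#' Voltage-dependent rate law for a VSD transition
#'
#' A transition rate is `k0 * exp(z * F * V / (R * T))` where `k0` is the
#' rate at 0 mV and `z` the equivalent valence (signed, in elementary
#' charges).
#'
#' @param k0 rate at 0 mV, per second; must be positive.
#' @param z equivalent valence; may be zero or negative.
#' @return object of class `rate_law`.
#' @export
rate_law <- function(k0, z) {
  stopifnot(is.numeric(k0), length(k0) == 1, is.finite(k0), k0 > 0,
            is.numeric(z), length(z) == 1, is.finite(z))
  structure(list(k0 = k0, z = z), class = "rate_law")
}

#' Gating-model parameter set
#'
#' Bundles everything the allosteric gating scheme needs: intrinsic VSD rate
#' laws for the resting-intermediate and intermediate-activated transitions,
#' voltage-independent intrinsic pore rates, the six VSD-pore coupling
#' strengths theta, channel count and per-ion conductances for translating
#' open probability into current, and fluorescence weights for the two VSD
#' steps.
#'
#' A coupling `theta_XP > 1` stabilises the channel state that pairs VSD
#' conformation `X` with pore state `P` and slows every transition leaving
#' that state.  There is a gauge degeneracy: multiplying all closed-state
#' couplings by a constant is equivalent to rescaling `kCO`, so by default
#' the resting-state couplings are fixed at 1 and act as the reference.
#'
#' @param kRI,kIR,kIA,kAI [rate_law()] objects for the four VSD transitions.
#' @param kCO,kOC intrinsic pore opening/closing rates, per second
#'   (voltage-independent).
#' @param theta_RC,theta_IC,theta_AC,theta_RO,theta_IO,theta_AO per-VSD
#'   coupling strengths (dimensionless, > 0).
#' @param N number of channels.
#' @param g named numeric vector of maximal single-channel conductances per
#'   ion condition (arbitrary units).
#' @param E_rev named numeric vector of reversal potentials per ion
#'   condition, mV.
#' @param f_I,f_A relative fluorescence of an intermediate / activated VSD
#'   (resting = 0); `f_A >= f_I >= 0`.
#' @param constants a [physical_constants()] object.
#' @return object of class `gating_parameters`.
#' @export
gating_parameters <- function(kRI, kIR, kIA, kAI,
                              kCO, kOC,
                              theta_RC = 1, theta_IC = 1, theta_AC = 1,
                              theta_RO = 1, theta_IO = 1, theta_AO = 1,
                              N = 1000,
                              g = c(K = 0.01, Rb = 0.007, Na = 0.0002),
                              E_rev = c(K = -80, Rb = -80, Na = -80),
                              f_I = 0.8, f_A = 1.0,
                              constants = physical_constants()) {
  for (rl in list(kRI, kIR, kIA, kAI))
    if (!inherits(rl, "rate_law")) stop("VSD rates must be rate_law objects")
  th <- c(theta_RC, theta_IC, theta_AC, theta_RO, theta_IO, theta_AO)
  if (!all(is.finite(th)) || any(th <= 0))
    stop("all coupling strengths theta must be positive and finite")
  if (!is.finite(kCO) || !is.finite(kOC) || kCO <= 0 || kOC <= 0)
    stop("pore rates kCO, kOC must be positive")
  if (!(f_A >= f_I && f_I >= 0))
    stop("fluorescence weights must satisfy f_A >= f_I >= 0")
  if (is.null(names(g)) || is.null(names(E_rev)))
    stop("g and E_rev must be named by ion condition")
  structure(list(
    kRI = kRI, kIR = kIR, kIA = kIA, kAI = kAI,
    kCO = kCO, kOC = kOC,
    theta = c(RC = theta_RC, IC = theta_IC, AC = theta_AC,
              RO = theta_RO, IO = theta_IO, AO = theta_AO),
    N = N, g = g, E_rev = E_rev,
    f_I = f_I, f_A = f_A,
    constants = constants
  ), class = "gating_parameters")
}

#' @export
print.gating_parameters <- function(x, ...) {
  cat("Allosteric VSD-pore gating parameters\n")
  cat(sprintf("  kRI: %.4g/s (z=%+.3g)   kIR: %.4g/s (z=%+.3g)\n",
              x$kRI$k0, x$kRI$z, x$kIR$k0, x$kIR$z))
  cat(sprintf("  kIA: %.4g/s (z=%+.3g)   kAI: %.4g/s (z=%+.3g)\n",
              x$kIA$k0, x$kIA$z, x$kAI$k0, x$kAI$z))
  cat(sprintf("  pore: kCO=%.4g/s, kOC=%.4g/s\n", x$kCO, x$kOC))
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  cat(sprintf("  N=%g channels; f_I=%.3g, f_A=%.3g; T=%.2f K\n",
              x$N, x$f_I, x$f_A, x$constants$T))
  invisible(x)
}

#' Default KCNQ1-like parameter set
#'
#' A hand-tuned baseline whose steady-state and kinetic behaviour is
#' qualitatively KCNQ1-like: the first VSD step (resting to intermediate) is
#' fast and half-activates near -45 mV, the second (intermediate to
#' activated) is slow and half-activates near +25 mV, the pore opens mainly
#' from intermediate-VSD states (`theta_IO > 1`) so the conductance-voltage
#' curve tracks the low-voltage fluorescence component, current onset is
#' biphasic, and maximal open probability is well below saturation, leaving
#' room for coupling perturbations to increase current severalfold.
#'
#' These values are the package's own calibration, not published estimates.
#'
#' @return a [gating_parameters()] object.
#' @export
default_kcnq1 <- function() {
  gating_parameters(
    kRI = rate_law(60, 0.6),
    kIR = rate_law(5, -0.8),
    kIA = rate_law(0.8, 0.4),
    kAI = rate_law(2.0, -0.5),
    kCO = 2, kOC = 700,
    theta_RC = 1, theta_IC = 1, theta_AC = 1,
    theta_RO = 1, theta_IO = 3, theta_AO = 3.5
  )
}

#' Read gating parameters from a YAML file
#'
#' The file mirrors the [gating_parameters()] fields: VSD rate laws as
#' mappings with `k0` (per second) and `z` (elementary charges), pore rates
#' and couplings as scalars, `g`/`E_rev` as mappings keyed by ion condition.
#' See `system.file("extdata", "default_kcnq1.yaml", package = "iksgating")`
#' for a complete annotated example.
#'
#' @param path file path.
#' @return a [gating_parameters()] object.
#' @export
read_gating_parameters <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("kRI", "kIR", "kIA", "kAI", "kCO", "kOC")
  if (!all(need %in% names(y)))
    stop("parameter file missing fields: ",
         paste(setdiff(need, names(y)), collapse = ", "))
  rl <- function(f) rate_law(y[[f]]$k0, y[[f]]$z)
  const <- if (!is.null(y$constants))
    physical_constants(y$constants$F, y$constants$R, y$constants$T)
  else physical_constants()
  args <- list(
    kRI = rl("kRI"), kIR = rl("kIR"), kIA = rl("kIA"), kAI = rl("kAI"),
    kCO = y$kCO, kOC = y$kOC, constants = const
  )
  for (f in c("theta_RC", "theta_IC", "theta_AC",
              "theta_RO", "theta_IO", "theta_AO",
              "N", "f_I", "f_A"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  for (f in c("g", "E_rev"))
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  do.call(gating_parameters, args)
}

#' Write gating parameters to a YAML file
#'
#' @param params a [gating_parameters()] object.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_gating_parameters <- function(params, path) {
  stopifnot(inherits(params, "gating_parameters"))
  y <- list(
    kRI = list(k0 = params$kRI$k0, z = params$kRI$z),
    kIR = list(k0 = params$kIR$k0, z = params$kIR$z),
    kIA = list(k0 = params$kIA$k0, z = params$kIA$z),
    kAI = list(k0 = params$kAI$k0, z = params$kAI$z),
    kCO = params$kCO, kOC = params$kOC,
    theta_RC = unname(params$theta["RC"]), theta_IC = unname(params$theta["IC"]),
    theta_AC = unname(params$theta["AC"]), theta_RO = unname(params$theta["RO"]),
    theta_IO = unname(params$theta["IO"]), theta_AO = unname(params$theta["AO"]),
    N = params$N,
    g = as.list(params$g), E_rev = as.list(params$E_rev),
    f_I = params$f_I, f_A = params$f_A,
    constants = list(F = params$constants$F, R = params$constants$R,
                     T = params$constants$T)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

## short textual digest of a parameter set, for recording provenance
params_digest <- function(params) {
  v <- c(params$kRI$k0, params$kRI$z, params$kIR$k0, params$kIR$z,
         params$kIA$k0, params$kIA$z, params$kAI$k0, params$kAI$z,
         params$kCO, params$kOC, params$theta, params$N,
         params$g, params$E_rev, params$f_I, params$f_A)
  paste(signif(v, 8), collapse = ",")
}
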