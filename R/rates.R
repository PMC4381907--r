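#' Voltage-dependent VSD transition rate
#'
#' Evaluates `k0 * exp(z * F * V / (R * T))` with the membrane voltage given
#' in millivolts (converted to volts internally).  The exponent magnitude is
#' capped at 700 (with a warning) to avoid silent floating-point overflow at
#' physically absurd voltages.
#'
#' @param law a [rate_law()] object.
#' @param V membrane voltage, mV (vectorised).
#' @param constants a [physical_constants()] object.
#' @return rate(s) in per second; strictly positive.
#' @examples
#' vsd_rate(rate_law(100, 1.2), 0)   # 100 at 0 mV regardless of z
#' @export
vsd_rate <- function(law, V, constants = physical_constants()) {
  stopifnot(inherits(law, "rate_law"), all(is.finite(V)))
  expo <- law$z * constants$F * (V / 1000) / (constants$R * constants$T)
  if (any(abs(expo) > 700)) {
    warning("rate-law exponent exceeds 700 in magnitude; clamping")
    expo <- pmin(pmax(expo, -700), 700)
  }
  law$k0 * exp(expo)
}

## all four VSD rates at voltage V, as a named list
vsd_rates_at <- function(params, V) {
  list(RI = vsd_rate(params$kRI, V, params$constants),
       IR = vsd_rate(params$kIR, V, params$constants),
       IA = vsd_rate(params$kIA, V, params$constants),
       AI = vsd_rate(params$kAI, V, params$constants))
}

#' Build the transition-rate matrix of the aggregated gating scheme
#'
#' Constructs the generator `Q` over the canonical state order of
#' [enumerate_states()]: `Q[i, j]` is the rate from state `i` to state `j`
#' and each diagonal entry is minus its row sum.  Only single-component
#' transitions are non-zero:
#'
#' * a VSD step `X -> Y` with the pore in state `P` proceeds at
#'   `n_X * k_XY(V) / theta_XP` — the number of eligible VSDs times the
#'   intrinsic rate, slowed by the transitioning VSD's coupling to the
#'   current pore state;
#' * pore opening proceeds at
#'   `kCO / (theta_RC^n_R * theta_IC^n_I * theta_AC^n_A)` and closing at
#'   `kOC / (theta_RO^n_R * theta_IO^n_I * theta_AO^n_A)` — the intrinsic
#'   pore rate divided by all couplings to the state being left.
#'
#' Dividing every departure rate by the couplings of the state being left
#' makes each `theta > 1` a pure stabilisation of that state and guarantees
#' detailed balance around every cycle of the scheme.
#'
#' @param params a [gating_parameters()] object.
#' @param V membrane voltage, mV (scalar).
#' @param states optional state table; must equal `enumerate_states(n_vsd)`.
#' @param n_vsd number of VSDs (default 4).
#' @return a `2 * choose(n_vsd + 2, 2)` square matrix (30 x 30 for the
#'   tetramer) with `dimnames` set to the canonical state labels.
#' @export
build_rate_matrix <- function(params, V, states = NULL, n_vsd = 4L) {
  stopifnot(inherits(params, "gating_parameters"),
            length(V) == 1, is.finite(V))
  canon <- enumerate_states(n_vsd)
  if (is.null(states)) {
    states <- canon
  } else if (!identical(states[c("pore", "n_R", "n_I", "n_A")],
                        canon[c("pore", "n_R", "n_I", "n_A")])) {
    stop("`states` is not in the canonical order of enumerate_states()")
  }
  th <- params$theta
  if (any(th <= 0)) stop("coupling strengths theta must be positive")
  k <- vsd_rates_at(params, V)
  n <- nrow(states)
  Q <- matrix(0, n, n, dimnames = list(states$label, states$label))

  idx <- function(pore, nR, nI, nA) state_index(states, pore, nR, nI, nA)
  for (i in seq_len(n)) {
    p  <- states$pore[i]
    nR <- states$n_R[i]; nI <- states$n_I[i]; nA <- states$n_A[i]
    ## VSD steps; theta of (transitioning VSD state, current pore state)
    if (nR > 0)
      Q[i, idx(p, nR - 1, nI + 1, nA)] <- nR * k$RI / th[paste0("R", p)]
    if (nI > 0) {
      Q[i, idx(p, nR + 1, nI - 1, nA)] <- nI * k$IR / th[paste0("I", p)]
      Q[i, idx(p, nR, nI - 1, nA + 1)] <- nI * k$IA / th[paste0("I", p)]
    }
    if (nA > 0)
      Q[i, idx(p, nR, nI + 1, nA - 1)] <- nA * k$AI / th[paste0("A", p)]
    ## pore step, slowed by every VSD's coupling to the pore state being left
    if (p == "C") {
      Q[i, idx("O", nR, nI, nA)] <-
        params$kCO / (th["RC"]^nR * th["IC"]^nI * th["AC"]^nA)
    } else {
      Q[i, idx("C", nR, nI, nA)] <-
        params$kOC / (th["RO"]^nR * th["IO"]^nI * th["AO"]^nA)
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## log Gibbs weight of each canonical state at voltage V (unnormalised)
state_log_weights <- function(params, V, states, n_vsd = 4L) {
  k <- vsd_rates_at(params, V)
  lKRI <- log(k$RI) - log(k$IR)
  lKIA <- log(k$IA) - log(k$AI)
  lKCO <- log(params$kCO) - log(params$kOC)
  th <- params$theta
  logmult <- lgamma(n_vsd + 1) - lgamma(states$n_R + 1) -
    lgamma(states$n_I + 1) - lgamma(states$n_A + 1)
  ltheta <- ifelse(states$pore == "C",
                   states$n_R * log(th["RC"]) + states$n_I * log(th["IC"]) +
                     states$n_A * log(th["AC"]),
                   states$n_R * log(th["RO"]) + states$n_I * log(th["IO"]) +
                     states$n_A * log(th["AO"]))
  logmult + (states$n_I + states$n_A) * lKRI + states$n_A * lKIA +
    ifelse(states$pore == "O", lKCO, 0) + ltheta
}

#' Equilibrium distribution of the gating scheme
#'
#' The scheme satisfies detailed balance, so its unique stationary
#' distribution has closed-form Gibbs weights
#' `w = multinomial(n_vsd; n_R, n_I, n_A) * K_RI(V)^(n_I + n_A) *
#' K_IA(V)^(n_A) * K_CO^[open] * prod(theta_XP^n_X)` (couplings with the
#' current pore state `P`), normalised to sum to one.  Weights are evaluated
#' in log space, so extreme voltages do not overflow.
#'
#' @param params a [gating_parameters()] object.
#' @param V membrane voltage, mV (scalar).
#' @param method `"closed_form"` (default) for the Gibbs weights, or
#'   `"nullspace"` to solve the stationary condition `pi Q = 0` from the
#'   rate matrix by singular-value decomposition (used as a cross-check).
#' @param n_vsd number of VSDs.
#' @return named probability vector over the canonical state order.
#' @export
equilibrium_distribution <- function(params, V,
                                     method = c("closed_form", "nullspace"),
                                     n_vsd = 4L) {
  method <- match.arg(method)
  states <- enumerate_states(n_vsd)
  if (method == "closed_form") {
    lw <- state_log_weights(params, V, states, n_vsd)
    w <- exp(lw - max(lw))
    p <- w / sum(w)
  } else {
    Q <- build_rate_matrix(params, V, n_vsd = n_vsd)
    sv <- svd(t(Q))
    d <- sv$d
    if (d[length(d) - 1] < 1e-10 * max(d))
      warning(sprintf(
        "stationary solve is ill-conditioned (two smallest singular values %.3g, %.3g)",
        d[length(d) - 1], d[length(d)]))
    v <- sv$v[, length(d)]
    if (sum(v) < 0) v <- -v
    if (any(v < -1e-8 * max(abs(v))))
      warning("nullspace vector has significant negative entries")
    v <- pmax(v, 0)
    p <- v / sum(v)
  }
  names(p) <- states$label
  p
}

#' Total equilibrium open probability
#'
#' @param params a [gating_parameters()] object.
#' @param V membrane voltage(s), mV (vectorised).
#' @return numeric vector of open probabilities.
#' @export
equilibrium_open_probability <- function(params, V) {
  states <- enumerate_states()
  vapply(V, function(v) {
    sum(equilibrium_distribution(params, v)[states$pore == "O"])
  }, numeric(1))
}
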