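## ---- master-equation propagation -----------------------------------------
##
## Within a constant-voltage segment the occupancy obeys dp/dt = p Q (row
## convention, Q from build_rate_matrix, rates in 1/s, time in s).  Because
## the scheme is reversible, D^{1/2} Q D^{-1/2} is symmetric when D is the
## diagonal of the stationary distribution at that voltage, so the matrix
## exponential is computed from a symmetric eigendecomposition; if the
## symmetrisation is numerically poor (stationary weights underflowing at
## extreme voltages) we fall back to scaling-and-squaring (Matrix::expm)
## stepped sample to sample.

## eigen machinery for exp(Q t) at one voltage; NULL if symmetrisation fails
segment_propagator <- function(params, V, n_vsd = 4L) {
  Q <- build_rate_matrix(params, V, n_vsd = n_vsd)
  states <- enumerate_states(n_vsd)
  lw <- state_log_weights(params, V, states, n_vsd)
  w <- exp(lw - max(lw))
  pi_v <- w / sum(w)
  ok <- all(pi_v > 1e-250)
  if (ok) {
    s <- sqrt(pi_v)
    S <- Q * outer(s, 1 / s)
    asym <- max(abs(S - t(S))) / max(abs(S))
    if (is.finite(asym) && asym < 1e-7) {
      eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
      return(list(Q = Q, type = "eigen", U = eg$vectors,
                  lambda = eg$values, s = s))
    }
  }
  list(Q = Q, type = "expm")
}

## occupancy rows at the requested times (s) within one segment, given p0
propagate_segment <- function(prop, p0, times_s) {
  n <- length(p0)
  if (prop$type == "eigen") {
    a <- drop((p0 / prop$s) %*% prop$U)           # coefficients
    E <- exp(outer(times_s, prop$lambda))         # T x n
    occ <- (E * matrix(a, nrow(E), n, byrow = TRUE)) %*% t(prop$U)
    occ <- occ * matrix(prop$s, nrow(occ), n, byrow = TRUE)
    ## eigen-route roundoff can leave ~1e-9 negatives when the stationary
    ## weights span many orders; redo the segment by scaling-and-squaring
    if (any(!is.finite(occ)) || min(occ) < -1e-9) {
      prop$type <- "expm"
      occ <- propagate_segment(prop, p0, times_s)
    }
  } else {
    dts <- diff(c(0, times_s))
    occ <- matrix(NA_real_, length(times_s), n)
    p <- p0
    last_dt <- -1; M <- NULL
    for (i in seq_along(times_s)) {
      dt <- dts[i]
      if (dt > 0) {
        if (dt != last_dt) {
          M <- as.matrix(Matrix::expm(prop$Q * dt))
          last_dt <- dt
        }
        p <- drop(p %*% M)
      }
      occ[i, ] <- p
    }
  }
  occ
}

#' Integrate the master equation under a voltage protocol
#'
#' Propagates the 30-state occupancy through each constant-voltage segment
#' with the exact matrix exponential of that segment's rate matrix, sampled
#' on the protocol's grid; segments chain continuously.
#'
#' @param params a [gating_parameters()] object.
#' @param protocol a [voltage_protocol()].
#' @param initial `"equilibrium"` (default; equilibrium at the holding
#'   potential) or an explicit probability vector over the canonical state
#'   order.
#' @param n_vsd number of VSDs (default 4).
#' @return object of class `occupancy_trajectory`: list with `times` (ms),
#'   `occupancy` (time x states matrix, canonical order), `voltage` (mV per
#'   sample), `protocol`, `states`.
#' @export
simulate_protocol <- function(params, protocol, initial = "equilibrium",
                              n_vsd = 4L) {
  stopifnot(inherits(params, "gating_parameters"),
            inherits(protocol, "voltage_protocol"))
  states <- enumerate_states(n_vsd)
  nstate <- nrow(states)
  if (identical(initial, "equilibrium")) {
    p0 <- equilibrium_distribution(params, protocol$holding, n_vsd = n_vsd)
  } else {
    p0 <- as.numeric(initial)
    if (length(p0) != nstate || abs(sum(p0) - 1) > 1e-6 || any(p0 < 0))
      stop("explicit initial occupancy must be a probability vector over ",
           nstate, " states")
  }
  samp <- protocol_samples(protocol)
  occ <- matrix(NA_real_, length(samp$times), nstate,
                dimnames = list(NULL, states$label))
  seg_start <- c(0, cumsum(protocol$durations))
  p <- p0
  for (s in seq_along(protocol$durations)) {
    sel <- which(samp$segment == s)
    rel_ms <- samp$times[sel] - seg_start[s]
    prop <- segment_propagator(params, protocol$voltages[s], n_vsd)
    occ[sel, ] <- propagate_segment(prop, p, rel_ms / 1000)
    ## advance to the segment end to seed the next segment
    p <- drop(propagate_segment(prop, p, protocol$durations[s] / 1000))
    if (any(!is.finite(p)))
      stop(sprintf("non-finite occupancy in segment %d (%g mV)",
                   s, protocol$voltages[s]))
  }
  if (any(!is.finite(occ)) || any(occ < -1e-9))
    stop("master-equation integration produced invalid occupancies")
  occ <- pmax(occ, 0)
  occ <- occ / rowSums(occ)
  structure(list(times = samp$times, occupancy = occ,
                 voltage = samp$voltage, protocol = protocol,
                 states = states),
            class = "occupancy_trajectory")
}

## occupancy at a single time point (ms) of a constant-voltage segment
endpoint_occupancy <- function(params, V, p0, t_ms, n_vsd = 4L) {
  prop <- segment_propagator(params, V, n_vsd)
  p <- drop(propagate_segment(prop, p0, t_ms / 1000))
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Macroscopic observables of an occupancy trajectory
#'
#' Maps state occupancies to the quantities an electrophysiology rig
#' records: total open probability, ohmic macroscopic current
#' `I = N * g_ion * P_open * (V - E_rev,ion)`, and relative fluorescence
#' `F = sum_states P(state) * (n_I * f_I + n_A * f_A) / n_vsd` (reported raw
#' and normalised to its maximum over the trace).
#'
#' @param traj an `occupancy_trajectory` from [simulate_protocol()].
#' @param params the [gating_parameters()] used to simulate it.
#' @param ion ion condition; must name entries of `params$g` and
#'   `params$E_rev` (default `"K"`).
#' @return data frame with columns `time_ms`, `voltage_mV`, `p_open`,
#'   `current`, `fluor_raw`, `fluor_norm`.
#' @export
observables <- function(traj, params, ion = "K") {
  stopifnot(inherits(traj, "occupancy_trajectory"))
  if (!ion %in% names(params$g) || !ion %in% names(params$E_rev))
    stop("unknown ion condition: ", ion)
  states <- traj$states
  n_vsd <- states$n_R[1] + states$n_I[1] + states$n_A[1]
  p_open <- rowSums(traj$occupancy[, states$pore == "O", drop = FALSE])
  fw <- (states$n_I * params$f_I + states$n_A * params$f_A) / n_vsd
  f_raw <- drop(traj$occupancy %*% fw)
  fmax <- max(f_raw)
  data.frame(
    time_ms = traj$times,
    voltage_mV = traj$voltage,
    p_open = p_open,
    current = params$N * params$g[[ion]] * p_open *
      (traj$voltage - params$E_rev[[ion]]),
    fluor_raw = f_raw,
    fluor_norm = if (fmax > 0) f_raw / fmax else f_raw
  )
}

#' Steady-state conductance-voltage and fluorescence-voltage curves
#'
#' For each test voltage the model is equilibrated at the holding potential,
#' stepped to the test voltage for `pulse_ms`, and the conductance-voltage
#' (GV) point is taken as the instantaneous tail current on stepping to
#' `tail_mV` (open probability at pulse end times the tail driving force);
#' the fluorescence-voltage (FV) point is the fluorescence at pulse end.
#' Both are normalised to the value at the highest test voltage.  With
#' `method = "equilibrium"` the pulse-end occupancy is replaced by the
#' analytic equilibrium at the test voltage (the infinite-pulse limit).
#'
#' Near-equilibration is diagnosed per point: the relative change of open
#' probability over the final 5% of the pulse must stay below `equil_tol`,
#' else the point is flagged (column `equilibrated`).
#'
#' @param params a [gating_parameters()] object.
#' @param test_voltages test-pulse voltages, mV.
#' @param tail_mV tail voltage, mV (default +60); must differ from the
#'   ion's reversal potential.
#' @param pulse_ms test-pulse duration, ms (default 4000).
#' @param method `"pulse"` (default) or `"equilibrium"`.
#' @param ion ion condition for the tail driving force.
#' @param equil_tol relative open-probability drift tolerated over the
#'   final 5% of the pulse.
#' @return list with data frames `gv` and `fv`, each with columns
#'   `voltage_mV`, `raw`, `norm`, `equilibrated`.
#' @export
steady_state_curves <- function(params, test_voltages,
                                tail_mV = 60, pulse_ms = 4000,
                                method = c("pulse", "equilibrium"),
                                ion = "K", equil_tol = 1e-4) {
  method <- match.arg(method)
  if (length(test_voltages) == 0) stop("empty test-voltage list")
  if (abs(tail_mV - params$E_rev[[ion]]) < 1e-9)
    stop("tail voltage equals the reversal potential: zero driving force")
  states <- enumerate_states()
  open <- states$pore == "O"
  fw <- (states$n_I * params$f_I + states$n_A * params$f_A) / 4
  holding <- -80
  p_hold <- equilibrium_distribution(params, holding)
  res <- lapply(test_voltages, function(V) {
    if (method == "equilibrium") {
      p_end <- equilibrium_distribution(params, V)
      eq <- TRUE
    } else {
      prop <- segment_propagator(params, V)
      p_end <- drop(propagate_segment(prop, p_hold, pulse_ms / 1000))
      p_95 <- drop(propagate_segment(prop, p_hold, 0.95 * pulse_ms / 1000))
      po_end <- sum(p_end[open]); po_95 <- sum(p_95[open])
      eq <- abs(po_end - po_95) <= equil_tol * max(po_end, 1e-12)
    }
    c(po = sum(p_end[open]), f = sum(p_end * fw), eq = eq)
  })
  res <- do.call(rbind, res)
  drive <- tail_mV - params$E_rev[[ion]]
  gv_raw <- params$N * params$g[[ion]] * res[, "po"] * drive
  fv_raw <- res[, "f"]
  ref <- which.max(test_voltages)
  if (gv_raw[ref] == 0 || fv_raw[ref] == 0)
    stop("reference (highest-voltage) GV or FV value is zero")
  list(
    gv = data.frame(voltage_mV = test_voltages, raw = gv_raw,
                    norm = gv_raw / gv_raw[ref],
                    equilibrated = as.logical(res[, "eq"])),
    fv = data.frame(voltage_mV = test_voltages, raw = fv_raw,
                    norm = fv_raw / fv_raw[ref],
                    equilibrated = as.logical(res[, "eq"]))
  )
}
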