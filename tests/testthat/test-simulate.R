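test_that("equilibrium initial condition is stationary under the holding potential", {
  p <- default_kcnq1()
  proto <- voltage_protocol(500, -80, sample_interval_ms = 5)
  traj <- simulate_protocol(p, proto)
  drift <- apply(traj$occupancy, 2, function(col) max(abs(col - col[1])))
  expect_lt(max(drift), 1e-9)
})

test_that("occupancy rows stay normalised and within [0, 1]", {
  withr::with_seed(53, {
    for (rep in 1:3) {
      p <- random_params()
      proto <- voltage_protocol(c(50, 200, 100), c(-80, 40, -30),
                                sample_interval_ms = 2)
      traj <- simulate_protocol(p, proto)
      expect_lt(max(abs(rowSums(traj$occupancy) - 1)), 1e-9)
      expect_true(all(traj$occupancy >= 0 & traj$occupancy <= 1))
    }
  })
})

test_that("matrix-exponential propagation matches a fine-step ODE integration", {
  skip_if_not_installed("deSolve")
  p <- default_kcnq1()
  proto <- voltage_protocol(c(40, 60), c(-80, 40), sample_interval_ms = 2)
  traj <- simulate_protocol(p, proto)
  p0 <- equilibrium_distribution(p, -80)
  ## independent route: stiff ODE solve of dp/dt = p Q, 1 us max step
  rhs <- function(t, y, parms) list(drop(y %*% parms))
  sol1 <- deSolve::lsoda(p0, seq(0, 0.040, by = 0.002), rhs,
                         build_rate_matrix(p, -80),
                         rtol = 1e-10, atol = 1e-12, hmax = 1e-6)
  p_mid <- sol1[nrow(sol1), -1]
  sol2 <- deSolve::lsoda(p_mid, seq(0, 0.060, by = 0.002), rhs,
                         build_rate_matrix(p, 40),
                         rtol = 1e-10, atol = 1e-12, hmax = 1e-6)
  ode_occ <- rbind(sol1[, -1], sol2[-1, -1])
  expect_lt(max(abs(ode_occ - traj$occupancy)), 1e-6)
})

test_that("observables vanish in the fully-resting closed state and at reversal", {
  p <- default_kcnq1()
  st <- enumerate_states()
  ## all occupancy on C_RRRR: no fluorescence, no current
  init <- as.numeric(st$label == "C_RRRR")
  proto <- voltage_protocol(10, 0, sample_interval_ms = 1)
  traj <- simulate_protocol(p, proto, initial = init)
  obs <- observables(traj, p, "K")
  expect_equal(obs$fluor_raw[1], 0)
  expect_equal(obs$current[1], 0)
  ## all occupancy open at V = E_rev: zero driving force
  init2 <- as.numeric(st$label == "O_AAAA")
  proto2 <- voltage_protocol(10, p$E_rev[["K"]], sample_interval_ms = 1)
  obs2 <- observables(simulate_protocol(p, proto2, initial = init2), p, "K")
  expect_equal(obs2$current[1], 0)
})

test_that("with equal fluorophore weights the signal is one minus the resting fraction", {
  p <- default_kcnq1()
  p$f_I <- 1; p$f_A <- 1
  proto <- voltage_protocol(c(100, 300), c(-80, 20), sample_interval_ms = 5)
  traj <- simulate_protocol(p, proto)
  obs <- observables(traj, p, "K")
  st <- traj$states
  resting_frac <- drop(traj$occupancy %*% (st$n_R / 4))
  expect_equal(obs$fluor_raw, 1 - resting_frac, tolerance = 1e-12)
})

test_that("unknown ion conditions are rejected", {
  p <- default_kcnq1()
  traj <- simulate_protocol(p, voltage_protocol(10, 0))
  expect_error(observables(traj, p, "Cs"), "ion")
})

test_that("uniform couplings across pore states flatten the normalised GV", {
  p <- default_kcnq1()
  p$theta["RO"] <- p$theta["RC"] <- 1.3
  p$theta["IO"] <- p$theta["IC"] <- 0.6
  p$theta["AO"] <- p$theta["AC"] <- 2.1
  cc <- steady_state_curves(p, seq(-80, 80, 40), method = "equilibrium")
  expect_equal(cc$gv$norm, rep(1, 5), tolerance = 1e-10)
})

test_that("tail-current GV converges to equilibrium open-probability ratios", {
  p <- default_kcnq1()
  V <- seq(-100, 100, by = 25)
  long <- steady_state_curves(p, V, pulse_ms = 15000, method = "pulse")
  eq <- steady_state_curves(p, V, method = "equilibrium")
  expect_true(all(long$gv$equilibrated))
  expect_lt(max(abs(long$gv$norm - eq$gv$norm)), 1e-8)
})

test_that("short pulses are flagged as unequilibrated rather than silently used", {
  p <- default_kcnq1()
  short <- steady_state_curves(p, c(-20, 40), pulse_ms = 100, method = "pulse")
  expect_false(all(short$gv$equilibrated))
})

test_that("the FV curve is non-decreasing for positive-valence activation", {
  p <- default_kcnq1()
  cc <- steady_state_curves(p, seq(-140, 120, by = 10), method = "equilibrium")
  expect_true(all(diff(cc$fv$raw) >= -1e-12))
})

test_that("steady-state curve edge cases error out", {
  p <- default_kcnq1()
  expect_error(steady_state_curves(p, numeric(0)), "empty")
  expect_error(steady_state_curves(p, c(-20, 40), tail_mV = p$E_rev[["K"]]),
               "reversal")
})

test_that("baseline current onset is biphasic; the coupling-perturbed onset is delayed", {
  p <- default_kcnq1()
  proto <- voltage_protocol(4000, 40)
  obs <- observables(simulate_protocol(p, proto), p, "K")
  sel <- select_exponential(obs$time_ms, obs$current, form = "onset")
  expect_equal(sel$selected, 2L)
  expect_lt(sel$p_value, 0.01)
  taus <- sel$fit$components$tau_ms
  expect_lt(taus[1] * 5, taus[2])      # well-separated fast and slow phases
  ## KCNE1-like coupling perturbation: sigmoid onset with a long delay
  pk <- apply_perturbation(p, kcne1_perturbation())
  obsk <- observables(simulate_protocol(pk, proto), pk, "K")
  i_end <- obsk$current[nrow(obsk)]
  t10 <- obsk$time_ms[which(obsk$current >= 0.1 * i_end)[1]]
  expect_gt(t10, 200)
})

test_that("aggregated observables match the labelled-VSD brute-force simulator", {
  withr::with_seed(59, {
    p <- random_params()
    proto <- voltage_protocol(c(30, 80, 40), c(-80, 30, -50),
                              sample_interval_ms = 10)
    traj <- simulate_protocol(p, proto)
    occ_micro <- micro_simulate(p, proto)
    agg <- t(apply(occ_micro, 1, micro_project))
    expect_lt(max(abs(agg - traj$occupancy)), 1e-8)
  })
})
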