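## Independent brute-force model with four *labelled* VSDs: 3^4 VSD
## configurations x 2 pore states = 162 microstates, per-VSD rates without
## multiplicity factors.  Used as an oracle for the aggregated 30-state
## scheme; deliberately coded from scratch (its own rate evaluation, state
## bookkeeping and propagation).

micro_states <- function() {
  g <- expand.grid(s1 = c("R", "I", "A"), s2 = c("R", "I", "A"),
                   s3 = c("R", "I", "A"), s4 = c("R", "I", "A"),
                   pore = c("C", "O"), stringsAsFactors = FALSE)
  g[, c("pore", "s1", "s2", "s3", "s4")]
}

micro_rate <- function(params, from, to, V) {
  law <- params[[paste0("k", from, to)]]
  law$k0 * exp(law$z * params$constants$F * (V / 1000) /
                 (params$constants$R * params$constants$T))
}

## 162 x 162 generator at voltage V
micro_rate_matrix <- function(params, V) {
  ms <- micro_states()
  n <- nrow(ms)
  key <- apply(ms, 1, paste, collapse = "")
  Q <- matrix(0, n, n, dimnames = list(key, key))
  allowed <- list(R = "I", I = c("R", "A"), A = "I")
  th <- params$theta
  for (i in seq_len(n)) {
    pore <- ms$pore[i]
    conf <- unlist(ms[i, c("s1", "s2", "s3", "s4")])
    for (v in 1:4) {
      x <- conf[v]
      for (y in allowed[[x]]) {
        to <- conf; to[v] <- y
        j <- which(key == paste0(pore, paste(to, collapse = "")))
        Q[i, j] <- Q[i, j] + micro_rate(params, x, y, V) /
          th[paste0(x, pore)]
      }
    }
    j <- which(key == paste0(if (pore == "C") "O" else "C",
                             paste(conf, collapse = "")))
    Q[i, j] <- if (pore == "C")
      params$kCO / prod(th[paste0(conf, "C")])
    else
      params$kOC / prod(th[paste0(conf, "O")])
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## project a 162-microstate distribution onto the canonical 30-state order
micro_project <- function(p_micro) {
  ms <- micro_states()
  counts <- t(apply(ms[, c("s1", "s2", "s3", "s4")], 1, function(r)
    c(sum(r == "R"), sum(r == "I"), sum(r == "A"))))
  lab <- paste0(ms$pore, "_", counts[, 1], counts[, 2], counts[, 3])
  agg <- tapply(p_micro, lab, sum)
  canon <- enumerate_states()
  canon_key <- paste0(canon$pore, "_", canon$n_R, canon$n_I, canon$n_A)
  as.numeric(agg[canon_key])
}

## stationary distribution of the microscopic model (eigen of the generator)
micro_equilibrium <- function(params, V) {
  Q <- micro_rate_matrix(params, V)
  ev <- eigen(t(Q))
  k <- which.min(abs(ev$values))
  v <- Re(ev$vectors[, k])
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / sum(v)
}

## occupancy at the given sample times (ms) of a piecewise-constant
## protocol, by repeated scaling-and-squaring matrix exponentials
micro_simulate <- function(params, protocol, p0 = NULL) {
  Qs <- lapply(protocol$voltages, function(V) micro_rate_matrix(params, V))
  if (is.null(p0)) p0 <- micro_equilibrium(params, protocol$holding)
  dt <- protocol$dt / 1000
  nsteps <- round(protocol$durations / protocol$dt)
  occ <- matrix(NA_real_, sum(nsteps) + 1, length(p0))
  occ[1, ] <- p0
  p <- p0
  row <- 1
  for (s in seq_along(nsteps)) {
    M <- as.matrix(Matrix::expm(Qs[[s]] * dt))
    for (k in seq_len(nsteps[s])) {
      p <- drop(p %*% M)
      row <- row + 1
      occ[row, ] <- p
    }
  }
  occ
}
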