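# shared oracles and fixtures, built in code

r1 <- function(...) neuron_preset("region1", ...)
r2 <- function(...) neuron_preset("region2", ...)

# independent vector field (plain R, written separately from the package)
oracle_field <- function(v, u, p) {
  c(v * (p$a - v) * (v - 1) - u + p$I,
    p$alpha * (1 / (1 + exp(-(v - p$beta) / p$eps)) - u))
}

# eigenvalues by the quadratic formula on tr/det (independent of eigen())
oracle_eigs <- function(J) {
  tr <- J[1, 1] + J[2, 2]
  de <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- as.complex(tr^2 - 4 * de)
  (tr + c(1, -1) * sqrt(disc)) / 2
}

# continuous-flow integration with deSolve (oracle for the package stepper)
oracle_continuous <- function(state0, p, times) {
  f <- function(t, y, parms) {
    list(oracle_field(y[1], y[2], p))
  }
  deSolve::lsodar(c(v = state0[1], u = state0[2]), times, f, NULL,
                  rtol = 1e-12, atol = 1e-12)
}

# hybrid spike times with deSolve lsodar root-stopping (independent event
# location; reset applied in R between calls)
oracle_spike_times <- function(state0, p, t_end, max_spikes = 10) {
  f <- function(t, y, parms) list(oracle_field(y[1], y[2], p))
  root <- function(t, y, parms) y[1] - p$v_peak
  spikes <- numeric(0)
  y <- state0
  t0 <- 0
  while (t0 < t_end && length(spikes) < max_spikes) {
    out <- deSolve::lsodar(c(v = y[1], u = y[2]),
                           seq(t0, t_end, length.out = 200), f, NULL,
                           rtol = 1e-12, atol = 1e-12, rootfunc = root)
    tr <- attr(out, "troot")
    if (is.null(tr) || length(tr) == 0) break
    spikes <- c(spikes, tr[1])
    yr <- out[nrow(out), ]
    y <- c(p$v_r, yr[["u"]] + p$d)
    t0 <- tr[1]
  }
  spikes
}

# scalar l-return map via the package (for finite-difference checks)
psi_for_test <- function(p, u0, l) {
  attr(hybridspike::return_map(p, u0, l), "u_out")
}
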