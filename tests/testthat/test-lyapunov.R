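test_that("saltation matrix has the stated structure", {
  p <- r1()
  S <- saltation_matrix(c(p$v_peak, 0.03), p)
  expect_identical(S[1, 2], 0)
  expect_identical(S[2, 2], 1)
  expect_error(saltation_matrix(c(0.3, 0.03), p), "section")
  # degenerate crossing: dv/dt <= 0 on the section
  expect_error(saltation_matrix(c(p$v_peak, 0.2), p), "degenerate")
})

test_that("saltation tends to the identity in the continuity limit", {
  p <- neuron_params(v_peak = 0.4, v_r = 0.4 - 1e-8, d = 1e-8)
  S <- saltation_matrix(c(0.4, 0.03), p)
  expect_lt(max(abs(S - diag(2))), 1e-6)
})

test_that("saltation equals the event sensitivity of the hybrid flow", {
  p <- r1()
  tr <- integrate_hybrid(p, t_end = 20, dt_sample = 0.01)
  sp <- spike_events(tr)
  t_ev <- sp$t[1]
  state_minus <- c(sp$v_minus[1], sp$u_minus[1])
  t_a <- t_ev - 0.5
  TT <- 1.0
  x_a <- attr(integrate_continuous(p, state0 = c(p$v_r, 0), t_end = t_a,
                                   quiescence_tol = 0), "final_state")
  # numerical sensitivity of the through-event flow map over [t_a, t_a + TT]
  G <- function(x) {
    attr(integrate_hybrid(p, state0 = x, t_end = TT, dt_sample = TT,
                          quiescence_tol = 0), "final_state")
  }
  flow <- function(x, tt) {
    attr(integrate_continuous(p, state0 = x, t_end = tt, dt_sample = tt,
                              quiescence_tol = 0), "final_state")
  }
  h <- 1e-6
  fd_jac <- function(f, x, ...) {
    cbind((f(x + c(h, 0), ...) - f(x - c(h, 0), ...)) / (2 * h),
          (f(x + c(0, h), ...) - f(x - c(0, h), ...)) / (2 * h))
  }
  D <- fd_jac(G, x_a)
  A <- fd_jac(flow, x_a, t_ev - t_a)            # continuous, pre-event
  x_plus <- c(p$v_r, state_minus[2] + p$d)
  B <- fd_jac(flow, x_plus, TT - (t_ev - t_a))  # continuous, post-event
  S <- saltation_matrix(state_minus, p)
  composed <- B %*% S %*% A
  expect_lt(max(abs(D - composed) / pmax(abs(composed), 1e-3)), 1e-4)
})

test_that("exponents at a non-spiking equilibrium match the Jacobian", {
  p <- r1(I = 0)
  eq <- find_equilibria(p)
  st <- eq[eq$stable, ]
  ly <- lyapunov_spectrum(p, state0 = c(0.01, 0.001), total_time = 1000,
                          transient = 100, renorm_interval = 1e-3)
  ref <- sort(Re(c(st$m1, st$m2)), decreasing = TRUE)
  expect_lt(max(abs(ly$lambda - ref)), 1e-3)
  expect_identical(as.integer(ly$n_spikes), 0L)
})

test_that("exponent signs separate chaotic and periodic reset settings", {
  ly_c <- lyapunov_spectrum(r1(v_r = 0.33), total_time = 4000,
                            transient = 500, renorm_interval = 0.1)
  expect_gt(ly_c$lambda[1], 1e-3)
  expect_lt(abs(ly_c$lambda[2]), 5e-3) # neutral direction
  ly_p <- lyapunov_spectrum(r1(v_r = 0.25), total_time = 4000,
                            transient = 500, renorm_interval = 0.1)
  expect_lt(abs(ly_p$lambda[1]), 5e-3)
  expect_lt(ly_p$lambda[2], -5e-3)
})

test_that("the reset-free planar flow has no positive exponent", {
  # spiking limit cycle, reset disabled
  ly <- lyapunov_spectrum(r1(), state0 = c(0.1, 0.01), total_time = 3000,
                          transient = 500, renorm_interval = 0.1,
                          reset = FALSE)
  expect_lt(ly$lambda[1], 5e-3)
  # resting flow: both exponents negative
  ly0 <- lyapunov_spectrum(r1(I = 0), state0 = c(0.05, 0), total_time = 1000,
                           transient = 100, renorm_interval = 0.1,
                           reset = FALSE)
  expect_lt(ly0$lambda[1], 0)
})

test_that("exponents are stable under doubling the horizon", {
  args <- list(r1(v_r = 0.25), transient = 500, renorm_interval = 0.1)
  l1 <- do.call(lyapunov_spectrum, c(args, total_time = 2000))
  l2 <- do.call(lyapunov_spectrum, c(args, total_time = 4000))
  expect_lt(max(abs(l1$lambda - l2$lambda)), 5e-3)
})

test_that("multiplier and contracting exponent are consistent", {
  p <- r1(v_r = 0.25)
  orb <- find_periodic_orbit(p, l = 1, u_guess = 0.028)
  ly <- lyapunov_spectrum(p, total_time = 4000, transient = 500,
                          renorm_interval = 0.1)
  expect_equal(log(abs(orb$mu)) / orb$orbit_time, ly$lambda[2],
               tolerance = 1e-2)
})

test_that("lyapunov result bookkeeping is coherent", {
  ly <- lyapunov_spectrum(r1(v_r = 0.25), total_time = 2000, transient = 200,
                          renorm_interval = 0.1)
  expect_gte(ly$lambda[1], ly$lambda[2])
  expect_equal(ly$n_renorm * ly$renorm_interval, ly$total_time - ly$transient,
               tolerance = 1)
  expect_s3_class(ly$trace, "tbl_df")
  expect_gt(nrow(ly$trace), 10)
  g <- glance(ly)
  expect_identical(g$lambda1, ly$lambda[1])
})

test_that("heatmap sweeps classify cells and honour the continuity limit", {
  p <- r1()
  hm <- lyapunov_heatmap(p, v_r_grid = c(0.25, 0.33, 0.399),
                         d_grid = c(0, 0.01), total_time = 1200,
                         transient = 300, refine_band = 0)
  expect_identical(nrow(hm), 6L)
  expect_true(all(c("v_r", "d", "lambda1", "chaotic") %in% names(hm)))
  # the near-continuity corner (v_r ~ v_peak, d = 0) cannot be chaotic
  corner <- hm[hm$v_r == 0.399 & hm$d == 0, ]
  expect_lt(corner$lambda1, 5e-3)
  # the chaotic preset cell is flagged
  expect_true(hm$chaotic[hm$v_r == 0.33 & hm$d == 0.01])
  expect_error(lyapunov_heatmap(p, v_r_grid = 0.41, d_grid = 0), "v_peak")
})
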