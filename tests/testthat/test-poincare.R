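# variational monodromy of the continuous cycle with deSolve (independent
# oracle for the continuity-limit multiplier)
oracle_floquet <- function(p, u_star, T_cyc) {
  f <- function(t, y, parms) {
    dv <- y[1] * (p$a - y[1]) * (y[1] - 1) - y[2] + p$I
    s <- 1 / (1 + exp(-(y[1] - p$beta) / p$eps))
    du <- p$alpha * (s - y[2])
    j11 <- -3 * y[1]^2 + 2 * (p$a + 1) * y[1] - p$a
    j21 <- p$alpha / p$eps * s * (1 - s)
    list(c(dv, du,
           j11 * y[3] - y[4], j21 * y[3] - p$alpha * y[4],
           j11 * y[5] - y[6], j21 * y[5] - p$alpha * y[6]))
  }
  y0 <- c(p$v_peak, u_star, 1, 0, 0, 1)
  out <- deSolve::lsoda(y0, c(0, T_cyc), f, NULL, rtol = 1e-12, atol = 1e-12)
  phi <- matrix(out[2, 4:7], nrow = 2)
  fl <- oracle_field(p$v_peak, u_star, p)
  drop(c(-fl[2] / fl[1], 1) %*% phi %*% c(0, 1))
}

test_that("the return map satisfies its fixed-point contract", {
  p <- r1(v_r = 0.25)
  orb <- find_periodic_orbit(p, l = 1, u_guess = 0.028)
  expect_lt(orb$residual, 1e-9)
  expect_true(orb$stable)
  rm1 <- return_map(p, orb$u_star, l = 1)
  expect_lt(abs(attr(rm1, "u_out") - orb$u_star), 1e-9)
  # profile at a single grid point equals return_map on that point
  pr <- return_map_profile(p, u_grid = orb$u_star, l = 1)
  expect_identical(pr$u_out, attr(rm1, "u_out"))
})

test_that("non-returning starts raise an informative error", {
  p <- r1(I = 0, v_r = 0.1) # resting: the orbit never reaches the section
  err <- tryCatch(return_map(p, 0.0, l = 3, t_cap = 200), error = identity)
  expect_s3_class(err, "hs_non_returning")
  expect_match(conditionMessage(err), "0 of 3")
})

test_that("the reset-free return map is nearly constant", {
  pr <- return_map_profile(r1(), u_grid = seq(-0.02, 0.1, length.out = 9),
                           reset = FALSE)
  expect_true(all(is.finite(pr$u_out)))
  expect_lt(diff(range(pr$u_out)), 0.005)
})

test_that("the reset map at v_r = 0.395 is piecewise near-linear", {
  p <- r1(v_r = 0.395)
  lo <- return_map_profile(p, u_grid = seq(-0.015, 0.05, length.out = 8))
  expect_lt(max(abs(lo$u_out - (lo$u_in + 0.01))), 0.006)
  hi <- return_map_profile(p, u_grid = seq(0.065, 0.095, length.out = 5))
  expect_lt(max(abs(hi$u_out - 0.011)), 0.006)
})

test_that("multipliers match finite differences of the map", {
  h <- 1e-7
  cases <- list(
    list(p = r1(v_r = 0.25), u0 = 0.028, l = 1),
    list(p = r1(v_r = 0.30), u0 = 0.025, l = 2),
    list(p = r1(v_r = 0.33), u0 = 0.030, l = 1),
    list(p = r1(v_r = 0.33), u0 = 0.045, l = 3),
    list(p = r1(v_r = 0.36), u0 = 0.020, l = 2),
    list(p = r1(v_r = 0.395), u0 = 0.030, l = 1),
    list(p = r2(v_r = 0.14), u0 = 0.050, l = 1),
    list(p = r2(v_r = 0.14), u0 = 0.055, l = 2),
    list(p = r2(v_r = 0.15), u0 = 0.047, l = 1),
    list(p = r2(v_r = 0.12), u0 = 0.049, l = 2))
  for (cs in cases) {
    mu <- as.numeric(characteristic_multiplier(cs$p, cs$u0, cs$l))
    fd <- (psi_for_test(cs$p, cs$u0 + h, cs$l) -
           psi_for_test(cs$p, cs$u0 - h, cs$l)) / (2 * h)
    expect_lt(abs(mu - fd) / max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("the continuous cycle's Floquet multiplier matches its contracting exponent", {
  # dual-route check on the reset-free limit cycle: the nontrivial Floquet
  # multiplier from an independently integrated (deSolve) monodromy must
  # agree with the contracting Lyapunov exponent, log|mu| / T = lambda_2.
  # Region 2's cycle (T ~ 28.5, mu ~ 0.16) keeps the one-period monodromy
  # well inside double precision; region 1's cycle contracts by e^-22 per
  # period, beyond what a one-period product can resolve.
  p <- r2()
  u_star <- attr(return_map(p, 0.0449, l = 1, reset = FALSE), "u_out")
  rm_c <- return_map(p, u_star, l = 1, reset = FALSE)
  T_cyc <- rm_c$t[1]
  mu_ref <- oracle_floquet(p, attr(rm_c, "u_in"), T_cyc)
  ly <- lyapunov_spectrum(p, state0 = c(0.2, 0.02), total_time = 5000,
                          transient = 1000, renorm_interval = 0.1,
                          reset = FALSE)
  expect_lt(abs(log(abs(mu_ref)) / T_cyc - ly$lambda[2]), 1e-2)
  expect_lt(abs(ly$lambda[1]), 5e-3) # neutral direction
})

test_that("the burst-regime attractor is periodic on the section", {
  u <- attractor_crossings(r1(v_r = 0.30), n = 30, transient = 400)
  # period-2 in this window: crossings revisit the same u two returns later
  expect_lt(max(abs(diff(u, lag = 2))), 1e-6)
  expect_gt(abs(u[2] - u[1]), 1e-4)
})

test_that("continuation rejects collapse onto a shorter period", {
  p <- r2(v_r = 0.13) # stable period-1 here
  expect_error(find_periodic_orbit(p, l = 2, u_guess = 0.0502),
               class = "hs_wrong_period")
  o <- find_periodic_orbit(p, l = 2, u_guess = 0.0502, strict_period = FALSE)
  expect_equal(o$mu, 1, tolerance = 0.5) # mu^2 = (mu^1)^2 < 1
})

test_that("the first two period-doublings are correctly ordered", {
  p <- r1()
  b1 <- locate_map_bifurcation(p, l = 1, c(0.27, 0.30), target_mu = -1,
                               n_scan = 12)
  b2 <- locate_map_bifurcation(p, l = 2, c(0.30, 0.325), target_mu = -1,
                               n_scan = 12)
  expect_identical(b1$kind, "period-doubling")
  expect_lt(b1$v_r_star, b2$v_r_star)
  expect_lt(abs(b1$mu_at_star + 1), 0.05)
  expect_lt(b2$bracket_width, 1e-4)
})

test_that("jump-sign classification uses the strict depolarising side", {
  p <- r1(v_r = 0.25)
  u <- attractor_crossings(p, n = 100, transient = 300)
  fld <- vector_field(tibble::tibble(v = 0.25, u = as.numeric(u) + p$d), p)
  expect_true(all(fld$dv < 0)) # all resets land on the hyperpolarising side
  # boundary convention: dv = 0 is not the depolarising side
  expect_false(any(fld$dv[fld$dv == 0] > 0))
})

test_that("ISI return maps have the stated structure", {
  p <- r1(v_r = 0.25)
  # |mu| ~ 0.87 per return: settling to the cycle needs ~150 returns
  tr <- integrate_hybrid(p, t_end = 2000, dt_sample = 0.1)
  isi <- isi_return_map(tr)
  n_sp <- nrow(spike_events(tr))
  expect_identical(nrow(isi), n_sp - 2L)
  # periodic spiking collapses onto one point
  late <- dplyr::slice_tail(isi, n = 10)
  expect_lt(diff(range(late$isi_i)), 1e-6)
  expect_lt(diff(range(late$isi_next)), 1e-6)
  # chaotic bursting spreads the intervals
  isic <- isi_return_map(integrate_hybrid(r1(v_r = 0.33), t_end = 400))
  expect_gt(stats::sd(isic$isi_i), 0.1)
  # too few spikes
  short <- integrate_hybrid(p, t_end = 400, max_spikes = 2)
  expect_error(isi_return_map(short), "3 spikes")
})

test_that("bifurcation diagrams resolve the cascade and iterate the map", {
  p <- r1()
  bd <- bifurcation_diagram(p, v_r_grid = c(0.27, 0.30),
                            crossings_per_cell = 30,
                            transient_crossings = 300)
  u27 <- bd$u[bd$v_r == 0.27]
  u30 <- bd$u[bd$v_r == 0.30]
  expect_lt(diff(range(u27)), 1e-6)                # single-valued
  expect_gt(diff(range(u30)), 1e-4)                # period-doubled
  expect_equal(max(abs(bd$post_reset_u - bd$u - p$d)), 0, tolerance = 1e-12)
  # consecutive samples iterate the one-return map
  u_next <- attr(return_map(set_params(p, v_r = 0.27), u27[1], l = 1),
                 "u_out")
  expect_equal(u_next, u27[2], tolerance = 1e-8)
})
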