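test_that("continuous integration matches the deSolve oracle", {
  p <- r1()
  times <- seq(0, 50, by = 0.05)
  ref <- oracle_continuous(c(0.05, 0.02), p, times)
  tr <- integrate_continuous(p, state0 = c(0.05, 0.02), t_end = 50,
                             dt_sample = 0.05)
  idx <- match(round(times, 8), round(tr$t, 8))
  expect_true(all(!is.na(idx)))
  expect_lt(max(abs(tr$v[idx] - ref[, "v"])), 1e-8)
  expect_lt(max(abs(tr$u[idx] - ref[, "u"])), 1e-8)
})

test_that("hybrid spike times match a deSolve root-finding oracle", {
  p <- r1()
  ref <- oracle_spike_times(c(p$v_r, 0), p, t_end = 40, max_spikes = 6)
  tr <- integrate_hybrid(p, t_end = 40)
  got <- spike_events(tr)$t
  expect_gte(length(got), length(ref))
  expect_equal(got[seq_along(ref)], ref, tolerance = 1e-7)
})

test_that("a resting run converges to the stable equilibrium", {
  p <- r1(I = 0)
  tr <- integrate_hybrid(p, state0 = c(0.05, 0), t_end = 2000)
  expect_identical(terminated_reason(tr), "converged")
  eq <- find_equilibria(p)
  st <- eq[eq$stable, ]
  fs <- attr(tr, "final_state")
  expect_lt(abs(fs["v"] - st$v), 1e-4)
  expect_lt(abs(fs["u"] - st$u), 1e-4)
})

test_that("a state on an equilibrium stays on it", {
  p <- r2(I = 0)
  eq <- find_equilibria(p)
  st <- eq[eq$stable, ]
  tr <- integrate_continuous(p, state0 = c(st$v, st$u), t_end = 1000,
                             quiescence_tol = 0, dt_sample = 10)
  expect_lt(max(abs(tr$v - st$v)), 1e-8)
  expect_lt(max(abs(tr$u - st$u)), 1e-8)
})

test_that("the spiking preset shows both burst behaviours", {
  p <- r1() # v_r = 0.33, d = 0.01: chaotic bursting
  tr <- integrate_hybrid(p, t_end = 400)
  sp <- spike_events(tr)
  expect_gt(nrow(sp), 20)
  expect_identical(terminated_reason(tr), "horizon")
  # spike events sit on the section to the event-location tolerance
  ev <- tr[tr$is_spike, ]
  expect_lt(max(abs(ev$v - p$v_peak)), 1e-10)
  # some inter-spike segments hyperpolarise to v ~ 0.25, others re-fire
  # without dipping below v_r
  min_between <- vapply(seq_len(nrow(sp) - 1), function(i) {
    seg <- tr$v[tr$t > sp$t[i] & tr$t < sp$t[i + 1]]
    if (length(seg) > 0) min(seg) else NA_real_
  }, numeric(1))
  expect_true(any(min_between < 0.27, na.rm = TRUE))
  expect_true(any(min_between > 0.3, na.rm = TRUE))
  expect_equal(min(min_between, na.rm = TRUE), 0.25, tolerance = 0.05)
  # spike times strictly increasing, states strictly ordered in time
  expect_true(all(diff(sp$t) > 0))
  expect_true(all(diff(tr$t) >= 0))
})

test_that("halving the tolerances leaves the first spike times unchanged", {
  p <- r1()
  t1 <- spike_events(integrate_hybrid(p, t_end = 150, rtol = 1e-10,
                                      atol = 1e-10, dt_sample = 1))$t
  t2 <- spike_events(integrate_hybrid(p, t_end = 150, rtol = 5e-11,
                                      atol = 5e-11, dt_sample = 1))$t
  n <- min(length(t1), length(t2), 20)
  expect_gt(n, 10)
  expect_lt(max(abs(t1[seq_len(n)] - t2[seq_len(n)])), 1e-6)
})

test_that("hybrid and continuous integration agree without crossings", {
  p <- r1(I = 0)
  th <- integrate_hybrid(p, state0 = c(0.05, 0), t_end = 100, dt_sample = 0.1)
  tc <- integrate_continuous(p, state0 = c(0.05, 0), t_end = 100,
                             dt_sample = 0.1)
  expect_identical(nrow(spike_events(th)), 0L)
  expect_equal(th$v, tc$v, tolerance = 1e-14)
  expect_equal(th$u, tc$u, tolerance = 1e-14)
})

test_that("the hybrid orbit converges to the continuous cycle in the continuity limit", {
  # The continuity limit requires the spike threshold at the maximum of v
  # along the continuous cycle (resets just below it then only shave off a
  # vanishing sliver of the excursion); the cycle's period is ~123 time
  # units, so windows must span several hundred units.
  p0 <- r1()
  tc <- integrate_continuous(p0, state0 = c(0.1, 0.01), t_end = 650,
                             dt_sample = 0.05)
  maxv <- max(tc$v[tc$t > 350])
  pk <- maxv - 2e-4
  pl <- set_params(p0, v_peak = pk, v_r = pk - 1e-6, d = 1e-9)
  th <- integrate_hybrid(pl, state0 = c(0.1, 0.01), t_end = 650,
                         dt_sample = 0.05)
  expect_gt(nrow(spike_events(th)), 0)
  hh <- th[th$t > 350 & !th$is_spike, c("v", "u")]
  cc <- tc[tc$t > 350, c("v", "u")]
  # one-sided Hausdorff distance of the late-time orbits
  dmax <- max(vapply(seq_len(nrow(hh)), function(i) {
    min(sqrt((cc$v - hh$v[i])^2 + (cc$u - hh$u[i])^2))
  }, numeric(1)))
  expect_lt(dmax, 1e-3)
})

test_that("integration preconditions are enforced", {
  p <- r1()
  expect_error(integrate_hybrid(p, state0 = c(0.41, 0)), "v_peak")
  expect_error(integrate_hybrid(p, state0 = c(NA, 0)), "finite")
  expect_error(integrate_hybrid(p, t_end = -1), "t_end")
  # continuous mode may start above the threshold
  tr <- integrate_continuous(p, state0 = c(0.41, 0.02), t_end = 5)
  expect_s3_class(tr, "neuron_trajectory")
})
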