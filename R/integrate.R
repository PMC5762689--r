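#' Event-located integration of the hybrid system
#'
#' Integrates the continuous flow with an adaptive explicit Runge-Kutta
#' scheme (Dormand-Prince 5(4)); each upward crossing of `v = v_peak` is
#' located by bisection to |v - v_peak| below 1e-12, the resetting rule
#' (v -> v_r, u -> u + d) is applied, and integration resumes from the
#' post-reset state. `integrate_continuous()` runs the same scheme with the
#' reset disabled, so `v` may exceed `v_peak`.
#'
#' A quiescence detector terminates the run early (reason `"converged"`)
#' once the flow magnitude stays below `quiescence_tol` for a sustained
#' window, so sweeps over non-spiking parameter cells do not burn the full
#' horizon.
#'
#' @param p A [neuron_params()] object.
#' @param state0 Initial state `c(v, u)`. Defaults to `(v_r, 0)`.
#' @param t_end Integration horizon (from t = 0).
#' @param dt_sample Dense-output sampling interval; event states are always
#'   stored in addition.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param max_step Upper bound on the internal step so threshold crossings
#'   cannot straddle a step.
#' @param max_spikes Stop after this many spikes (hybrid mode).
#' @param quiescence_tol Flow-magnitude threshold for early termination;
#'   set to `0` to disable.
#' @return A `neuron_trajectory`: a tibble with columns `t`, `v`, `u`,
#'   `is_spike`, carrying attributes `spikes` (a tibble of spike events with
#'   pre- and post-reset states), `params`, and `reason` (one of
#'   `"horizon"`, `"converged"`, `"crossings_done"`, `"step_failure"`).
#' @examples
#' \donttest{
#' tr <- integrate_hybrid(neuron_preset("region1"), t_end = 200)
#' nrow(spike_events(tr))
#' }
#' @export
integrate_hybrid <- function(p, state0 = NULL, t_end = 1000,
                             dt_sample = 1e-2, rtol = 1e-12, atol = 1e-12,
                             max_step = 0.02, max_spikes = Inf,
                             quiescence_tol = 1e-12) {
  run_integration(p, state0, t_end, reset = TRUE, dt_sample, rtol, atol,
                  max_step, max_spikes, quiescence_tol)
}

#' @rdname integrate_hybrid
#' @export
integrate_continuous <- function(p, state0 = NULL, t_end = 1000,
                                 dt_sample = 1e-2, rtol = 1e-12, atol = 1e-12,
                                 max_step = 0.02,
                                 quiescence_tol = 1e-12) {
  run_integration(p, state0, t_end, reset = FALSE, dt_sample, rtol, atol,
                  max_step, Inf, quiescence_tol)
}

run_integration <- function(p, state0, t_end, reset, dt_sample, rtol, atol,
                            max_step, max_spikes, quiescence_tol) {
  stopifnot(inherits(p, "neuron_params"))
  if (is.null(state0)) state0 <- c(p$v_r, 0)
  if (length(state0) != 2 || !all(is.finite(state0))) {
    abort("`state0` must be a finite (v, u) pair")
  }
  if (reset && state0[1] >= p$v_peak) {
    abort(paste0("initial state has v >= v_peak; apply_reset() it first ",
                 "or start below the threshold"))
  }
  if (t_end <= 0) abort("`t_end` must be positive")
  res <- cpp_simulate(unclass(p), state0[1], state0[2], 0, t_end, reset,
                      rtol, atol, max_step, dt_sample,
                      if (is.finite(max_spikes)) as.integer(max_spikes) else -1L,
                      quiescence_tol)
  if (res$reason == "step_failure") {
    abort("integration failed (non-finite state or step breakdown)")
  }
  traj <- tibble(t = res$t, v = res$v, u = res$u,
                 is_spike = res$is_spike == 1L)
  spikes <- tibble(
    t = res$spike_t,
    v_minus = rep(p$v_peak, length(res$spike_t)),
    u_minus = res$spike_u_minus,
    v_plus = rep(p$v_r, length(res$spike_t)),
    u_plus = res$spike_u_minus + p$d
  )
  if (!reset && nrow(spikes) > 0) {
    spikes$v_plus <- spikes$v_minus
    spikes$u_plus <- spikes$u_minus
  }
  structure(traj,
            class = c("neuron_trajectory", class(traj)),
            spikes = spikes,
            params = p,
            reset = reset,
            final_state = c(v = res$final_v, u = res$final_u),
            final_t = res$final_t,
            reason = res$reason)
}

#' Spike events of a trajectory
#'
#' @param traj A `neuron_trajectory` from [integrate_hybrid()].
#' @return A tibble with one row per spike: event time `t`, the crossing
#'   state (`v_minus`, `u_minus`) and the post-reset state
#'   (`v_plus`, `u_plus`).
#' @export
spike_events <- function(traj) {
  stopifnot(inherits(traj, "neuron_trajectory"))
  attr(traj, "spikes")
}

#' @rdname spike_events
#' @export
terminated_reason <- function(traj) {
  stopifnot(inherits(traj, "neuron_trajectory"))
  attr(traj, "reason")
}

#' @export
print.neuron_trajectory <- function(x, ...) {
  sp <- attr(x, "spikes")
  cat(sprintf("<neuron_trajectory> %d samples, %d spikes, t in [%g, %g] (%s)\n",
              nrow(x), nrow(sp),
              if (nrow(x) > 0) min(x$t) else NA, attr(x, "final_t"),
              attr(x, "reason")))
  NextMethod()
}

#' Export a trajectory (and its spikes) to CSV
#'
#' Writes the sampled orbit as columns `t, v, u, is_spike`; if `spikes_path`
#' is given, the spike events go to a second CSV with columns
#' `index, t` (plus the pre-/post-reset states).
#'
#' @param traj A `neuron_trajectory`.
#' @param path Output CSV path for the sampled orbit.
#' @param spikes_path Optional output CSV path for the spike events.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, spikes_path = NULL) {
  stopifnot(inherits(traj, "neuron_trajectory"))
  readr::write_csv(as_tibble(traj), path)
  if (!is.null(spikes_path)) {
    sp <- spike_events(traj)
    sp <- dplyr::mutate(sp, index = dplyr::row_number(), .before = 1)
    readr::write_csv(sp, spikes_path)
  }
  invisible(path)
}
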