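#' Poincare return map on the spike-threshold section
#'
#' The section is the set of upward crossings of `v = v_peak`. Starting from
#' a section value `u0`, the hybrid system is integrated (the reset applied
#' first, so the run starts at `(v_r, u0 + d)`) and the recovery variable is
#' recorded at each subsequent upward crossing; the map
#' \eqn{u_{i+l} = \psi^l(u_i)} sends a crossing value to the value `l`
#' crossings later. With `reset = FALSE` the run instead starts on the
#' section at `(v_peak, u0)` and follows the continuous flow, whose return
#' map is nearly constant in `u0` (the limit cycle forgets its phase).
#'
#' @param p A [neuron_params()] object.
#' @param u0 Recovery value at the starting section crossing.
#' @param l Return count (map iterations).
#' @param reset Hybrid (`TRUE`) or continuous (`FALSE`) mode.
#' @param t_cap Horizon cap per evaluation; fewer than `l` crossings within
#'   it raises a "non-returning" error stating how many occurred.
#' @param rtol,atol,max_step Integrator controls.
#' @return A tibble of class `hs_return` with one row per crossing
#'   (`i`, `t`, `u`); the `l`-th value is also attached as attribute
#'   `u_out`.
#' @examples
#' \donttest{
#' rm <- return_map(neuron_preset("region1", v_r = 0.25), u0 = 0.05, l = 3)
#' attr(rm, "u_out")
#' }
#' @export
return_map <- function(p, u0, l = 1, reset = TRUE, t_cap = 1e4,
                       rtol = 1e-12, atol = 1e-12, max_step = 0.02) {
  stopifnot(inherits(p, "neuron_params"), l >= 1)
  res <- cpp_crossings(unclass(p), NA_real_, u0, as.integer(l), reset,
                       TRUE, FALSE, t_cap, rtol, atol, max_step)
  if (res$n_cross < l) {
    abort(sprintf(
      "non-returning: only %d of %d crossings occurred within t_cap = %g (%s)",
      res$n_cross, l, t_cap, res$reason), class = "hs_non_returning",
      n_cross = res$n_cross)
  }
  out <- tibble(i = seq_len(l), t = res$cross_t, u = res$cross_u)
  class(out) <- c("hs_return", class(out))
  attr(out, "u_out") <- res$cross_u[l]
  attr(out, "u_in") <- u0
  attr(out, "params") <- p
  out
}

# scalar psi^l, the workhorse for root finding
psi_l <- function(p, u0, l, reset = TRUE, t_cap = 1e4, rtol = 1e-12,
                  atol = 1e-12, max_step = 0.02) {
  res <- cpp_crossings(unclass(p), NA_real_, u0, as.integer(l), reset,
                       TRUE, FALSE, t_cap, rtol, atol, max_step)
  if (res$n_cross < l) return(NA_real_)
  res$cross_u[l]
}

#' Characteristic multiplier of the l-return map
#'
#' Computes \eqn{\mu^l = d\psi^l/du} at `u0` from the variational monodromy:
#' the state-transition matrix \eqn{\Phi} is integrated along the orbit from
#' the post-reset point (initialised to the identity), left-multiplied by
#' the saltation matrix at each of the `l - 1` interior crossings, and the
#' section projection is applied at the terminal crossing. With the
#' embedding derivative \eqn{(0,1)^T} (perturbations move along the section)
#' and the flow-aligned projection row \eqn{(-\dot u/\dot v,\ 1)} evaluated
#' at the terminal crossing state,
#' \deqn{\mu^l = (-\dot u/\dot v,\ 1)\ \Phi(t_l, t_0)\ (0, 1)^T.}
#' \eqn{|\mu| < 1} marks a stable periodic orbit; \eqn{\mu = -1} a
#' period-doubling and \eqn{\mu = +1} a tangent bifurcation.
#'
#' @inheritParams return_map
#' @return The multiplier (scalar), with attributes `phi` (the assembled
#'   monodromy), `orbit_time`, and `crossings`.
#' @export
characteristic_multiplier <- function(p, u0, l = 1, t_cap = 1e4,
                                      rtol = 1e-12, atol = 1e-12,
                                      max_step = 0.02) {
  stopifnot(inherits(p, "neuron_params"), l >= 1)
  res <- cpp_crossings(unclass(p), NA_real_, u0, as.integer(l), TRUE,
                       TRUE, TRUE, t_cap, rtol, atol, max_step)
  if (res$n_cross < l) {
    abort(sprintf(
      "non-returning: only %d of %d crossings occurred within t_cap = %g",
      res$n_cross, l, t_cap), class = "hs_non_returning")
  }
  f <- res$f_minus # flow at the terminal crossing state (v_peak, u_l)
  if (abs(f[1]) < 1e-12) abort("degenerate crossing: dv/dt ~ 0 at the section")
  phi <- matrix(res$phi, nrow = 2) # column-major: Phi(t_l, t_0)
  mu <- drop(c(-f[2] / f[1], 1) %*% phi %*% c(0, 1))
  attr(mu, "phi") <- phi
  attr(mu, "orbit_time") <- res$cross_t[l]
  attr(mu, "crossings") <- res$cross_u
  mu
}

#' Sample the attractor's section crossings
#'
#' Integrates the hybrid system and records the recovery variable at
#' successive upward crossings, discarding an initial transient. Used to
#' seed periodic-orbit searches and to build bifurcation diagrams.
#'
#' @param p A [neuron_params()] object.
#' @param n Number of crossings to keep.
#' @param transient Crossings discarded before sampling (attractor
#'   settling; chaotic regimes need a few hundred).
#' @param state0 Starting state; defaults to `(v_r, 0)`.
#' @param t_cap Horizon cap.
#' @param ... Integrator controls.
#' @return Numeric vector of section `u` values (possibly shorter than `n`
#'   if the orbit stops spiking), with the final state as an attribute.
#' @export
attractor_crossings <- function(p, n = 200, transient = 200, state0 = NULL,
                                t_cap = 1e5, ...) {
  stopifnot(inherits(p, "neuron_params"))
  if (is.null(state0)) state0 <- c(p$v_r, 0)
  dots <- list(...)
  res <- cpp_crossings(unclass(p), state0[1], state0[2],
                       as.integer(n + transient), TRUE, FALSE, FALSE, t_cap,
                       dots$rtol %||% 1e-12, dots$atol %||% 1e-12,
                       dots$max_step %||% 0.02)
  u <- res$cross_u
  u <- if (length(u) > transient) u[-seq_len(transient)] else numeric(0)
  attr(u, "final_state") <- c(v = res$final_v, u = res$final_u)
  u
}

#' Locate a periodic orbit as a fixed point of the l-return map
#'
#' Solves \eqn{\psi^l(u) - u = 0} by damped Newton iteration with the
#' variational derivative \eqn{\mu^l - 1}, falling back to bisection when a
#' sign-changing bracket is available and Newton stalls.
#'
#' @param p A [neuron_params()] object.
#' @param l Orbit period in section crossings.
#' @param u_guess Starting value on the section (see
#'   [attractor_crossings()]).
#' @param tol Convergence tolerance on the residual
#'   \eqn{|\psi^l(u) - u|}.
#' @param strict_period Reject convergence onto an orbit whose actual period
#'   is a proper divisor of `l` (a period-1 orbit is also a fixed point of
#'   \eqn{\psi^2}). Disable to continue a fixed point of \eqn{\psi^l}
#'   through a period-doubling collapse.
#' @param max_iter Newton iteration cap.
#' @param ... Integrator controls.
#' @return A `periodic_orbit` list: `u_star`, `l`, `mu`, `orbit_time`,
#'   `residual`, `stable`.
#' @export
find_periodic_orbit <- function(p, l, u_guess, tol = 1e-11, max_iter = 60,
                                strict_period = TRUE, ...) {
  stopifnot(inherits(p, "neuron_params"), l >= 1)
  g <- function(u) psi_l(p, u, l, ...) - u
  u <- u_guess
  gu <- g(u)
  if (is.na(gu)) abort("orbit search failed: starting point is non-returning")
  bracket <- NULL # c(lo, hi) with g(lo) * g(hi) < 0
  for (it in seq_len(max_iter)) {
    if (abs(gu) < tol) break
    mu <- tryCatch(characteristic_multiplier(p, u, l, ...),
                   error = function(e) NA_real_)
    deriv <- if (is.na(mu)) -1 else mu - 1
    if (abs(deriv) < 1e-8) deriv <- sign(deriv + 1e-16) * 1e-8
    step <- -gu / deriv
    # damping: never jump further than the section's natural scale
    step <- max(min(step, 0.05), -0.05)
    u_new <- u + step
    g_new <- g(u_new)
    tries <- 0
    while ((is.na(g_new) || abs(g_new) > abs(gu)) && tries < 8) {
      step <- step / 2
      u_new <- u + step
      g_new <- g(u_new)
      tries <- tries + 1
    }
    if (is.na(g_new)) abort(sprintf(
      "orbit search failed: non-returning near u = %.6g (residual %.3g)",
      u, gu))
    if (!is.null(bracket) || (sign(g_new) != sign(gu) && !is.na(g_new))) {
      if (is.null(bracket)) bracket <- sort(c(u, u_new))
    }
    u <- u_new
    gu <- g_new
  }
  if (abs(gu) >= tol && !is.null(bracket)) {
    r <- tryCatch(stats::uniroot(g, bracket, tol = 1e-13),
                  error = function(e) NULL)
    if (!is.null(r)) { u <- r$root; gu <- g(u) }
  }
  if (abs(gu) >= max(tol, 1e-9)) {
    abort(sprintf("periodic orbit did not converge: last residual %.3g", gu),
          class = "hs_no_convergence", residual = gu, u_last = u)
  }
  mu <- characteristic_multiplier(p, u, l, ...)
  # a fixed point of psi^l whose orbit revisits u* after fewer than l
  # crossings has a shorter actual period (e.g. a period-1 orbit is also a
  # fixed point of psi^2); converging onto one is an error, not a silent
  # substitute for the requested period
  inter <- attr(mu, "crossings")
  if (l > 1 && strict_period) {
    hits <- which(abs(inter[seq_len(l - 1)] - u) < 1e-7)
    if (length(hits) > 0) {
      abort(sprintf(
        "converged to an orbit of period %d, not the requested l = %d",
        hits[1], l), class = "hs_wrong_period", actual_period = hits[1])
    }
  }
  structure(list(u_star = u, l = l, mu = as.numeric(mu),
                 orbit_time = attr(mu, "orbit_time"),
                 residual = abs(gu), stable = abs(mu) < 1, params = p),
            class = "periodic_orbit")
}

#' @export
print.periodic_orbit <- function(x, ...) {
  cat(sprintf(
    "<periodic_orbit> l = %d, u* = %.8g, mu = %.6g (%s), T = %.5g\n",
    x$l, x$u_star, x$mu, if (x$stable) "stable" else "unstable",
    x$orbit_time))
  invisible(x)
}

# initial fixed-point guesses for period l at the current parameters: the
# last l attractor crossings (the l phases of the settled cycle), most
# recent first, plus the fold-modulo-l median as a fallback
seed_orbit <- function(p, l, n = 120, transient = 250, ...) {
  u <- attractor_crossings(p, n = n, transient = transient, ...)
  if (length(u) < l + 1) abort("attractor yields too few crossings to seed")
  c(rev(utils::tail(u, l)), stats::median(u[seq(1, length(u), by = l)]))
}

#' Locate a period-doubling or tangent bifurcation in the reset voltage
#'
#' Continues an l-periodic orbit of the Poincare map across `v_r`
#' (warm-starting the fixed point) and locates the parameter at which the
#' characteristic multiplier reaches `target_mu`: -1 for period-doubling,
#' +1 for a tangent (fold) bifurcation. For a tangent point the orbit
#' ceases to exist past the fold, so the bisection treats loss of the orbit
#' as the far side of the bracket; at the returned value the multiplier is
#' at the target within the orbit-location accuracy.
#'
#' @param p A [neuron_params()] object; `v_r` is swept.
#' @param l Orbit period in crossings.
#' @param v_r_interval Interval to scan. Continuation starts at the end
#'   where the orbit is stable: the first element.
#' @param target_mu `-1` or `+1`.
#' @param u_guess Optional fixed-point seed at `v_r_interval[1]`; defaulted
#'   from the simulated attractor.
#' @param n_scan Coarse continuation steps across the interval.
#' @param bracket_tol Bisection width on `v_r`.
#' @param ... Integrator controls.
#' @return A one-row tibble of class `hs_map_bif`: `v_r_star`, `l`, `kind`,
#'   `mu_at_star`, `bracket_width`.
#' @export
locate_map_bifurcation <- function(p, l, v_r_interval, target_mu,
                                   u_guess = NULL, n_scan = 40,
                                   bracket_tol = 1e-5, ...) {
  stopifnot(inherits(p, "neuron_params"), target_mu %in% c(-1, 1))
  kind <- if (target_mu == -1) "period-doubling" else "tangent"
  vr0 <- v_r_interval[1]
  vr1 <- v_r_interval[2]
  if (is.null(u_guess)) u_guess <- seed_orbit(set_params(p, v_r = vr0), l, ...)
  orb <- NULL
  for (ug in u_guess) {
    orb <- tryCatch(find_periodic_orbit(set_params(p, v_r = vr0), l, ug, ...),
                    error = function(e) NULL)
    if (!is.null(orb)) break
  }
  if (is.null(orb)) {
    abort(sprintf("could not locate an l = %d orbit at v_r = %g to start from",
                  l, vr0))
  }
  if (!orb$stable) {
    abort(sprintf("the l = %d orbit is not stable at v_r = %g: start the
continuation inside the orbit's stable window", l, vr0))
  }
  # The orbit is continued while it stays stable (|mu| < 1). At the target
  # the branch either crosses mu = -1 transversally (period-doubling) or
  # folds at mu = +1 and ceases to exist (tangent); in both cases losing
  # stability marks the far side of the bracket. Near a fold the Newton
  # iteration may land on a distinct unstable orbit embedded in the chaotic
  # attractor beyond the bifurcation -- such points also count as far side.
  on_branch <- function(vr, u_warm) {
    o <- tryCatch(find_periodic_orbit(set_params(p, v_r = vr), l, u_warm, ...),
                  error = function(e) NULL)
    if (is.null(o) || !o$stable) NULL else o
  }
  u_warm <- orb$u_star
  grid <- seq(vr0, vr1, length.out = n_scan + 1)[-1]
  lo <- vr0
  hi <- NA_real_
  for (vr in grid) {
    o <- on_branch(vr, u_warm)
    if (is.null(o)) { hi <- vr; break }
    lo <- vr
    u_warm <- o$u_star
  }
  if (is.na(hi)) {
    abort(sprintf(
      "no %s bifurcation of the l = %d orbit found in [%g, %g] (last good v_r = %g)",
      kind, l, vr0, vr1, lo), class = "hs_not_found", last_v_r = lo)
  }
  mu_near <- orb$mu
  while (abs(hi - lo) > bracket_tol) {
    mid <- 0.5 * (lo + hi)
    o <- on_branch(mid, u_warm)
    if (!is.null(o)) {
      lo <- mid; u_warm <- o$u_star; mu_near <- o$mu
    } else {
      hi <- mid
    }
  }
  out <- tibble(v_r_star = 0.5 * (lo + hi), l = l, kind = kind,
                mu_at_star = mu_near, bracket_width = abs(hi - lo))
  class(out) <- c("hs_map_bif", class(out))
  out
}

#' Bifurcation diagram over the reset voltage
#'
#' For each grid value of `v_r`, discards `transient_crossings` section
#' crossings and records the next `crossings_per_cell` values of `u` (and
#' the post-reset value `u + d`, whose position relative to the v-nullcline
#' distinguishes spiking from bursting). Each cell is warm-started from the
#' final state of the previous one.
#'
#' @param p A [neuron_params()] object; `v_r` is swept.
#' @param v_r_grid Reset voltages (all below `v_peak`).
#' @param crossings_per_cell,transient_crossings Samples kept / discarded.
#' @param t_cap Time cap per cell; non-spiking cells come back empty.
#' @param ... Integrator controls.
#' @return A tibble of class `hs_bifdiag`: `v_r`, `i`, `u`, `post_reset_u`.
#' @export
bifurcation_diagram <- function(p, v_r_grid, crossings_per_cell = 100,
                                transient_crossings = 200, t_cap = 5e4,
                                ...) {
  stopifnot(inherits(p, "neuron_params"))
  if (any(v_r_grid >= p$v_peak)) abort("`v_r_grid` must stay below v_peak")
  rows <- list()
  state <- NULL
  for (vr in v_r_grid) {
    pc <- set_params(p, v_r = vr)
    if (!is.null(state) && state[1] >= p$v_peak) state <- c(vr, state[2])
    u <- attractor_crossings(pc, n = crossings_per_cell,
                             transient = transient_crossings,
                             state0 = state, t_cap = t_cap, ...)
    state <- attr(u, "final_state")
    if (length(u) > 0) {
      rows[[length(rows) + 1]] <-
        tibble(v_r = vr, i = seq_along(u), u = as.numeric(u),
               post_reset_u = as.numeric(u) + p$d)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(v_r = numeric(), i = integer(), u = numeric(),
                  post_reset_u = numeric())
  }
  class(out) <- c("hs_bifdiag", class(out))
  attr(out, "params") <- p
  out
}

#' Smallest reset voltage whose attractor resets into the depolarising region
#'
#' Classifies every post-reset point `(v_r, u_i + d)` of the attractor by
#' the sign of \eqn{\dot v} there. Below the returned threshold all
#' post-reset points land on the \eqn{\dot v < 0} (hyperpolarising) side of
#' the v-nullcline — periodic spiking; above it at least one lands in
#' \eqn{\dot v > 0}, the slow/fast alternation that produces bursting.
#' Points exactly on the nullcline count as not-depolarising.
#'
#' @param p A [neuron_params()] object.
#' @param v_r_interval Interval of reset voltages to scan.
#' @param d Recovery increment used for the sweep.
#' @param n_sample,transient Crossings kept/discarded per evaluation.
#' @param tol Bisection width on `v_r`.
#' @param ... Integrator controls.
#' @return The threshold `v_r` (scalar); `NA` if the predicate never flips
#'   in the interval.
#' @export
jump_sign_threshold <- function(p, v_r_interval, d = p$d, n_sample = 200,
                                transient = 200, tol = 1e-3, ...) {
  stopifnot(inherits(p, "neuron_params"))
  any_depolarising <- function(vr) {
    pc <- set_params(p, v_r = vr, d = d)
    u <- attractor_crossings(pc, n = n_sample, transient = transient, ...)
    if (length(u) == 0) return(NA)
    fld <- vector_field(tibble(v = vr, u = as.numeric(u) + d), pc)
    any(fld$dv > 0)
  }
  n_scan <- 20
  grid <- seq(v_r_interval[1], v_r_interval[2], length.out = n_scan)
  flags <- vapply(grid, any_depolarising, logical(1))
  if (all(is.na(flags)) || !any(flags %in% TRUE)) return(NA_real_)
  first_true <- min(which(flags %in% TRUE))
  if (first_true == 1) return(grid[1])
  lo <- grid[first_true - 1]
  hi <- grid[first_true]
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    f <- any_depolarising(mid)
    if (isTRUE(f)) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}

#' Interspike-interval return map
#'
#' Consecutive pairs \eqn{(ISI_i, ISI_{i+1})} of the interspike intervals
#' \eqn{ISI_i = t_{i+1} - t_i}. In chaotic bursting the scatter shows a
#' unimodal peak; strictly periodic spiking collapses onto a point.
#'
#' @param traj A `neuron_trajectory` with at least 3 spikes.
#' @return A tibble of class `hs_isi` with columns `isi_i`, `isi_next`.
#' @export
isi_return_map <- function(traj) {
  stopifnot(inherits(traj, "neuron_trajectory"))
  st <- spike_events(traj)$t
  if (length(st) < 3) abort("need at least 3 spikes for an ISI return map")
  isi <- diff(st)
  out <- tibble(isi_i = isi[-length(isi)], isi_next = isi[-1])
  class(out) <- c("hs_isi", class(out))
  out
}

#' Tabulate the return map over a grid of section values
#'
#' Evaluates \eqn{\psi^l} on `u_grid` in either mode (with or without the
#' resetting process), for profile plots and exports. Non-returning points
#' are kept with `u_out = NA`.
#'
#' @param p A [neuron_params()] object.
#' @param u_grid Section values to map.
#' @param l Return count.
#' @param reset Hybrid or continuous mode.
#' @param t_cap Horizon cap per point.
#' @param ... Integrator controls.
#' @return A tibble of class `hs_profile`: `u_in`, `u_out`, `l`, `mode`.
#' @export
return_map_profile <- function(p, u_grid, l = 1, reset = TRUE, t_cap = 1e4,
                               ...) {
  stopifnot(inherits(p, "neuron_params"))
  u_out <- vapply(u_grid, function(u0) {
    tryCatch(psi_l(p, u0, l, reset = reset, t_cap = t_cap, ...),
             error = function(e) NA_real_)
  }, numeric(1))
  out <- tibble(u_in = u_grid, u_out = u_out, l = l,
                mode = if (reset) "reset" else "continuous")
  class(out) <- c("hs_profile", class(out))
  attr(out, "params") <- p
  out
}
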