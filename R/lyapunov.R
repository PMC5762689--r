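#' Saltation matrix at a spike event
#'
#' The correction matrix inserted into variational and monodromy products at
#' a reset, accounting for the state dependence of the event time:
#' \deqn{S = \begin{pmatrix} \dot v^+/\dot v^- & 0 \\
#'   (\dot u^+ - \dot u^-)/\dot v^- & 1 \end{pmatrix},}
#' where the minus/plus flows are evaluated at the crossing state
#' \eqn{(v_{peak}, u)} and the post-reset state \eqn{(v_r, u + d)}.
#' In the continuity limit (`v_r -> v_peak`, `d -> 0`) S tends to the
#' identity and the hybrid system tends to the continuous one.
#'
#' @param state_minus The crossing state, `c(v, u)` with `v` on the
#'   threshold (within `tol`).
#' @param p A [neuron_params()] object.
#' @param tol Allowed distance of `state_minus[1]` from `v_peak`.
#' @return A 2x2 matrix with attribute `context` (the pre/post states and
#'   flow values used).
#' @export
saltation_matrix <- function(state_minus, p, tol = 1e-6) {
  stopifnot(inherits(p, "neuron_params"))
  if (abs(state_minus[1] - p$v_peak) > tol) {
    abort("`state_minus` must lie on the section v = v_peak")
  }
  u <- state_minus[2]
  fm <- vector_field(tibble(v = p$v_peak, u = u), p)
  if (fm$dv <= 0) abort("degenerate crossing: need dv/dt > 0 at v = v_peak")
  if (abs(fm$dv) < 1e-12) abort("degenerate crossing: |dv/dt| < 1e-12")
  fp <- vector_field(tibble(v = p$v_r, u = u + p$d), p)
  S <- matrix(c(fp$dv / fm$dv, (fp$du - fm$du) / fm$dv, 0, 1), nrow = 2)
  attr(S, "context") <- list(
    state_minus = c(v = p$v_peak, u = u),
    state_plus = c(v = p$v_r, u = u + p$d),
    f_minus = c(fm$dv, fm$du), f_plus = c(fp$dv, fp$du))
  S
}

#' Lyapunov spectrum of the hybrid system
#'
#' Evolves a 2x2 perturbation matrix by the variational equation
#' \eqn{\dot\Lambda = J(v,u)\Lambda} jointly with the state, left-multiplies
#' the saltation matrix at every spike, and applies Gram-Schmidt
#' renormalisation every `renorm_interval` time units, accumulating the
#' column log-norms after the transient. The exponents are
#' \eqn{\lambda_j = (1/N\tau)\sum_k \log |l_j^k|}, sorted descending.
#'
#' A positive \eqn{\lambda_1} on a bounded orbit indicates chaos; on any
#' non-equilibrium attractor one exponent is the neutral (flow-direction)
#' exponent and is close to zero.
#'
#' @param p A [neuron_params()] object.
#' @param state0 Initial state; defaults to `(v_r, 0)`.
#' @param total_time Integration horizon (includes the transient).
#' @param transient Initial window excluded from the accumulators.
#' @param renorm_interval Gram-Schmidt renormalisation period \eqn{\tau}.
#' @param reset Integrate the hybrid system (`TRUE`) or the continuous flow
#'   without the resetting process (`FALSE`).
#' @param rtol,atol,max_step Integrator controls, as in
#'   [integrate_hybrid()].
#' @return A `lyapunov_result` list: `lambda` (sorted pair), `total_time`,
#'   `transient`, `renorm_interval`, `n_renorm`, `n_spikes`, a convergence
#'   `trace` tibble of running estimates, the final state, and
#'   `early_termination` flag.
#' @examples
#' \donttest{
#' lyapunov_spectrum(neuron_preset("region1"), total_time = 2000,
#'                   transient = 200, renorm_interval = 0.1)
#' }
#' @export
lyapunov_spectrum <- function(p, state0 = NULL, total_time = 1e4,
                              transient = 1e3, renorm_interval = 1e-3,
                              reset = TRUE, rtol = 1e-12, atol = 1e-12,
                              max_step = 0.02) {
  stopifnot(inherits(p, "neuron_params"))
  if (!(total_time > transient && transient > 0)) {
    abort("need total_time > transient > 0")
  }
  if (is.null(state0)) state0 <- c(p$v_r, 0)
  res <- cpp_lyapunov(unclass(p), state0[1], state0[2], total_time,
                      transient, renorm_interval, reset, rtol, atol, max_step)
  if (res$reason == "step_failure") abort("integration failed during Lyapunov run")
  early <- !(res$reason %in% c("horizon"))
  if (early) {
    warn(paste0("trajectory terminated early (", res$reason,
                "): exponents computed on the available window"))
  }
  lam <- sort(c(res$lambda1, res$lambda2), decreasing = TRUE)
  structure(list(
    lambda = lam,
    total_time = total_time,
    transient = transient,
    renorm_interval = renorm_interval,
    n_renorm = res$n_renorm,
    n_spikes = res$n_spikes,
    trace = tibble(t = res$trace_t, lambda1 = res$trace_l1,
                   lambda2 = res$trace_l2),
    final_state = c(v = res$final_v, u = res$final_u),
    early_termination = early,
    params = p
  ), class = "lyapunov_result")
}

#' @export
print.lyapunov_result <- function(x, ...) {
  cat(sprintf("<lyapunov_result> lambda1 = %.5g, lambda2 = %.5g\n",
              x$lambda[1], x$lambda[2]))
  cat(sprintf("  T = %g (transient %g), tau = %g, %d spikes%s\n",
              x$total_time, x$transient, x$renorm_interval,
              as.integer(x$n_spikes),
              if (x$early_termination) ", early termination" else ""))
  invisible(x)
}

#' Maximum-Lyapunov-exponent map over the reset parameters
#'
#' Computes \eqn{\lambda_1} on a `(v_r, d)` grid, sweeping `v_r` within each
#' `d` row and warm-starting every cell from the final state of its left
#' neighbour so the sweep stays on the attractor branch; the first cell of
#' each row starts from `(v_r, 0)`. Cells with \eqn{\lambda_1} above
#' `chaos_threshold` are flagged chaotic.
#'
#' @param p A [neuron_params()] object; its `v_r` and `d` are overridden by
#'   the grids.
#' @param v_r_grid,d_grid Grid values; every `v_r` must lie below `v_peak`.
#' @param total_time,transient,renorm_interval Per-cell Lyapunov settings
#'   (see [lyapunov_spectrum()]); the defaults trade run time for the
#'   resolution needed to classify cells by sign.
#' @param chaos_threshold \eqn{\lambda_1} above this value flags a cell as
#'   chaotic; the default 1e-3 separates the neutral exponent's numerical
#'   jitter from genuine positivity.
#' @param refine_band,refine_factor Cells whose first-pass \eqn{\lambda_1}
#'   falls within `refine_band` of the threshold are re-run with
#'   `refine_factor` times the horizon, since the finite-time estimate of a
#'   neutral exponent fluctuates at the few-1e-3 level over short runs.
#'   Set `refine_band = 0` to disable.
#' @param ... Passed to the integrator (`rtol`, `atol`, `max_step`).
#' @return A tibble of class `hs_heatmap` with columns `v_r`, `d`,
#'   `lambda1`, `chaotic`. Failed cells carry `NA`.
#' @export
lyapunov_heatmap <- function(p, v_r_grid, d_grid, total_time = 1500,
                             transient = 300, renorm_interval = 0.1,
                             chaos_threshold = 1e-3, refine_band = 5e-3,
                             refine_factor = 8, ...) {
  stopifnot(inherits(p, "neuron_params"))
  if (any(v_r_grid >= p$v_peak)) abort("all `v_r_grid` values must be < v_peak")
  if (any(d_grid < 0)) abort("`d_grid` values must be non-negative")
  dots <- list(...)
  rtol <- dots$rtol %||% 1e-10
  atol <- dots$atol %||% 1e-10
  max_step <- dots$max_step %||% 0.02
  rows <- list()
  for (d in d_grid) {
    state <- c(v_r_grid[1], 0)
    for (v_r in v_r_grid) {
      pc <- set_params(p, v_r = v_r, d = d)
      lam1 <- NA_real_
      res <- tryCatch(
        cpp_lyapunov(unclass(pc), state[1], state[2], total_time, transient,
                     renorm_interval, TRUE, rtol, atol, max_step),
        error = function(e) NULL)
      if (!is.null(res) && res$reason != "step_failure") {
        lam1 <- max(res$lambda1, res$lambda2)
        if (refine_band > 0 &&
            abs(lam1 - chaos_threshold) < refine_band) {
          res2 <- tryCatch(
            cpp_lyapunov(unclass(pc), state[1], state[2],
                         refine_factor * total_time, transient,
                         renorm_interval, TRUE, rtol, atol, max_step),
            error = function(e) NULL)
          if (!is.null(res2) && res2$reason != "step_failure") {
            lam1 <- max(res2$lambda1, res2$lambda2)
            res <- res2
          }
        }
        state <- c(res$final_v, res$final_u)
      } else {
        state <- c(v_r, 0)
      }
      rows[[length(rows) + 1]] <- tibble(v_r = v_r, d = d, lambda1 = lam1)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$chaotic <- !is.na(out$lambda1) & out$lambda1 > chaos_threshold
  class(out) <- c("hs_heatmap", class(out))
  attr(out, "params") <- p
  attr(out, "chaos_threshold") <- chaos_threshold
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
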