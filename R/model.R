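#' Evaluate the continuous vector field
#'
#' Computes \eqn{\dot v = v(a-v)(v-1) - u + I} and
#' \eqn{\dot u = \alpha(\sigma((v-\beta)/\varepsilon) - u)} at one or more
#' phase points.
#'
#' @param states A data frame with columns `v` and `u` (one row per state).
#' @param p A [neuron_params()] object.
#' @return The input as a tibble with columns `dv` and `du` appended.
#' @examples
#' p <- neuron_preset("region1", I = 0)
#' vector_field(data.frame(v = 0, u = 0), p)
#' @export
vector_field <- function(states, p) {
  stopifnot(inherits(p, "neuron_params"))
  states <- as_tibble(states)
  if (!all(c("v", "u") %in% names(states))) {
    abort("`states` must have columns `v` and `u`")
  }
  if (!all(is.finite(states$v)) || !all(is.finite(states$u))) {
    abort("states must be finite")
  }
  v <- states$v
  u <- states$u
  states$dv <- v * (p$a - v) * (v - 1) - u + p$I
  states$du <- p$alpha * (sigmoid((v - p$beta) / p$eps) - u)
  states
}

# logistic function, numerically safe for large |x|
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Jacobian of the continuous flow at a phase point
#'
#' The entries are derived analytically from the flow:
#' \deqn{J = \begin{pmatrix} -3v^2 + 2(a+1)v - a & -1 \\
#'   (\alpha/\varepsilon)\,\sigma(1-\sigma) & -\alpha \end{pmatrix}}
#' with \eqn{\sigma = \sigma((v-\beta)/\varepsilon)}.
#'
#' @param v,u Phase coordinates (scalars). `u` does not enter any entry but
#'   is accepted so the signature matches a general planar flow.
#' @param p A [neuron_params()] object.
#' @return A 2x2 numeric matrix.
#' @export
jacobian_matrix <- function(v, u = NULL, p) {
  stopifnot(inherits(p, "neuron_params"), length(v) == 1, is.finite(v))
  s <- sigmoid((v - p$beta) / p$eps)
  matrix(c(-3 * v^2 + 2 * (p$a + 1) * v - p$a, p$alpha / p$eps * s * (1 - s),
           -1, -p$alpha),
         nrow = 2)
}

#' Apply the after-spike resetting rule
#'
#' Maps a state on (or above) the spike-detection threshold to
#' \eqn{(v_r, u + d)}. The caller guarantees a spike event:
#' states with `v < v_peak` (beyond `tol`) are a precondition violation.
#'
#' @param states Data frame with columns `v` and `u`.
#' @param p A [neuron_params()] object.
#' @param tol Slack allowed below `v_peak` (event-location tolerance).
#' @return A tibble of post-reset states.
#' @export
apply_reset <- function(states, p, tol = 1e-8) {
  stopifnot(inherits(p, "neuron_params"))
  states <- as_tibble(states)
  if (any(states$v < p$v_peak - tol)) {
    abort("apply_reset() requires v >= v_peak: no spike event at this state")
  }
  tibble(v = rep(p$v_r, nrow(states)), u = states$u + p$d)
}

#' Nullclines of the continuous flow
#'
#' The v-nullcline is the cubic \eqn{u = v(a-v)(v-1) + I}; the u-nullcline is
#' the sigmoid \eqn{u = \sigma((v-\beta)/\varepsilon)}. Their intersections
#' are the equilibria (see [find_equilibria()]).
#'
#' @param p A [neuron_params()] object.
#' @param v_grid Voltages at which to evaluate both curves.
#' @return A tibble in long format: columns `v`, `nullcline`
#'   (`"v"` or `"u"`), `u`.
#' @export
nullclines <- function(p, v_grid = seq(-0.5, 1.2, length.out = 400)) {
  stopifnot(inherits(p, "neuron_params"), all(is.finite(v_grid)))
  out <- tibble(
    v = rep(v_grid, 2),
    nullcline = rep(c("v", "u"), each = length(v_grid)),
    u = c(v_grid * (p$a - v_grid) * (v_grid - 1) + p$I,
          sigmoid((v_grid - p$beta) / p$eps))
  )
  class(out) <- c("hs_nullclines", class(out))
  attr(out, "params") <- p
  out
}
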