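#' Equilibria of the continuous flow
#'
#' Eliminates `u` via the u-nullcline and finds all roots of the reduced
#' scalar equation
#' \deqn{f(v) = v(a-v)(v-1) + I - \sigma((v-\beta)/\varepsilon) = 0}
#' in a window, by sign-change bracketing on a fine grid followed by
#' [stats::uniroot()] polishing. This guarantees every nullcline
#' intersection in the window is found, unlike a 2-D Newton search.
#'
#' @param p A [neuron_params()] object.
#' @param v_window Search interval for `v`.
#' @param n_grid Number of bracketing grid points.
#' @return An `equilibrium_report`: a tibble with one row per equilibrium
#'   and columns `v`, `u`, complex eigenvalues `m1`, `m2` (ordered by
#'   decreasing real part), `stable`, and `residual` (norm of the vector
#'   field at the root).
#' @examples
#' find_equilibria(neuron_preset("region1", I = 0))
#' @export
find_equilibria <- function(p, v_window = c(-0.5, 1.2), n_grid = 1e4) {
  stopifnot(inherits(p, "neuron_params"), all(is.finite(v_window)))
  f <- function(v) v * (p$a - v) * (v - 1) + p$I - sigmoid((v - p$beta) / p$eps)
  vg <- seq(v_window[1], v_window[2], length.out = n_grid)
  fg <- f(vg)
  roots <- vg[fg == 0]
  idx <- which(fg[-1] * fg[-length(fg)] < 0)
  for (i in idx) {
    r <- stats::uniroot(f, c(vg[i], vg[i + 1]), tol = 1e-14)
    roots <- c(roots, r$root)
  }
  roots <- sort(roots)
  # deduplicate near-identical roots
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-8)
    roots <- roots[keep]
  }
  rows <- lapply(roots, function(v) {
    u <- sigmoid((v - p$beta) / p$eps)
    ev <- eigen(jacobian_matrix(v, u, p), only.values = TRUE)$values
    ev <- as.complex(ev)
    ev <- ev[order(-Re(ev), -Im(ev))]
    fld <- vector_field(tibble(v = v, u = u), p)
    tibble(v = v, u = u, m1 = ev[1], m2 = ev[2],
           stable = all(Re(ev) < 0),
           residual = sqrt(fld$dv^2 + fld$du^2))
  })
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(v = numeric(), u = numeric(), m1 = complex(), m2 = complex(),
           stable = logical(), residual = numeric())
  class(out) <- c("equilibrium_report", class(out))
  attr(out, "params") <- p
  out
}

#' Tabulate equilibrium eigenvalues over a current sweep
#'
#' Tracks the equilibrium branch continuing the stable fixed point at the
#' first grid value and records its Jacobian eigenvalues at every `I`,
#' for eigenvalue-versus-current plots.
#'
#' @param p A [neuron_params()] object (its `I` is ignored).
#' @param I_grid Currents to sweep, in increasing order.
#' @return A tibble with columns `I`, `m1`, `m2` (complex), `max_re`,
#'   `stable`. Currents where the tracked branch has disappeared are
#'   omitted.
#' @export
eigen_sweep <- function(p, I_grid) {
  stopifnot(inherits(p, "neuron_params"))
  v_prev <- NULL
  rows <- list()
  for (I in I_grid) {
    eq <- find_equilibria(set_params(p, I = I))
    if (nrow(eq) == 0) break
    if (is.null(v_prev)) {
      st <- which(eq$stable)
      if (length(st) == 0) st <- which.min(abs(eq$v))
      pick <- st[1]
    } else {
      pick <- which.min(abs(eq$v - v_prev))
      if (abs(eq$v[pick] - v_prev) > 0.05) break
    }
    v_prev <- eq$v[pick]
    rows[[length(rows) + 1]] <-
      tibble(I = I, m1 = eq$m1[pick], m2 = eq$m2[pick],
             max_re = max(Re(c(eq$m1[pick], eq$m2[pick]))),
             stable = eq$stable[pick])
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hs_eigen_sweep", class(out))
  attr(out, "params") <- p
  out
}

# track the branch through I; returns function(I) -> list(v, J, exists)
track_branch <- function(p, I, v_prev) {
  eq <- find_equilibria(set_params(p, I = I))
  if (nrow(eq) == 0) return(NULL)
  pick <- which.min(abs(eq$v - v_prev))
  if (abs(eq$v[pick] - v_prev) > 0.05) return(NULL)
  eq[pick, ]
}

#' Locate the bifurcation of the resting equilibrium in the current I
#'
#' Continues the stable equilibrium from the lower end of `I_range` upward
#' and locates the first bifurcation: a saddle-node (fold), detected as the
#' disappearance of the tracked branch when the stable/unstable pair
#' annihilates, or a Hopf point, detected as a complex-conjugate eigenvalue
#' pair crossing the imaginary axis. The critical current is bisected to an
#' interval of width `tol`.
#'
#' @param p A [neuron_params()] object (its `I` is ignored).
#' @param I_range Interval of currents to scan (increasing).
#' @param n_scan Coarse-scan resolution before bisection.
#' @param tol Bisection bracket width on `I`.
#' @return A one-row tibble of class `hs_bif_in_I` with columns `I_star`,
#'   `kind` (`"saddle-node"` or `"Hopf"`), and `bracket_width`; `kind` is
#'   `"none"` (with `I_star = NA`) when no bifurcation lies in the range.
#' @examples
#' \donttest{
#' locate_bifurcation_in_I(neuron_preset("region1"), c(-0.005, 0.005))
#' }
#' @export
locate_bifurcation_in_I <- function(p, I_range, n_scan = 200, tol = 1e-6) {
  stopifnot(inherits(p, "neuron_params"), I_range[1] < I_range[2])
  Ig <- seq(I_range[1], I_range[2], length.out = n_scan)
  eq0 <- find_equilibria(set_params(p, I = Ig[1]))
  st <- which(eq0$stable)
  if (length(st) == 0) {
    abort("no stable equilibrium at the lower end of `I_range`")
  }
  v_prev <- eq0$v[st[1]]
  prev_max_re <- max(Re(c(eq0$m1[st[1]], eq0$m2[st[1]])))
  none <- tibble(I_star = NA_real_, kind = "none", bracket_width = NA_real_)
  class(none) <- c("hs_bif_in_I", class(none))

  lo <- Ig[1]
  v_lo <- v_prev
  hit <- NULL
  for (i in seq(2, length(Ig))) {
    br <- track_branch(p, Ig[i], v_prev)
    if (is.null(br)) { hit <- list(kind = "saddle-node", hi = Ig[i]); break }
    max_re <- max(Re(c(br$m1, br$m2)))
    if (prev_max_re < 0 && max_re >= 0 && Im(br$m1) != 0) {
      hit <- list(kind = "Hopf", hi = Ig[i]); break
    }
    lo <- Ig[i]; v_lo <- br$v
    v_prev <- br$v; prev_max_re <- max_re
  }
  if (is.null(hit)) return(none)

  hi <- hit$hi
  v_prev <- v_lo
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    br <- track_branch(p, mid, v_prev)
    on_near_side <- if (hit$kind == "saddle-node") {
      !is.null(br)
    } else {
      !is.null(br) && max(Re(c(br$m1, br$m2))) < 0
    }
    if (on_near_side) { lo <- mid; v_prev <- br$v } else hi <- mid
  }
  out <- tibble(I_star = 0.5 * (lo + hi), kind = hit$kind,
                bracket_width = hi - lo)
  class(out) <- c("hs_bif_in_I", class(out))
  out
}

#' Current at which the tracked equilibrium's eigenvalues turn real
#'
#' Bisects the sign change of the Jacobian discriminant
#' \eqn{\mathrm{tr}(J)^2 - 4\det(J)} along the continued stable branch:
#' below the returned current the eigenvalues form a complex-conjugate
#' pair, above it they are two real numbers.
#'
#' @inheritParams locate_bifurcation_in_I
#' @return The critical current (scalar), or `NA` if no transition occurs
#'   in the range.
#' @export
locate_eigenvalue_split <- function(p, I_range, n_scan = 200, tol = 1e-7) {
  stopifnot(inherits(p, "neuron_params"), I_range[1] < I_range[2])
  disc <- function(br) {
    J <- jacobian_matrix(br$v, br$u, p)
    (J[1, 1] + J[2, 2])^2 - 4 * det(J)
  }
  Ig <- seq(I_range[1], I_range[2], length.out = n_scan)
  eq0 <- find_equilibria(set_params(p, I = Ig[1]))
  st <- which(eq0$stable)
  if (length(st) == 0) abort("no stable equilibrium at the lower end of `I_range`")
  v_prev <- eq0$v[st[1]]
  d_prev <- disc(eq0[st[1], ])
  # scan the branch, remembering every complex -> real (disc - to +) change;
  # the last one before the branch ends is the lower end of the real interval
  lo <- NA; hi <- NA; v_lo <- NA
  I_prev <- Ig[1]
  for (i in seq(2, length(Ig))) {
    br <- track_branch(p, Ig[i], v_prev)
    if (is.null(br)) break
    d_now <- disc(br)
    if (d_prev < 0 && d_now >= 0) { lo <- I_prev; hi <- Ig[i]; v_lo <- v_prev }
    I_prev <- Ig[i]; v_prev <- br$v; d_prev <- d_now
  }
  if (is.na(hi)) return(NA_real_)
  v_prev <- v_lo
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    br <- track_branch(p, mid, v_prev)
    if (is.null(br)) { hi <- mid; next }
    if (disc(br) < 0) { lo <- mid; v_prev <- br$v } else hi <- mid
  }
  0.5 * (lo + hi)
}
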