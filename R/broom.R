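#' Tidiers for analysis results
#'
#' `tidy()` returns the per-element table of a result; `glance()` returns a
#' one-row summary, following the broom conventions.
#'
#' @param x An `equilibrium_report`, `lyapunov_result`, or
#'   `periodic_orbit`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.equilibrium_report <- function(x, ...) {
  tibble(v = x$v, u = x$u,
         re_m1 = Re(x$m1), im_m1 = Im(x$m1),
         re_m2 = Re(x$m2), im_m2 = Im(x$m2),
         stable = x$stable, residual = x$residual)
}

#' @rdname tidiers
#' @export
glance.equilibrium_report <- function(x, ...) {
  tibble(n_equilibria = nrow(x), n_stable = sum(x$stable),
         max_residual = if (nrow(x) > 0) max(x$residual) else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.lyapunov_result <- function(x, ...) x$trace

#' @rdname tidiers
#' @export
glance.lyapunov_result <- function(x, ...) {
  tibble(lambda1 = x$lambda[1], lambda2 = x$lambda[2],
         total_time = x$total_time, transient = x$transient,
         renorm_interval = x$renorm_interval,
         n_spikes = as.integer(x$n_spikes),
         early_termination = x$early_termination)
}

#' @rdname tidiers
#' @export
glance.periodic_orbit <- function(x, ...) {
  tibble(u_star = x$u_star, l = as.integer(x$l), mu = x$mu,
         orbit_time = x$orbit_time, residual = x$residual,
         stable = x$stable)
}
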