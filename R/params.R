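#' Model parameters for the hybrid spiking neuron
#'
#' Bundles the scalar parameters of the planar flow
#' \deqn{\dot v = v(a - v)(v - 1) - u + I, \qquad
#'       \dot u = \alpha\,(\sigma((v - \beta)/\varepsilon) - u),}
#' where \eqn{\sigma} is the logistic function, together with the
#' after-spike resetting rule: when \eqn{v} reaches `v_peak`, the state jumps
#' to \eqn{(v_r,\, u + d)}.
#'
#' All quantities are dimensionless. `a` shapes the cubic v-nullcline,
#' `alpha` is the recovery rate (1/time), `beta` and `eps` are the midpoint
#' and slope width of the sigmoidal u-nullcline, `I` is the applied current,
#' `v_peak` the spike-detection threshold, `v_r` the after-spike reset
#' voltage and `d` the after-spike recovery increment.
#'
#' @param a Cubic-shape parameter.
#' @param alpha Recovery time-constant rate; must be positive.
#' @param beta Sigmoid midpoint (voltage units).
#' @param eps Sigmoid slope width; must be positive.
#' @param I Applied current.
#' @param v_peak Spike-detection threshold.
#' @param v_r After-spike reset voltage; must satisfy `v_r < v_peak`.
#' @param d After-spike recovery increment; must be non-negative.
#'
#' @return A `neuron_params` object (a validated named list).
#' @examples
#' p <- neuron_params() # region #1 defaults
#' p2 <- neuron_preset("region2")
#' @export
neuron_params <- function(a = 0.1, alpha = 0.1, beta = 0.5, eps = 0.05,
                          I = 0.004, v_peak = 0.4, v_r = 0.33, d = 0.01) {
  p <- list(a = a, alpha = alpha, beta = beta, eps = eps, I = I,
            v_peak = v_peak, v_r = v_r, d = d)
  validate_params(p)
}

validate_params <- function(p) {
  req <- c("a", "alpha", "beta", "eps", "I", "v_peak", "v_r", "d")
  missing <- setdiff(req, names(p))
  if (length(missing) > 0) {
    abort(paste0("missing model parameters: ", paste(missing, collapse = ", ")))
  }
  p <- p[req]
  vals <- unlist(p)
  if (!all(is.finite(vals))) abort("all model parameters must be finite numbers")
  if (p$eps <= 0) abort("`eps` must be positive")
  if (p$alpha <= 0) abort("`alpha` must be positive")
  if (p$v_r >= p$v_peak) abort("`v_r` must be strictly below `v_peak`")
  if (p$d < 0) abort("`d` must be non-negative")
  structure(p, class = "neuron_params")
}

#' Named parameter presets
#'
#' Two parameter regions are built in. Both share
#' `a = 0.1, alpha = 0.1, eps = 0.05`. Region #1
#' (`beta = 0.5, I = 0.004, v_peak = 0.4`) spikes via a saddle-node
#' bifurcation of the resting equilibrium; region #2
#' (`beta = 0.3, I = 0.04, v_peak = 0.225`) via a Hopf bifurcation.
#' The default reset settings place each region in its chaotic window
#' (`v_r = 0.33` resp. `0.14`, `d = 0.01`); override them with `...`.
#'
#' @param name `"region1"` or `"region2"`.
#' @param ... Overrides for individual parameters, e.g. `v_r = 0.25`.
#' @return A [neuron_params()] object.
#' @examples
#' neuron_preset("region1", I = 0)
#' @export
neuron_preset <- function(name = c("region1", "region2"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    region1 = list(a = 0.1, alpha = 0.1, beta = 0.5, eps = 0.05,
                   I = 0.004, v_peak = 0.4, v_r = 0.33, d = 0.01),
    region2 = list(a = 0.1, alpha = 0.1, beta = 0.3, eps = 0.05,
                   I = 0.04, v_peak = 0.225, v_r = 0.14, d = 0.01))
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad) > 0) {
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  }
  base[names(over)] <- over
  validate_params(base)
}

#' Modify a parameter set
#'
#' @param p A [neuron_params()] object.
#' @param ... Parameters to change, e.g. `v_r = 0.3, d = 0`.
#' @return A new validated `neuron_params` object.
#' @export
set_params <- function(p, ...) {
  stopifnot(inherits(p, "neuron_params"))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) {
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  }
  q <- unclass(p)
  q[names(over)] <- over
  validate_params(q)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  flow:  a=%g alpha=%g beta=%g eps=%g I=%g\n",
              x$a, x$alpha, x$beta, x$eps, x$I))
  cat(sprintf("  reset: v_peak=%g v_r=%g d=%g\n", x$v_peak, x$v_r, x$d))
  invisible(x)
}

#' @export
as.list.neuron_params <- function(x, ...) unclass(x)

#' Read / write parameter sets as YAML
#'
#' The file holds the flat keys `a, alpha, beta, eps, I, v_peak, v_r, d`,
#' or a single key `preset: region1|region2` optionally combined with
#' overrides.
#'
#' @param path File path.
#' @param p A [neuron_params()] object.
#' @return `read_params()` returns a `neuron_params`; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$preset)) {
    nm <- raw$preset
    raw$preset <- NULL
    return(do.call(neuron_preset, c(list(name = nm), raw)))
  }
  do.call(neuron_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "neuron_params"))
  yaml::write_yaml(lapply(unclass(p), as.numeric), path)
  invisible(path)
}
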