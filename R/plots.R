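#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_path geom_tile
#'   geom_abline geom_hline labs scale_fill_viridis_c theme_minimal
NULL

#' Plot a trajectory
#'
#' `type = "time"` draws the membrane-potential time series with spike
#' events marked; `type = "phase"` draws the orbit in the (v, u) phase
#' plane over the model's nullclines.
#'
#' @param object A `neuron_trajectory`.
#' @param type `"time"` or `"phase"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neuron_trajectory <- function(object, type = c("time", "phase"),
                                       ...) {
  type <- match.arg(type)
  p <- attr(object, "params")
  sp <- spike_events(object)
  if (type == "time") {
    ggplot(as_tibble(object), aes(x = .data$t, y = .data$v)) +
      geom_line(linewidth = 0.3) +
      geom_point(data = sp, aes(x = .data$t, y = .data$v_minus),
                 colour = "red", size = 0.8) +
      labs(x = "t", y = "v") +
      theme_minimal()
  } else {
    nc <- nullclines(p)
    ggplot(as_tibble(object), aes(x = .data$v, y = .data$u)) +
      geom_line(data = as_tibble(nc),
                aes(group = .data$nullcline, linetype = .data$nullcline)) +
      geom_path(linewidth = 0.3, colour = "steelblue") +
      ggplot2::coord_cartesian(ylim = range(object$u) + c(-0.02, 0.02)) +
      labs(x = "v", y = "u", linetype = "nullcline") +
      theme_minimal()
  }
}

#' @export
autoplot.hs_nullclines <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$v, y = .data$u, linetype = .data$nullcline)) +
    geom_line() +
    labs(x = "v", y = "u") +
    theme_minimal()
}

#' @export
autoplot.hs_eigen_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::transmute(as_tibble(object), I = .data$I,
                     `Re m1` = Re(.data$m1), `Re m2` = Re(.data$m2)),
    -"I", names_to = "eigenvalue", values_to = "re")
  ggplot(df, aes(x = .data$I, y = .data$re, colour = .data$eigenvalue)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "I", y = "Re(m)") +
    theme_minimal()
}

#' @export
autoplot.hs_heatmap <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$v_r, y = .data$d, fill = .data$lambda1)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "v_r", y = "d", fill = expression(lambda[1])) +
    theme_minimal()
}

#' @export
autoplot.hs_bifdiag <- function(object, post_reset = FALSE, ...) {
  y <- if (post_reset) "post_reset_u" else "u"
  ggplot(as_tibble(object), aes(x = .data$v_r, y = .data[[y]])) +
    geom_point(size = 0.1, alpha = 0.4) +
    labs(x = "v_r", y = if (post_reset) "u + d" else "u") +
    theme_minimal()
}

#' @export
autoplot.hs_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$u_in, y = .data$u_out)) +
    geom_abline(slope = 1, intercept = 0, linetype = 3) +
    geom_point(size = 0.5) +
    labs(x = expression(u[i]), y = expression(u[i + l])) +
    theme_minimal()
}

#' @export
autoplot.hs_isi <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$isi_i, y = .data$isi_next)) +
    geom_point(size = 0.5, alpha = 0.5) +
    labs(x = expression(ISI[i]), y = expression(ISI[i + 1])) +
    theme_minimal()
}

#' Convergence trace of a Lyapunov run
#'
#' @param object A `lyapunov_result`.
#' @param ... Unused.
#' @return A ggplot of the running exponent estimates against time.
#' @export
autoplot.lyapunov_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"t", names_to = "exponent",
                            values_to = "lambda")
  ggplot(df, aes(x = .data$t, y = .data$lambda, colour = .data$exponent)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "t", y = expression(lambda)) +
    theme_minimal()
}
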