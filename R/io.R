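#' Export results as JSON
#'
#' Writes an analysis result together with the resolved model parameters,
#' so every output file carries the configuration that produced it.
#'
#' @param x An `equilibrium_report`, `lyapunov_result`, `hs_bif_in_I` or
#'   `hs_map_bif` object (tibbles are written as-is).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  payload <- if (inherits(x, "equilibrium_report")) {
    list(result = tidy(x), params = par_list(attr(x, "params")))
  } else if (inherits(x, "lyapunov_result")) {
    list(result = glance(x), params = par_list(x$params))
  } else if (inherits(x, "periodic_orbit")) {
    list(result = glance(x), params = par_list(x$params))
  } else if (is.data.frame(x)) {
    list(result = as_tibble(x), params = par_list(attr(x, "params")))
  } else {
    abort("no JSON writer for this object")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

par_list <- function(p) if (is.null(p)) NULL else lapply(unclass(p), as.numeric)
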