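# internal helpers shared across modules

# Evaluate code under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL leaves the current stream untouched.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# Reflect positions into [lo, hi] (folding, preserves path length).
reflect <- function(p, lo, hi) {
  w <- hi - lo
  p <- (p - lo) %% (2 * w)
  lo + ifelse(p > w, 2 * w - p, p)
}

stopifnotPositive <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (k in seq_along(vals)) {
    v <- vals[[k]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nms[k]),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read simulation parameters from a YAML file
#'
#' Convenience loader so simulation runs can be driven by a parameter file:
#' the returned named list can be spliced into any generator with
#' `do.call()`, e.g. `do.call(simulateMovie, simParamsFromYAML("movie.yml"))`.
#'
#' @param path path to a YAML file whose top-level keys are argument names of
#'   one of the `simulate*()` generators.
#' @return Named list of parameters.
#' @export
simParamsFromYAML <- function(path) {
  p <- yaml::read_yaml(path)
  if (!is.list(p) || is.null(names(p)) || any(names(p) == ""))
    stop("YAML parameter file must be a mapping of argument names to values")
  p
}
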