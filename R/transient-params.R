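#' Parameters of the constrained rise-decay transient model
#'
#' Container for the four free parameters of the calcium-transient model
#' \deqn{f(t) = -(b + c)\,e^{-(\tau_{decay} + \tau_\Delta) t} + b\,e^{-\tau_{decay} t} + c.}
#' The rise magnitude `a = b + c` and rise rate
#' `tau_rise = tau_decay + tau_delta` are derived, never stored, so the
#' model constraints `a >= b` (zero fluorescence at transient onset) and
#' `tau_rise >= tau_decay` (rise faster than decay) hold by construction.
#'
#' @param tau_decay Decay rate constant (1/s), `>= 0`.
#' @param tau_delta Gap between rise and decay rates (1/s), `>= 0`.
#' @param b Decay amplitude (fluorescence a.u.), `>= 0`.
#' @param c Steady-state fluorescence level (a.u.), `>= 0`.
#'
#' @return An object of class `"transient_params"`: a named list with the
#'   four stored parameters.
#' @seealso [param_a()], [param_tau_rise()], [model_eval()]
#' @examples
#' p <- transient_params(tau_decay = 1 / 200, tau_delta = 0.02, b = 5, c = 2)
#' param_a(p)        # 7
#' param_tau_rise(p) # 0.025
#' @export
transient_params <- function(tau_decay, tau_delta, b, c) {
  for (nm in c("tau_decay", "tau_delta", "b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    if (v < 0)
      stop(sprintf("invariant violated: '%s' must be >= 0 (got %g)", nm, v),
           call. = FALSE)
  }
  structure(
    list(tau_decay = as.numeric(tau_decay), tau_delta = as.numeric(tau_delta),
         b = as.numeric(b), c = as.numeric(c)),
    class = "transient_params"
  )
}

#' @rdname transient_params
#' @param params A `"transient_params"` object.
#' @export
param_a <- function(params) {
  stopifnot(inherits(params, "transient_params"))
  params$b + params$c
}

#' @rdname transient_params
#' @export
param_tau_rise <- function(params) {
  stopifnot(inherits(params, "transient_params"))
  params$tau_decay + params$tau_delta
}

#' @export
print.transient_params <- function(x, ...) {
  cat("Rise-decay transient parameters:\n")
  cat(sprintf("  tau_decay = %g 1/s  (1/tau_decay = %g s)\n",
              x$tau_decay, if (x$tau_decay > 0) 1 / x$tau_decay else Inf))
  cat(sprintf("  tau_delta = %g 1/s  (tau_rise = %g 1/s)\n",
              x$tau_delta, x$tau_decay + x$tau_delta))
  cat(sprintf("  b = %g a.u., c = %g a.u.  (a = b + c = %g a.u.)\n",
              x$b, x$c, x$b + x$c))
  invisible(x)
}
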