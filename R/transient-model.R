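#' Evaluate the rise-decay transient model
#'
#' Computes \deqn{f(t) = -(b + c)\,e^{-(\tau_{decay} + \tau_\Delta) t} +
#' b\,e^{-\tau_{decay} t} + c} at the supplied times. The parameterisation
#' forces `f(0) = 0` exactly (the transient starts at baseline) and a rise
#' that is at least as fast as the decay.
#'
#' @param t Times in seconds from transient onset; all `>= 0`.
#' @param params A [transient_params()] object.
#' @return Numeric vector of model fluorescence values (a.u.), one per time.
#' @examples
#' p <- transient_params(1 / 200, 0.02, 5, 2)
#' model_eval(0, p)              # exactly 0
#' model_eval(c(30, 300, 3000), p)
#' @export
model_eval <- function(t, params) {
  stopifnot(inherits(params, "transient_params"))
  if (!is.numeric(t) || anyNA(t))
    stop("'t' must be numeric with no missing values", call. = FALSE)
  if (any(t < 0))
    stop("'t' must be non-negative (time is measured from transient onset)",
         call. = FALSE)
  tau_rise <- params$tau_decay + params$tau_delta
  # grouped as b(e^-td t - e^-tr t) + c(1 - e^-tr t): algebraically equal to
  # -(b+c)e^-tr t + b e^-td t + c but exactly 0 at t = 0 in floating point
  e_rise <- exp(-tau_rise * t)
  params$b * (exp(-params$tau_decay * t) - e_rise) +
    params$c * (1 - e_rise)
}

#' Time of the transient peak
#'
#' Setting the derivative of the model to zero gives the interior maximum
#' \deqn{t^* = \frac{1}{\tau_\Delta}\,\log\frac{a\,\tau_{rise}}{b\,\tau_{decay}}}
#' with `a = b + c` and `tau_rise = tau_decay + tau_delta`. An interior
#' peak only exists when the rise and decay rates differ (`tau_delta > 0`),
#' there is a decaying component (`b > 0`) and the decay actually proceeds
#' (`tau_decay > 0`); otherwise the model is monotone and the call fails
#' with an error of class `"calshape_no_peak"`.
#'
#' @inheritParams model_eval
#' @return Peak time in seconds (a single number).
#' @examples
#' p <- transient_params(1 / 200, 0.02, 5, 2)
#' ts <- peak_time(p)
#' model_eval(ts, p) >= model_eval(ts + 10, p)
#' @export
peak_time <- function(params) {
  stopifnot(inherits(params, "transient_params"))
  if (params$tau_delta <= 0 || params$b <= 0 || params$tau_decay <= 0) {
    cond <- structure(
      class = c("calshape_no_peak", "error", "condition"),
      list(message = paste("no interior peak: requires tau_delta > 0,",
                           "b > 0 and tau_decay > 0"),
           call = sys.call())
    )
    stop(cond)
  }
  a <- params$b + params$c
  tau_rise <- params$tau_decay + params$tau_delta
  log(a * tau_rise / (params$b * params$tau_decay)) / params$tau_delta
}

#' Eligibility criteria for model fitting
#'
#' A cell is only fitted when its trace passes three checks: (1) the median
#' of the baseline-subtracted transient segment is non-negative, so the
#' steady-state initialisation lies inside the parameter bounds; (2) the
#' post-onset observations are stochastically greater than the baseline
#' frames by a one-sided Wilcoxon rank-sum test at `alpha` (a
#' non-responsive cell fails this); (3) the transient's maximum falls in
#' the first half of the transient segment, so the decay is observed long
#' enough for its rate to be identifiable.
#'
#' The rank-sum test uses the normal approximation with tie correction
#' (`stats::wilcox.test(exact = FALSE)`), appropriate for the 8-frame
#' baseline versus ~52-frame transient comparison.
#'
#' @param y Raw fluorescence trace for one cell (numeric vector, frames in
#'   acquisition order after the first-frame drop).
#' @param baseline_frames Indices (1-based) of the pre-agonist baseline
#'   frames; default `1:8`, with the transient starting at the next frame.
#' @param alpha Significance level of the responsiveness test.
#' @return An object of class `"fit_criteria"`: a list with logical flags
#'   `median_nonnegative`, `responsive`, `peak_in_first_half` and their
#'   conjunction `eligible`, plus the rank-sum `p_value`.
#' @export
check_fit_criteria <- function(y, baseline_frames = 1:8, alpha = 0.005) {
  if (!is.numeric(y) || anyNA(y))
    stop("'y' must be numeric with no missing values", call. = FALSE)
  if (length(y) < max(baseline_frames) + 1L)
    stop("trace must extend beyond the baseline frames", call. = FALSE)
  baseline <- y[baseline_frames]
  post <- y[-seq_len(max(baseline_frames))]
  yprime <- post - mean(baseline)

  median_ok <- stats::median(yprime) >= 0
  p <- suppressWarnings(
    stats::wilcox.test(post, baseline, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  )
  responsive <- is.finite(p) && p < alpha
  peak_idx <- which.max(yprime)
  peak_ok <- peak_idx <= ceiling(length(yprime) / 2)

  structure(
    list(median_nonnegative = median_ok,
         responsive = responsive,
         peak_in_first_half = peak_ok,
         eligible = median_ok && responsive && peak_ok,
         p_value = p),
    class = "fit_criteria"
  )
}

#' @export
print.fit_criteria <- function(x, ...) {
  cat(sprintf(
    "Fit criteria: median>=0 %s | responsive (p=%.3g) %s | early peak %s => %s\n",
    x$median_nonnegative, x$p_value, x$responsive, x$peak_in_first_half,
    if (x$eligible) "ELIGIBLE" else "not eligible"))
  invisible(x)
}

#' Grid of initialisation candidates for the transient fit
#'
#' The fit is restarted from a fixed 3-dimensional grid of initial values
#' to avoid local minima: ten logarithmically spaced decay rates with
#' `1/tau_decay` spanning 15 to 1500 s, six logarithmically spaced values
#' of `tau_delta` from 1e-6 to 1e-1, and five logarithmically spaced decay
#' amplitudes `b` from 0.1 to 1000 - 300 candidates in all. The
#' steady-state `c` is always initialised at the median of the
#' baseline-subtracted transient, which must therefore be non-negative.
#' Candidates are emitted in deterministic lexicographic order of
#' (`tau_decay`, `tau_delta`, `b`), each ascending, so ties downstream are
#' broken reproducibly.
#'
#' @param yprime Baseline-subtracted transient segment (numeric vector).
#' @return A data frame with 300 rows and columns `tau_decay`, `tau_delta`,
#'   `b`, `c`.
#' @export
grid_candidates <- function(yprime) {
  if (!is.numeric(yprime) || anyNA(yprime))
    stop("'yprime' must be numeric with no missing values", call. = FALSE)
  if (stats::median(yprime) < 0)
    stop(paste("median of the transient segment is negative;",
               "the steady-state initialisation would violate its bounds"),
         call. = FALSE)
  log_space <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))
  tau_decay_vals <- sort(1 / log_space(15, 1500, 10))  # 1/1500 .. 1/15
  tau_delta_vals <- log_space(1e-6, 1e-1, 6)
  b_vals <- log_space(0.1, 1000, 5)
  g <- expand.grid(b = b_vals, tau_delta = tau_delta_vals,
                   tau_decay = tau_decay_vals, KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first column fastest; reorder columns so rows
  # are lexicographic in (tau_decay, tau_delta, b)
  g <- g[, c("tau_decay", "tau_delta", "b")]
  g <- g[order(g$tau_decay, g$tau_delta, g$b), , drop = FALSE]
  rownames(g) <- NULL
  g$c <- stats::median(yprime)
  g
}

#' Fit the constrained rise-decay model to one transient
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints, [minpack.lm::nls.lm()]) run from every [grid_candidates()]
#' start; the reported fit is the converged start with the smallest sum of
#' squared residuals, ties broken by grid order. Bounds: `tau_decay >= 0`,
#' `tau_delta >= 0`, `b >= 0` and `0 <= c <= max(yprime)`.
#'
#' @param yprime Baseline-subtracted transient segment (a.u.).
#' @param times Times in seconds from transient onset, same length as
#'   `yprime`, starting at 0.
#' @param ftol Cost convergence tolerance passed to the optimiser.
#' @param max_eval Maximum residual evaluations per start.
#' @return An object of class `"transient_fit"`: list with elements
#'   `params` ([transient_params()]), `r2_error` (residual sum of squares),
#'   `n_starts_evaluated`, `converged` (TRUE when at least one start
#'   converged) and `start_index` (grid row of the winning start).
#' @examples
#' p <- transient_params(1 / 120, 0.03, 4, 1.5)
#' tt <- seq(0, 1530, by = 30)
#' fit <- fit_transient(model_eval(tt, p), tt)
#' 1 / fit$params$tau_decay  # ~120 s
#' @export
fit_transient <- function(yprime, times, ftol = 1e-8, max_eval = 1000) {
  if (length(yprime) != length(times))
    stop("'yprime' and 'times' must have the same length", call. = FALSE)
  if (times[1] != 0)
    stop("'times' must start at 0 (the transient onset)", call. = FALSE)
  starts <- grid_candidates(yprime)
  c_max <- max(yprime)
  if (c_max < 0)
    stop("all transient values are negative; upper bound for 'c' is invalid",
         call. = FALSE)
  lower <- c(0, 0, 0, 0)
  upper <- c(Inf, Inf, Inf, c_max)
  resid_fn <- function(p) {
    e_rise <- exp(-(p[1] + p[2]) * times)
    yprime - (p[3] * (exp(-p[1] * times) - e_rise) + p[4] * (1 - e_rise))
  }
  best_ssr <- Inf
  best_par <- NULL
  best_idx <- NA_integer_
  any_converged <- FALSE
  ctrl <- minpack.lm::nls.lm.control(ftol = ftol, maxfev = max_eval,
                                     maxiter = min(max_eval, 1000L))
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    converged <- fit$info %in% 1:4
    if (!converged) next
    any_converged <- TRUE
    ssr <- sum(fit$fvec^2)
    if (ssr < best_ssr) {  # strict: earlier grid rows win ties
      best_ssr <- ssr
      best_par <- fit$par
      best_idx <- i
    }
  }
  if (!any_converged) {
    return(structure(
      list(params = NULL, r2_error = NA_real_,
           n_starts_evaluated = nrow(starts), converged = FALSE,
           start_index = NA_integer_),
      class = "transient_fit"
    ))
  }
  # clamp tiny negative round-off before constructing the params object
  best_par <- pmax(best_par, 0)
  structure(
    list(params = transient_params(best_par[1], best_par[2],
                                   best_par[3], best_par[4]),
         r2_error = best_ssr,
         n_starts_evaluated = nrow(starts),
         converged = TRUE,
         start_index = best_idx),
    class = "transient_fit"
  )
}

#' @export
print.transient_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Transient fit: no start converged (unfit)\n")
    return(invisible(x))
  }
  cat(sprintf("Transient fit (r2 error = %.4g, %d starts):\n",
              x$r2_error, x$n_starts_evaluated))
  print(x$params)
  invisible(x)
}

#' Fit every eligible cell of a trace matrix
#'
#' Applies [check_fit_criteria()] and, for eligible cells, baseline
#' subtraction ([baseline_split()]) followed by [fit_transient()]. One row
#' per cell is returned whether or not the cell was fitted, so downstream
#' code can account for every cell.
#'
#' @param tm A [trace_matrix()] (frames already aligned so that
#'   `baseline_frames` are pre-agonist).
#' @param baseline_frames 1-based indices of the baseline frames.
#' @param alpha Significance level of the responsiveness criterion.
#' @return Data frame with the cell metadata plus `eligible`,
#'   `median_nonnegative`, `responsive`, `peak_in_first_half`, `converged`,
#'   `tau_decay`, `tau_delta`, `b`, `c`, `inv_tau_decay` (the decay time in
#'   seconds) and `r2_error` (NA when not fitted).
#' @export
fit_cohort <- function(tm, baseline_frames = 1:8, alpha = 0.005) {
  stopifnot(inherits(tm, "trace_matrix"))
  n <- nrow(tm$values)
  out <- tm$metadata
  out$eligible <- out$median_nonnegative <- out$responsive <-
    out$peak_in_first_half <- out$converged <- logical(n)
  out$tau_decay <- out$tau_delta <- out$b <- out$c <-
    out$inv_tau_decay <- out$r2_error <- NA_real_
  n_base <- max(baseline_frames)
  fit_times <- tm$times[-seq_len(n_base)]
  fit_times <- fit_times - fit_times[1]
  for (i in seq_len(n)) {
    y <- tm$values[i, ]
    cr <- check_fit_criteria(y, baseline_frames, alpha)
    out$median_nonnegative[i] <- cr$median_nonnegative
    out$responsive[i] <- cr$responsive
    out$peak_in_first_half[i] <- cr$peak_in_first_half
    out$eligible[i] <- cr$eligible
    if (!cr$eligible) next
    sp <- baseline_split(y, baseline_frames)
    fit <- fit_transient(sp$transient, fit_times)
    out$converged[i] <- fit$converged
    if (!fit$converged) next
    out$tau_decay[i] <- fit$params$tau_decay
    out$tau_delta[i] <- fit$params$tau_delta
    out$b[i] <- fit$params$b
    out$c[i] <- fit$params$c
    out$inv_tau_decay[i] <- if (fit$params$tau_decay > 0)
      1 / fit$params$tau_decay else Inf
    out$r2_error[i] <- fit$r2_error
  }
  out
}
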