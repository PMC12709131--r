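#' Cumulative trapezoidal integral
#'
#' @param times Strictly increasing times in s.
#' @param values Values at `times`, same length.
#' @return Cumulative integral (units of `values` times s), first element 0.
#' @examples
#' cumulative_trapezoid(c(0, 1), c(0, 2))  # 0, 1
#' @export
cumulative_trapezoid <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have the same length", call. = FALSE)
  if (length(times) == 0) stop("empty input", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  n <- length(times)
  if (n == 1) return(0)
  c(0, cumsum(diff(times) * (values[-n] + values[-1]) / 2))
}

#' Ordinary least squares line fit
#'
#' Unweighted OLS with intercept, with `R^2 = 1 - SS_res/SS_tot` (defined as
#' 0 when the response is constant) and standard errors of slope and
#' intercept. Backed by [stats::lm()].
#'
#' @param x,y Numeric vectors, `n >= 2`, `x` not all equal.
#' @return An object of class `"linfit"`: list with `slope`, `intercept`,
#'   `r_squared`, `se_slope`, `se_intercept`, `n`.
#' @examples
#' fit_linear(1:10, 500 * (1:10))
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (diff(range(x)) == 0) stop("degenerate x: all values equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # exact synthetic data triggers lm's "essentially perfect fit" warning;
  # a zero residual variance is a legitimate case here, not a problem
  se <- withCallingHandlers(
    sqrt(diag(stats::vcov(fit))),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r2, se_slope = unname(se[2]),
                 se_intercept = unname(se[1]), n = length(x)),
            class = "linfit")
}

#' @export
print.linfit <- function(x, ...) {
  cat(sprintf("<linfit> y = %.6g x + %.6g  (R2 = %.6g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("  SE(slope) %.4g, SE(intercept) %.4g\n",
              x$se_slope, x$se_intercept))
  invisible(x)
}

#' Assemble a paired MSOLD / SOED dose time series
#'
#' Joins the unmixed singlet oxygen amplitudes of one phantom with its SOED
#' trajectory at the acquisition times, and adds cumulative columns: the
#' trapezoidal cumulative of the MSOLD amplitude (counts s) and of the
#' instantaneous SOED singlet oxygen (uM s) on the same acquisition grid, so
#' the two cumulative quantities share a quadrature and their regression
#' slope is the detection scale. The integrator's cumulative reacted dose
#' `O2rx_uM` is carried alongside.
#'
#' @param amplitudes data.frame from [unmix_series()] (columns `t_s`,
#'   `a_o2`, ...).
#' @param trajectory A `soed_trajectory` covering the acquisition times.
#' @param label Phantom label.
#' @return An object of class `"dose_time_series"` (a data.frame): columns
#'   `t_s, a_o2, cum_msold, inst_soed_uM, cum_soed_uM_s, O2rx_uM, label`.
#' @export
dose_time_series <- function(amplitudes, trajectory, label = "phantom") {
  stopifnot(is.data.frame(amplitudes), "t_s" %in% names(amplitudes),
            "a_o2" %in% names(amplitudes))
  idx <- match(amplitudes$t_s, trajectory$t_s)
  if (anyNA(idx))
    stop("trajectory does not cover all acquisition times", call. = FALSE)
  out <- data.frame(
    t_s = amplitudes$t_s,
    a_o2 = amplitudes$a_o2,
    cum_msold = cumulative_trapezoid(amplitudes$t_s, amplitudes$a_o2),
    inst_soed_uM = trajectory$inst_1O2_uM[idx],
    cum_soed_uM_s = cumulative_trapezoid(amplitudes$t_s,
                                         trajectory$inst_1O2_uM[idx]),
    O2rx_uM = trajectory$O2rx_uM[idx],
    label = label)
  class(out) <- c("dose_time_series", "data.frame")
  out
}

# Nearest acquisition to a requested time, within half a cadence step.
# Equidistant requests resolve to the earlier acquisition.
nearest_acquisition <- function(times, at, cadence) {
  d <- abs(times - at)
  i <- which.min(d)  # ties -> earlier time (which.min returns first)
  if (d[i] > cadence / 2 + 1e-9)
    stop(sprintf("no acquisition within half a cadence step of t = %g s", at),
         call. = FALSE)
  i
}

#' Instantaneous MSOLD-vs-SOED regression at selected times
#'
#' For each requested time, regresses the MSOLD singlet oxygen amplitude
#' against the instantaneous SOED singlet oxygen concentration across
#' phantoms ("instantaneous at t" means the nearest acquisition within half a
#' cadence step). Near-identical slopes across times are the signature of a
#' common detection scale.
#'
#' @param series_list List of `dose_time_series`, one per phantom (>= 2).
#' @param at_times Times in s at which to compare (default `c(1, 450, 900)`).
#' @param cadence_s Acquisition cadence in s (default 100).
#' @return Named list of `linfit` objects, one per requested time.
#' @export
correlate_instantaneous <- function(series_list, at_times = c(1, 450, 900),
                                    cadence_s = 100) {
  if (length(series_list) < 2)
    stop("regression across phantoms needs at least 2 series", call. = FALSE)
  fits <- lapply(at_times, function(at) {
    pts <- vapply(series_list, function(s) {
      i <- nearest_acquisition(s$t_s, at, cadence_s)
      c(s$inst_soed_uM[i], s$a_o2[i])
    }, numeric(2))
    fit_linear(pts[1, ], pts[2, ])
  })
  names(fits) <- paste0("t", at_times, "s")
  fits
}

#' Cumulative MSOLD-vs-SOED regression
#'
#' Pools all (cumulative SOED, cumulative MSOLD) pairs across phantoms and
#' acquisition times and fits one OLS line. With amplitudes generated as
#' `kappa_detect` times the instantaneous singlet oxygen concentration, the
#' recovered slope is `kappa_detect` (counts per uM).
#'
#' @param series_list List of `dose_time_series` (>= 2).
#' @return A `linfit`.
#' @export
correlate_cumulative <- function(series_list) {
  if (length(series_list) < 2)
    stop("need at least 2 series", call. = FALSE)
  x <- unlist(lapply(series_list, function(s) s$cum_soed_uM_s))
  y <- unlist(lapply(series_list, function(s) s$cum_msold))
  fit_linear(x, y)
}

#' Linear photobleaching fit
#'
#' OLS line fit of relative photosensitizer concentration against time
#' (bleaching is approximately linear over a treatment at these
#' concentrations).
#'
#' @param times Times in s.
#' @param relative_concentration Concentration normalised to 1 at t = 0.
#' @return A `linfit`.
#' @export
photobleach_fit <- function(times, relative_concentration) {
  fit_linear(times, relative_concentration)
}
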