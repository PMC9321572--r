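# Environmental curves: construction, smoothing and evaluation. The curve
# plays the role of a paleoenvironmental series (e.g. global temperature)
# driving speciation rates in the environment-dependent models.

#' Environmental time series
#'
#' An ordered table of (age, value) pairs with a smoothing specification.
#' Evaluation ([env_fun()]) goes through a cubic smoothing spline with the
#' stated degrees of freedom (default 33, the conventional smoothing used
#' for Phanerozoic temperature series), with linear extrapolation outside
#' the tabulated age range.
#'
#' @param age_ma Ages, Myr before present; non-negative, strictly increasing.
#' @param value Environmental values at those ages.
#' @param df Degrees of freedom of the smoothing spline.
#' @return An object of class `"env_curve"`.
#' @export
env_curve <- function(age_ma, value, df = 33) {
  stopifnot(is.numeric(age_ma), is.numeric(value),
            length(age_ma) == length(value), length(age_ma) >= 2L)
  if (any(age_ma < 0) || any(diff(age_ma) <= 0))
    stop("ages must be non-negative and strictly increasing")
  structure(list(age_ma = age_ma, value = value, df = df),
            class = "env_curve")
}

#' Smoothed evaluator for an environmental curve
#'
#' Returns a vectorised function of age. The tabulated series is smoothed
#' with [stats::smooth.spline()] at `curve$df` degrees of freedom (capped at
#' the number of distinct ages); ages outside the tabulated range are
#' extrapolated linearly from the spline's boundary slope, with a warning.
#' A constant series is returned as a constant function.
#'
#' @param curve An [env_curve()] object.
#' @param warn_extrapolation Warn when evaluated outside the tabulated range.
#' @return `function(age)` returning environmental values.
#' @export
env_fun <- function(curve, warn_extrapolation = TRUE) {
  stopifnot(inherits(curve, "env_curve"))
  x <- curve$age_ma; y <- curve$value
  if (stats::var(y) == 0) {
    cst <- y[1L]
    return(function(age) rep(cst, length(age)))
  }
  df <- min(curve$df, length(unique(x)))
  sp <- stats::smooth.spline(x, y, df = df)
  lo <- min(x); hi <- max(x)
  slope_lo <- stats::predict(sp, lo, deriv = 1L)$y
  slope_hi <- stats::predict(sp, hi, deriv = 1L)$y
  warned <- FALSE
  function(age) {
    out <- numeric(length(age))
    inside <- age >= lo & age <= hi
    if (any(inside)) out[inside] <- stats::predict(sp, age[inside])$y
    if (any(!inside)) {
      if (warn_extrapolation && !warned) {
        warning("environmental curve evaluated outside its age range; ",
                "extrapolating linearly")
        warned <<- TRUE
      }
      below <- !inside & age < lo
      above <- !inside & age > hi
      if (any(below))
        out[below] <- stats::predict(sp, lo)$y + slope_lo * (age[below] - lo)
      if (any(above))
        out[above] <- stats::predict(sp, hi)$y + slope_hi * (age[above] - hi)
    }
    out
  }
}

#' Simulate an environmental curve
#'
#' Generates an [env_curve()] on a regular age grid under a simple parametric
#' shape, optionally with observation noise. Shapes: `"constant"` (params:
#' `value`), `"linear"` (`from` at age 0 to `to` at `age_max`), `"sinusoid"`
#' (`mean`, `amplitude`, `period` in Myr, optional `phase`).
#'
#' @param shape Curve shape.
#' @param params Named list of shape parameters (see Details).
#' @param age_max Maximum age, Myr.
#' @param step Grid spacing, Myr.
#' @param noise_sd Standard deviation of iid Gaussian noise added to the
#'   tabulated values.
#' @param df Smoothing degrees of freedom stored with the curve.
#' @param seed Optional integer seed.
#' @return An `"env_curve"` object.
#' @export
simulate_env_curve <- function(shape = c("constant", "linear", "sinusoid"),
                               params = list(), age_max = 505, step = 1,
                               noise_sd = 0, df = 33, seed = NULL) {
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  age <- seq(0, age_max, by = step)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  value <- switch(shape,
    constant = rep(p("value", 0), length(age)),
    linear   = p("from", 0) + (p("to", 1) - p("from", 0)) * age / age_max,
    sinusoid = p("mean", 0) + p("amplitude", 1) *
      sin(2 * pi * (age / p("period", 100)) + p("phase", 0)))
  if (noise_sd > 0) value <- value + stats::rnorm(length(age), 0, noise_sd)
  env_curve(age, value, df = df)
}

#' @export
print.env_curve <- function(x, ...) {
  cat(sprintf("Environmental curve: %d points over [%g, %g] Myr, spline df = %g\n",
              length(x$age_ma), min(x$age_ma), max(x$age_ma), x$df))
  invisible(x)
}
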