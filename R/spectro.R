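# Spectroscopy and aggregation-kinetics statistics: Parameter A, emission
# maximum, denaturant transition curves and first-order turbidity fits.

#' Construct a fluorescence emission spectrum
#'
#' @param wavelengths nm, strictly increasing.
#' @param intensities arbitrary units, non-negative, same length.
#' @param excitation excitation wavelength (nm), informational.
#' @param label free-text label.
#' @return object of class `Spectrum`.
#' @export
new_spectrum <- function(wavelengths, intensities, excitation = NA_real_, label = "") {
  stopifnot(length(wavelengths) == length(intensities))
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(
    list(
      wavelengths = as.numeric(wavelengths), intensities = as.numeric(intensities),
      excitation = excitation, label = label
    ),
    class = "Spectrum"
  )
}

#' Parameter A of a tryptophan emission spectrum
#'
#' The shape statistic I320/I365: fluorescence intensity at 320 nm divided by
#' the intensity at 365 nm, each obtained by linear interpolation on the
#' wavelength grid.  Sensitive to the tryptophan environment; raw intensities
#' are used (no baseline correction).
#'
#' @param spec `Spectrum` covering 320-365 nm.
#' @return numeric ratio.
#' @export
parameter_a <- function(spec) {
  w <- spec$wavelengths
  if (min(w) > 320 || max(w) < 365) {
    stop("coverage error: spectrum must span 320-365 nm")
  }
  i320 <- stats::approx(w, spec$intensities, xout = 320)$y
  i365 <- stats::approx(w, spec$intensities, xout = 365)$y
  if (i365 == 0) stop("division error: zero intensity at 365 nm")
  i320 / i365
}

moving_average <- function(y, width) {
  if (width <= 1) {
    return(y)
  }
  if (width %% 2 == 0) width <- width + 1
  k <- rep(1 / width, width)
  sm <- stats::filter(y, k, sides = 2)
  as.numeric(ifelse(is.na(sm), y, sm)) # keep raw values at the edges
}

#' Emission maximum wavelength (E_max)
#'
#' Wavelength of maximum intensity after fixed-width moving-average smoothing,
#' refined by three-point quadratic interpolation around the grid maximum.
#' A plateau, multiple equal maxima, or a boundary maximum triggers an
#' ambiguity warning and the leftmost grid maximum is reported unrefined.
#'
#' @param spec `Spectrum` with at least 5 points.
#' @param smooth_width moving-average window in points (default 5).
#' @return wavelength in nm.
#' @export
e_max <- function(spec, smooth_width = 5) {
  w <- spec$wavelengths
  y <- spec$intensities
  if (length(w) < 5) stop("need at least 5 points")
  sm <- moving_average(y, smooth_width)
  imax <- which(sm == max(sm))
  if (length(imax) > 1 || imax[1] == 1 || imax[1] == length(w)) {
    warning("ambiguous emission maximum (plateau or boundary); reporting leftmost")
    return(w[imax[1]])
  }
  i <- imax
  # quadratic vertex through the three points around the grid maximum
  y1 <- sm[i - 1]
  y2 <- sm[i]
  y3 <- sm[i + 1]
  denom <- (y1 - 2 * y2 + y3)
  if (abs(denom) < 1e-15) {
    return(w[i])
  }
  delta <- 0.5 * (y1 - y3) / denom
  w[i] + delta * (w[i + 1] - w[i])
}

#' Assemble a denaturant titration curve
#'
#' Sorts (concentration, signal) observations into a `TitrationCurve`; signals
#' may be scalars or `Spectrum` objects reduced by a named statistic.
#' Duplicate concentrations are merged by their mean (logged).
#'
#' @param conc denaturant concentrations, mol/L (at least 6 distinct values).
#' @param signal numeric vector, or list of `Spectrum` objects when
#'   `signal_name` is `"ParamA"` or `"Emax"`.
#' @param signal_name one of `"CD222"`, `"Emax"`, `"IntF"`, `"ParamA"`,
#'   `"ANS"`, `"turbidity"`, `"signal"`.
#' @param normalize min-max normalize the signal to `[0, 1]`.
#' @return object of class `TitrationCurve`: data frame `conc`, `signal` with
#'   a `signal_name` attribute.
#' @export
assemble_transition <- function(conc, signal,
                                signal_name = c(
                                  "signal", "CD222", "Emax", "IntF",
                                  "ParamA", "ANS", "turbidity"
                                ),
                                normalize = FALSE) {
  signal_name <- match.arg(signal_name)
  stopifnot(all(conc >= 0))
  if (is.list(signal) && inherits(signal[[1]], "Spectrum")) {
    signal <- switch(signal_name,
      ParamA = vapply(signal, parameter_a, numeric(1)),
      Emax = vapply(signal, e_max, numeric(1)),
      stop("signal_name '", signal_name, "' cannot be computed from spectra")
    )
  }
  stopifnot(length(conc) == length(signal))
  if (anyDuplicated(conc)) {
    message("duplicate concentrations merged by mean")
    agg <- tapply(signal, conc, mean)
    conc <- as.numeric(names(agg))
    signal <- as.numeric(agg)
  }
  if (length(unique(conc)) < 6) stop("need at least 6 distinct concentrations")
  ord <- order(conc)
  out <- data.frame(conc = conc[ord], signal = signal[ord])
  if (normalize) {
    rng <- range(out$signal)
    if (diff(rng) > 0) out$signal <- (out$signal - rng[1]) / diff(rng)
  }
  attr(out, "signal_name") <- signal_name
  class(out) <- c("TitrationCurve", "data.frame")
  out
}

#' Detect transition midpoints of a titration curve
#'
#' Midpoints are located at the extrema of the smoothed first derivative of
#' the min-max-normalized signal versus concentration: the curve is linearly
#' interpolated onto a fine grid, smoothed with a fixed-width moving average,
#' differentiated, and the `n_transitions` strongest well-separated local
#' extrema of the absolute derivative are refined by quadratic interpolation
#' and returned in ascending concentration order.
#'
#' @param tc `TitrationCurve`.
#' @param n_transitions 1 or 2.
#' @param grid_step interpolation grid step, mol/L (default 0.01).
#' @param smooth_width smoothing window on the grid, points (default 15).
#' @param min_separation minimum spacing between reported midpoints, mol/L.
#' @return numeric vector of midpoints (mol/L), ascending.
#' @export
detect_midpoints <- function(tc, n_transitions, grid_step = 0.01, smooth_width = 15,
                             min_separation = 0.4) {
  stopifnot(n_transitions %in% c(1, 2))
  x <- tc$conc
  y <- tc$signal
  rng <- range(y)
  if (diff(rng) == 0) stop("detection error: flat curve has no transitions")
  y <- (y - rng[1]) / diff(rng)
  grid <- seq(min(x), max(x), by = grid_step)
  yg <- stats::approx(x, y, xout = grid)$y
  yg <- moving_average(yg, smooth_width)
  dy <- diff(yg) / diff(grid)
  xm <- (grid[-1] + grid[-length(grid)]) / 2
  ady <- abs(moving_average(dy, smooth_width))
  # local maxima of |dy|
  n <- length(ady)
  is_peak <- c(FALSE, ady[2:(n - 1)] > ady[1:(n - 2)] & ady[2:(n - 1)] >= ady[3:n], FALSE)
  peaks <- which(is_peak)
  peaks <- peaks[order(-ady[peaks])]
  chosen <- integer(0)
  for (p in peaks) {
    if (all(abs(xm[p] - xm[chosen]) >= min_separation)) chosen <- c(chosen, p)
    if (length(chosen) == n_transitions) break
  }
  if (length(chosen) < n_transitions) {
    stop("detection error: found ", length(chosen), " transition(s), requested ", n_transitions)
  }
  refine <- vapply(chosen, function(p) {
    if (p <= 1 || p >= n) {
      return(xm[p])
    }
    y1 <- ady[p - 1]
    y2 <- ady[p]
    y3 <- ady[p + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) < 1e-15) {
      return(xm[p])
    }
    xm[p] + 0.5 * (y1 - y3) / denom * (xm[p + 1] - xm[p])
  }, numeric(1))
  sort(refine)
}

#' Fit first-order aggregation kinetics to a turbidity trace
#'
#' Least-squares fit of the lagged single-exponential progress curve
#' `A(t) = baseline` for `t < lag`, and
#' `A(t) = baseline + plateau (1 - exp(-k (t - lag)))` for `t >= lag`,
#' the standard form for turbidity time courses of aggregating protein with a
#' lag phase.  The baseline is initialized from the pre-rise points and the
#' nonlinear minimization uses Levenberg-Marquardt.
#'
#' @param time time in seconds, increasing.
#' @param a400 turbidity (absorbance at 400 nm), same length, at least 20
#'   points with a non-decreasing overall trend.
#' @return object of class `AggregationFit`: list with `rate_k` (per second),
#'   `lag_time` (s), `plateau`, `baseline`, `residual_rms`.
#' @export
fit_aggregation <- function(time, a400) {
  stopifnot(length(time) == length(a400))
  if (length(time) < 20) stop("need at least 20 points")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  amp <- max(a400) - min(a400)
  if (amp <= 0 || stats::cor(time, a400) < 0.2) {
    stop("fit error: no aggregation signal (flat or non-increasing trace)")
  }
  base0 <- stats::quantile(a400, 0.02, names = FALSE)
  plateau0 <- stats::quantile(a400, 0.98, names = FALSE) - base0
  above <- which(a400 > base0 + 0.05 * plateau0)
  lag0 <- if (length(above) > 0) time[above[1]] else time[1]
  lag0 <- max(lag0, time[1])
  # crude rate guess from the 5-95% rise interval
  hi <- which(a400 > base0 + 0.95 * plateau0)
  t95 <- if (length(hi) > 0) time[hi[1]] else time[length(time)]
  k0 <- 3 / max(t95 - lag0, diff(range(time)) / 50)

  model <- function(p, t) {
    lag <- p[["lag"]]
    ifelse(t < lag, p[["base"]],
      p[["base"]] + p[["plateau"]] * (1 - exp(-p[["k"]] * (t - lag)))
    )
  }
  fit <- minpack.lm::nls.lm(
    par = list(base = base0, plateau = plateau0, k = k0, lag = lag0),
    fn = function(p) a400 - model(p, time),
    lower = c(-Inf, 0, 1e-8, time[1]),
    upper = c(Inf, Inf, Inf, time[length(time)]),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info %in% c(0, 5)) {
    stop("fit error: no convergence (", fit$message, ")")
  }
  p <- fit$par
  if (p$k <= 0) stop("fit error: non-positive aggregation rate")
  structure(
    list(
      rate_k = p$k, lag_time = p$lag, plateau = p$plateau, baseline = p$base,
      residual_rms = sqrt(mean(fit$fvec^2))
    ),
    class = "AggregationFit"
  )
}

#' @export
print.AggregationFit <- function(x, ...) {
  cat(sprintf(
    "First-order aggregation fit: k = %.4g /s, lag = %.4g s, plateau = %.4g (rms %.3g)\n",
    x$rate_k, x$lag_time, x$plateau, x$residual_rms
  ))
  invisible(x)
}
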