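# Circular-dichroism thermal unfolding: fraction-unfolded curves from
# temperature-ellipticity traces and the denaturation midpoint Tm.

#' Construct a CD melting trace
#'
#' @param temperature Strictly increasing temperatures in degrees C.
#' @param ellipticity Signed ellipticity readings (arbitrary CD units,
#'   typically theta at 220 nm).
#' @param t_low,t_high Reference temperatures pinning the folded (fraction
#'   unfolded 0) and fully unfolded (fraction 1) baselines. The defaults
#'   (20, 60) suit the standard scan; thermostable variants use
#'   `t_high = 70` - a parameter, not a separate code path.
#' @return A data frame of class `"melt_trace"`.
#' @export
melt_trace <- function(temperature, ellipticity, t_low = 20, t_high = 60) {
  temperature <- as.numeric(temperature)
  ellipticity <- as.numeric(ellipticity)
  if (length(temperature) != length(ellipticity)) {
    stop("temperature and ellipticity differ in length")
  }
  if (any(diff(temperature) <= 0)) stop("temperature grid must be strictly increasing")
  if (t_low < min(temperature) - 1e-9 || t_high > max(temperature) + 1e-9) {
    stop("reference temperatures must lie within the trace span")
  }
  out <- data.frame(temperature = temperature, ellipticity = ellipticity)
  attr(out, "t_low") <- t_low
  attr(out, "t_high") <- t_high
  class(out) <- c("melt_trace", "data.frame")
  out
}

#' Read a melting trace from a two-column file
#'
#' @param path CSV or TSV file with temperature in the first column and
#'   ellipticity in the second (header optional, auto-detected).
#' @param ... Passed to [melt_trace()] (e.g. `t_high = 70`).
#' @return A [melt_trace()].
#' @export
read_melt_trace <- function(path, ...) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- is.na(suppressWarnings(as.numeric(strsplit(first, sep)[[1]][1])))
  tab <- utils::read.table(path, sep = sep, header = header)
  melt_trace(tab[[1]], tab[[2]], ...)
}

#' Fraction-unfolded curve from a melting trace
#'
#' Smooths the raw ellipticity by an unweighted mean over all samples within
#' +/- `window` degrees C of each point, resamples onto a `grid_step` grid by
#' linear interpolation, and normalizes to fraction unfolded
#' f(T) = (theta_T - theta_low) / (theta_high - theta_low) using the smoothed
#' values at the reference temperatures, so f(t_low) = 0 and f(t_high) = 1 by
#' construction. The result is invariant to affine rescaling of the CD units.
#'
#' @param trace A [melt_trace()].
#' @param window Smoothing half-window in degrees C (default 0.4).
#' @param grid_step Output grid interval in degrees C (default 1.0).
#' @return An `"unfolding_curve"` data frame with columns `temperature` and
#'   `fraction`, spanning `[t_low, t_high]`.
#' @export
fraction_unfolded <- function(trace, window = 0.4, grid_step = 1.0) {
  stopifnot(inherits(trace, "melt_trace"))
  t_low <- attr(trace, "t_low")
  t_high <- attr(trace, "t_high")
  tt <- trace$temperature
  th <- trace$ellipticity
  smooth <- vapply(tt, function(t0) mean(th[abs(tt - t0) <= window + 1e-9]),
                   numeric(1))
  grid <- seq(t_low, t_high, by = grid_step)
  on_grid <- stats::approx(tt, smooth, xout = grid, rule = 2)$y
  denom <- on_grid[length(on_grid)] - on_grid[1]
  if (abs(denom) < 1e-12 * max(abs(on_grid), 1)) {
    stop("degenerate baselines: ellipticity at t_high equals that at t_low")
  }
  out <- data.frame(temperature = grid,
                    fraction = (on_grid - on_grid[1]) / denom)
  attr(out, "t_low") <- t_low
  attr(out, "t_high") <- t_high
  class(out) <- c("unfolding_curve", "data.frame")
  out
}

#' Denaturation midpoint Tm
#'
#' The temperature at which half the sample is unfolded: the first upward
#' crossing of fraction = 0.5, linearly interpolated between the bracketing
#' grid points. Noisy multi-crossing curves use the first crossing (two-state
#' assumption).
#'
#' @param curve An [fraction_unfolded()] result.
#' @return Tm in degrees C.
#' @export
estimate_tm <- function(curve) {
  stopifnot(inherits(curve, "unfolding_curve"))
  f <- curve$fraction
  tt <- curve$temperature
  for (i in seq_len(length(f) - 1)) {
    if (f[i] < 0.5 && f[i + 1] >= 0.5) {
      return(tt[i] + (0.5 - f[i]) / (f[i + 1] - f[i]) * (tt[i + 1] - tt[i]))
    }
  }
  stop("no midpoint in range: the curve never crosses 0.5 upward")
}
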