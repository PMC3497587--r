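#' Drop the transient head of a trajectory
#'
#' Limit-cycle features are computed after discarding the initial
#' transient; this returns the sub-trajectory with `time_min >= discard`
#' on the unchanged grid.
#'
#' @param traj a `wolf_trajectory` (see [simulate_wolf()]).
#' @param discard minutes to drop from the start (must leave a non-empty
#'   window).
#' @return The retained `wolf_trajectory`.
#' @export
steady_window <- function(traj, discard) {
  stopifnot(is.numeric(discard), discard >= 0)
  span <- traj$time_min[nrow(traj)]
  if (discard >= span)
    stop("discard (", discard, " min) must be smaller than the trajectory ",
         "span (", span, " min)")
  out <- traj[traj$time_min >= discard, , drop = FALSE]
  attr(out, "params") <- attr(traj, "params")
  class(out) <- class(traj)
  out
}

#' Locate peaks with parabolic interpolation
#'
#' Finds strict local maxima (samples above both neighbours) of a
#' uniformly sampled series and refines each peak time by fitting a
#' parabola through the three bracketing samples, giving sub-grid peak
#' locations.
#'
#' @param times uniform, strictly increasing sampling times.
#' @param values series values (same length as `times`, >= 3 points).
#' @return Sorted numeric vector of interpolated peak times (possibly
#'   empty).
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' find_peaks(t, sin(2 * pi * t))  # peaks 0.25, 1.25, ...
#' @export
find_peaks <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 3)
  n <- length(values)
  dt <- times[2] - times[1]
  mid <- values[2:(n - 1)]
  idx <- which(mid > values[1:(n - 2)] & mid > values[3:n]) + 1L
  if (!length(idx)) return(numeric(0))
  y1 <- values[idx - 1]; y2 <- values[idx]; y3 <- values[idx + 1]
  # vertex of the parabola through the three samples
  shift <- (y1 - y3) / (2 * (y1 - 2 * y2 + y3))
  sort(times[idx] + shift * dt)
}

#' Limit-cycle oscillation features of one species
#'
#' Extracts amplitude, period and oscillatory status of one species of a
#' model trajectory. The transient is discarded (default 10 model
#' minutes); if the inter-peak intervals in the retained window still vary
#' by more than `cv_max`, the discard is increased stepwise up to half the
#' horizon. Amplitude is measured over the retained window as the full
#' peak-to-trough range (`mode = "range"`, the package's calibrated
#' default) or as half of it (`"half_range"`). The period is the slope of
#' a least-squares regression of interpolated peak times on cycle index,
#' converted from model minutes to seconds; peak-time regression averages
#' interpolation error over all cycles. A series whose range falls below
#' `death_threshold` (or with fewer than `min_peaks` peaks) is flagged
#' non-oscillatory and carries no period.
#'
#' @param traj a `wolf_trajectory`.
#' @param species one of `"S1"..."S6x"`, `"N2"`, `"A3"`.
#' @param discard initial transient discard, model minutes.
#' @param mode amplitude convention, `"range"` (calibrated default) or
#'   `"half_range"`.
#' @param death_threshold oscillation-death threshold on the range, mM.
#' @param min_peaks minimum number of peaks for a period estimate.
#' @param cv_max maximum tolerated coefficient of variation of inter-peak
#'   intervals before discarding more transient.
#' @return An `osc_features` list: `species`, `amplitude` (mM), `period`
#'   (s, `NA` when non-oscillatory), `frequency` (cycles/s), `oscillatory`,
#'   `n_peaks`, `window` (minutes), `mode`.
#' @examples
#' \donttest{
#' traj <- simulate_wolf(t_end = 20)
#' oscillation_features(traj, "N2")
#' }
#' @export
oscillation_features <- function(traj, species = "N2", discard = 10,
                                 mode = c("range", "half_range"),
                                 death_threshold = 1e-4, min_peaks = 4,
                                 cv_max = 0.01) {
  mode <- match.arg(mode)
  if (!species %in% names(traj))
    stop("unknown species '", species, "'")
  span <- traj$time_min[nrow(traj)]
  d <- min(discard, span / 2)
  repeat {
    w <- steady_window(traj, d)
    x <- w[[species]]
    pk <- find_peaks(w$time_min, x)
    gaps <- diff(pk)
    cv <- if (length(gaps) >= 2) stats::sd(gaps) / mean(gaps) else Inf
    if (length(pk) < min_peaks || cv <= cv_max || d >= span / 2) break
    d <- min(d + span / 10, span / 2)
  }
  rng <- max(x) - min(x)
  amp <- if (mode == "range") rng else rng / 2
  oscillatory <- rng >= death_threshold && length(pk) >= min_peaks
  period <- frequency <- NA_real_
  if (oscillatory) {
    period <- 60 * unname(stats::coef(
      stats::lm(pk ~ seq_along(pk)))[2])  # min -> s
    frequency <- 1 / period
  }
  structure(list(species = species, amplitude = amp, period = period,
                 frequency = frequency, oscillatory = oscillatory,
                 n_peaks = length(pk),
                 window = c(w$time_min[1], w$time_min[length(w$time_min)]),
                 mode = mode),
            class = "osc_features")
}

#' @export
print.osc_features <- function(x, ...) {
  cat(sprintf("Oscillation features of %s over [%.2f, %.2f] min:\n",
              x$species, x$window[1], x$window[2]))
  if (x$oscillatory)
    cat(sprintf("  amplitude %.4g (%s), period %.4f s, %d peaks\n",
                x$amplitude, x$mode, x$period, x$n_peaks))
  else
    cat(sprintf("  non-oscillatory (range %.3g, %d peaks)\n",
                x$amplitude, x$n_peaks))
  invisible(x)
}

#' Limit-cycle period of one species, seconds
#'
#' @inheritParams oscillation_features
#' @param ... passed to [oscillation_features()].
#' @return Period in seconds; errors if the species is not oscillating.
#' @export
period_of <- function(traj, species = "N2", ...) {
  f <- oscillation_features(traj, species, ...)
  if (!f$oscillatory)
    stop("no oscillation detected for species '", species,
         "' (range ", signif(f$amplitude, 3), ", ", f$n_peaks, " peaks)")
  f$period
}

#' Limit-cycle amplitude of one species, mM
#'
#' @inheritParams oscillation_features
#' @param ... passed to [oscillation_features()].
#' @return Amplitude in the requested mode (0 for a flat series).
#' @export
amplitude_of <- function(traj, species = "N2",
                         mode = c("range", "half_range"), ...) {
  mode <- match.arg(mode)
  oscillation_features(traj, species, mode = mode, ...)$amplitude
}

#' Discrete Fourier transform of a real series
#'
#' Computes `X_k = sum_{n=1..N} x_n * exp(-i*2*pi*(k-1)*(n-1)/N)` for
#' `k = 1..N` (1-based indexing; `X_1` is the DC term). The fast transform
#' ([stats::fft()]) is used; it equals the direct sum to round-off.
#'
#' @param x real series, length >= 2, finite.
#' @param dt sampling interval of `x` in the time unit of interest
#'   (seconds for fluorescence traces); fixes the bin-frequency scale.
#' @return A `spectrum_dft` list: `N`, complex `coef` (length N), `freq`
#'   (bin frequencies `(k-1)/(N*dt)`, cycles per time unit), `power`
#'   (`|X_k|^2`), `dt`.
#' @examples
#' s <- dft(c(1, 2, 0, -1))
#' s$coef
#' @export
dft <- function(x, dt = 1) {
  if (length(x) < 2) stop("series must have length >= 2")
  if (!all(is.finite(x))) stop("non-finite values in series")
  stopifnot(dt > 0)
  X <- stats::fft(x)
  N <- length(x)
  structure(list(N = N, coef = X, freq = (seq_len(N) - 1) / (N * dt),
                 power = Mod(X)^2, dt = dt),
            class = "spectrum_dft")
}

#' @export
print.spectrum_dft <- function(x, ...) {
  cat(sprintf("DFT spectrum: N = %d, bin width %.4g cycles/unit\n",
              x$N, 1 / (x$N * x$dt)))
  invisible(x)
}

#' Dominant non-DC frequency of a spectrum
#'
#' Frequency of the maximum-power bin among the one-sided non-DC bins
#' `k = 2..floor(N/2)+1`; ties break toward the lowest frequency.
#'
#' @param spec a `spectrum_dft` (see [dft()]); `N >= 4`.
#' @return Frequency in cycles per time unit of `dt`.
#' @export
dominant_frequency <- function(spec) {
  stopifnot(inherits(spec, "spectrum_dft"))
  if (spec$N < 4) stop("need N >= 4 for a one-sided spectrum")
  k <- 2:(floor(spec$N / 2) + 1)
  pw <- spec$power[k]
  if (max(pw) <= sum(spec$power) * 1e-20)
    stop("no oscillation: all spectral power is in the DC bin")
  spec$freq[k[which.max(pw)]]
}
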