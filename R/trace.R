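#' NADH fluorescence trace object
#'
#' Container for a fluorescence time series recorded under the standard
#' oscillation-induction protocol: sampling at 10 Hz, glucose added at
#' 60 s, KCN at 140 s, intensities in arbitrary units. Uniform sampling
#' is enforced to 1e-6 s.
#'
#' @param time_s sampling times, seconds, uniform grid.
#' @param intensity fluorescence intensity, arbitrary units.
#' @param glucose_time glucose addition time, s.
#' @param kcn_time KCN addition time, s (must satisfy
#'   `glucose_time < kcn_time < max(time_s)`).
#' @param strain strain label (optional).
#' @param replicate replicate id (optional).
#' @return An `nadh_trace`: a data frame with columns `time_s`,
#'   `intensity` and event/strain metadata in attributes.
#' @export
nadh_trace <- function(time_s, intensity, glucose_time = 60,
                       kcn_time = 140, strain = NA_character_,
                       replicate = NA_integer_) {
  if (length(time_s) != length(intensity) || length(time_s) < 3)
    stop("time_s and intensity must have equal length >= 3")
  if (!all(is.finite(intensity))) stop("non-finite intensity values")
  dt <- diff(time_s)
  if (any(abs(dt - dt[1]) > 1e-6))
    stop("non-uniform sampling: time steps deviate by more than 1e-6 s")
  if (!(glucose_time < kcn_time && kcn_time < time_s[length(time_s)]))
    stop("event times must satisfy glucose_time < kcn_time < last sample")
  tr <- data.frame(time_s = time_s, intensity = intensity)
  attr(tr, "glucose_time") <- glucose_time
  attr(tr, "kcn_time") <- kcn_time
  attr(tr, "strain") <- strain
  attr(tr, "replicate") <- replicate
  class(tr) <- c("nadh_trace", "data.frame")
  tr
}

#' @export
print.nadh_trace <- function(x, ...) {
  cat(sprintf(
    "NADH trace%s: %d samples at %.3g Hz, glucose at %g s, KCN at %g s\n",
    if (is.na(attr(x, "strain"))) "" else paste0(" [", attr(x, "strain"), "]"),
    nrow(x), 1 / (x$time_s[2] - x$time_s[1]),
    attr(x, "glucose_time"), attr(x, "kcn_time")))
  invisible(x)
}

.trace_rate <- function(trace) 1 / (trace$time_s[2] - trace$time_s[1])

.meta_path <- function(path) sub("\\.[^.]*$", "", path)  # strip extension

#' Read / write an NADH trace as CSV plus metadata sidecar
#'
#' The trace is a two-column CSV with header `time_s,intensity`. Event
#' times, strain and (for synthetic traces) the generator ground truth
#' live in a JSON sidecar named `<stem>.meta.json`; when the sidecar is
#' absent the protocol defaults (glucose 60 s, KCN 140 s) are used.
#'
#' @param path CSV file path.
#' @param trace an `nadh_trace` (for writing).
#' @param write_meta write the sidecar as well (default `TRUE`).
#' @return `read_trace()` returns an `nadh_trace`; `write_trace()` the
#'   path, invisibly.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "intensity") %in% names(df)))
    stop("trace CSV must have columns time_s,intensity")
  meta_file <- paste0(.meta_path(path), ".meta.json")
  meta <- if (file.exists(meta_file))
    jsonlite::read_json(meta_file, simplifyVector = TRUE) else list()
  tr <- nadh_trace(
    df$time_s, df$intensity,
    glucose_time = meta$glucose_time %||% 60,
    kcn_time = meta$kcn_time %||% 140,
    strain = meta$strain %||% NA_character_,
    replicate = meta$replicate %||% NA_integer_)
  if (!is.null(meta$ground_truth))
    attr(tr, "ground_truth") <- meta$ground_truth
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_trace
#' @export
write_trace <- function(trace, path, write_meta = TRUE) {
  df <- as.data.frame(trace)[, c("time_s", "intensity")]
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  if (write_meta) {
    meta <- list(glucose_time = attr(trace, "glucose_time"),
                 kcn_time = attr(trace, "kcn_time"),
                 strain = attr(trace, "strain"),
                 replicate = attr(trace, "replicate"))
    gt <- attr(trace, "ground_truth")
    if (!is.null(gt)) meta$ground_truth <- gt
    jsonlite::write_json(meta, paste0(.meta_path(path), ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# centered rolling range (max - min) evaluated on a decimated grid and
# step-interpolated back; window and stride in samples
.rolling_range <- function(x, window, stride) {
  n <- length(x)
  centers <- seq(1L, n, by = stride)
  half <- window %/% 2
  rr <- vapply(centers, function(i) {
    j <- max(1L, i - half):min(n, i + half)
    max(x[j]) - min(x[j])
  }, numeric(1))
  stats::approx(centers, rr, xout = seq_len(n), method = "constant",
                rule = 2)$y
}

.running_mean <- function(x, w) {
  if (w < 2) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  # fill the filter's NA edges with the original samples
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Select the oscillating window of a fluorescence trace
#'
#' Identifies the portion of a trace that carries sustained oscillations.
#' The measurement noise SD is estimated from the pre-glucose baseline
#' (residuals of a linear fit). The post-KCN signal is linearly detrended
#' and lightly smoothed; the window starts at the second peak after KCN
#' (skipping the induction transient) and ends where the rolling
#' peak-to-trough range over three nominal periods falls below three
#' times the noise SD, or at the trace end. If no post-KCN peak rises
#' above the noise the verdict is non-oscillatory (not an error).
#'
#' @param trace an `nadh_trace`.
#' @param nominal_period expected oscillation period, s, used only to set
#'   the smoothing and rolling-window lengths.
#' @return A list: `oscillatory`, `t_start`, `t_end` (s; `NA` when
#'   non-oscillatory), `noise_sd` (a.u.), `n_peaks`.
#' @export
select_oscillating_window <- function(trace, nominal_period = 26) {
  stopifnot(inherits(trace, "nadh_trace"))
  rate <- .trace_rate(trace)
  tg <- attr(trace, "glucose_time")
  tk <- attr(trace, "kcn_time")
  base <- trace$time_s < tg
  if (sum(base) < 3) stop("no pre-glucose baseline to estimate noise from")
  noise_sd <- stats::sd(stats::resid(
    stats::lm(trace$intensity[base] ~ trace$time_s[base])))
  floor_sd <- max(noise_sd, 1e-12)

  post <- trace$time_s > tk
  t <- trace$time_s[post]
  x <- stats::resid(stats::lm(trace$intensity[post] ~ t))
  w_smooth <- max(3L, as.integer(round(rate * nominal_period / 10)))
  xs <- .running_mean(x, w_smooth)
  w_range <- as.integer(round(rate * 3 * nominal_period))
  rr <- .rolling_range(xs, w_range, stride = max(1L, as.integer(rate %/% 2)))
  mask <- rr >= 3 * floor_sd

  pk <- find_peaks(t, xs)
  if (length(pk)) {
    keep <- vapply(pk, function(tp) {
      i <- which.min(abs(t - tp))
      mask[i] && xs[i] > 3 * floor_sd
    }, logical(1))
    pk <- pk[keep]
  }
  # enforce a minimum peak separation of half a nominal period: smoothed
  # noise can split a single crest into several local maxima; keep the
  # highest peak of each cluster
  if (length(pk) > 1) {
    h <- vapply(pk, function(tp) xs[which.min(abs(t - tp))], numeric(1))
    acc <- numeric(0)
    for (i in order(-h))
      if (!length(acc) || min(abs(pk[i] - acc)) >= nominal_period / 2)
        acc <- c(acc, pk[i])
    pk <- sort(acc)
  }
  if (length(pk) < 2)
    return(list(oscillatory = FALSE, t_start = NA_real_, t_end = NA_real_,
                noise_sd = noise_sd, n_peaks = length(pk)))
  t_start <- pk[2]
  after <- t > t_start
  dead <- after & !mask
  t_end <- if (any(dead)) t[which(dead)[1]] else t[length(t)]
  # sustained oscillation means repeated cycles: the window must span at
  # least the three nominal periods the rolling-range statistic uses,
  # hold four or more peaks, and carry a dominant spectral component
  # completing two or more cycles -- the monotone induction transient
  # (spike relaxation after KCN) concentrates its power below one cycle
  # per window and is rejected here
  pk_in <- pk[pk >= t_start & pk <= t_end]
  sustained <- t_end - t_start >= 3 * nominal_period &&
    length(pk_in) >= 4
  if (sustained) {
    d <- detrend_window(trace, c(t_start, t_end))
    f0 <- tryCatch(dominant_frequency(dft(d$values, dt = 1 / rate)),
                   error = function(e) NA_real_)
    sustained <- is.finite(f0) && f0 * (t_end - t_start) >= 2
  }
  if (!sustained)
    return(list(oscillatory = FALSE, t_start = NA_real_, t_end = NA_real_,
                noise_sd = noise_sd, n_peaks = length(pk)))
  list(oscillatory = TRUE, t_start = t_start, t_end = t_end,
       noise_sd = noise_sd, n_peaks = length(pk_in))
}

#' Linearly detrend a trace over a window
#'
#' Removes the least-squares line from the intensity over `[t_start,
#' t_end]`, returning a zero-mean series (DC and linear drift otherwise
#' dominate the low-frequency end of the spectrum).
#'
#' @param trace an `nadh_trace`.
#' @param window numeric `c(t_start, t_end)` in seconds, within the trace.
#' @return A list with `time_s` and zero-mean `values`.
#' @export
detrend_window <- function(trace, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(sel) < 3) stop("window must contain at least 3 samples")
  t <- trace$time_s[sel]
  res <- stats::resid(stats::lm(trace$intensity[sel] ~ t))
  list(time_s = t, values = as.numeric(res))
}

#' Spectral features of an NADH fluorescence trace
#'
#' Full analysis pipeline for one trace: oscillating-window selection,
#' linear detrending, DFT and dominant-frequency extraction. The dominant
#' period is `1/frequency`; the spectral amplitude uses the one-sided
#' sinusoid-calibrated convention `2*|X_k|/N` at the dominant bin (a pure
#' on-bin sinusoid of amplitude `a` yields spectral amplitude `a`).
#' A non-oscillatory verdict from the window selection is propagated as a
#' flag, never as an error.
#'
#' @inheritParams select_oscillating_window
#' @return A `trace_features` list: `oscillatory`, `period` (s),
#'   `frequency` (Hz), `amplitude` (a.u.), `window` (s), `noise_sd`,
#'   `strain`, `replicate`.
#' @examples
#' tr <- generate_trace(trace_preset("by4743"), seed = 1)
#' trace_features(tr)
#' @export
trace_features <- function(trace, nominal_period = 26) {
  win <- select_oscillating_window(trace, nominal_period)
  feat <- list(oscillatory = win$oscillatory, period = NA_real_,
               frequency = NA_real_, amplitude = NA_real_,
               window = c(win$t_start, win$t_end),
               noise_sd = win$noise_sd,
               strain = attr(trace, "strain"),
               replicate = attr(trace, "replicate"))
  if (win$oscillatory) {
    d <- detrend_window(trace, c(win$t_start, win$t_end))
    spec <- dft(d$values, dt = 1 / .trace_rate(trace))
    f <- dominant_frequency(spec)
    k_star <- which.min(abs(spec$freq - f))
    feat$frequency <- f
    feat$period <- 1 / f
    feat$amplitude <- 2 * Mod(spec$coef[k_star]) / spec$N
  }
  structure(feat, class = "trace_features")
}

#' @export
print.trace_features <- function(x, ...) {
  if (x$oscillatory)
    cat(sprintf(
      "Trace features%s: period %.2f s (%.4g Hz), amplitude %.3g a.u., window [%.1f, %.1f] s\n",
      if (is.na(x$strain)) "" else paste0(" [", x$strain, "]"),
      x$period, x$frequency, x$amplitude, x$window[1], x$window[2]))
  else
    cat(sprintf("Trace features%s: non-oscillatory (noise SD %.3g a.u.)\n",
                if (is.na(x$strain)) "" else paste0(" [", x$strain, "]"),
                x$noise_sd))
  invisible(x)
}

#' Replicate statistics of trace features
#'
#' Sample mean and sample SD (n-1 denominator) of dominant frequency and
#' spectral amplitude across analytical replicates of one strain. With a
#' single replicate the SD is 0 by convention and flagged by `n = 1`.
#'
#' @param features a list of `trace_features` objects of the same strain.
#' @param strain strain label; defaults to the label carried by the
#'   features.
#' @return A one-row data frame: `strain`, `n`, `n_oscillatory`,
#'   `mean_frequency`, `sd_frequency`, `mean_amplitude`, `sd_amplitude`.
#' @export
replicate_summary <- function(features, strain = NULL) {
  stopifnot(length(features) >= 1)
  labs <- vapply(features, function(f) as.character(f$strain), character(1))
  if (is.null(strain)) strain <- labs[1]
  if (!all(is.na(labs) | labs == strain))
    stop("replicates from mixed strains: ",
         paste(unique(labs), collapse = ", "))
  fr <- vapply(features, function(f) f$frequency, numeric(1))
  am <- vapply(features, function(f) f$amplitude, numeric(1))
  n <- length(features)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  data.frame(strain = strain, n = n,
             n_oscillatory = sum(vapply(features, function(f)
               isTRUE(f$oscillatory), logical(1))),
             mean_frequency = mean(fr), sd_frequency = sd0(fr),
             mean_amplitude = mean(am), sd_amplitude = sd0(am))
}
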