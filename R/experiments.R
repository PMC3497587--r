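#' Scale GAPDH activity in a parameter set
#'
#' Models a change in glyceraldehyde-3-phosphate dehydrogenase activity by
#' scaling the forward (`kg1`) and/or reverse (`kg2`) rate constants of
#' the lumped GAPDH-PGK reaction; enzyme level is proportional to the
#' rate constant under mass-action kinetics. The input is not modified.
#'
#' @param params a [wolf_params()] object.
#' @param f_fwd forward scaling factor (>= 0) applied to `kg1`.
#' @param f_rev reverse scaling factor (>= 0) applied to `kg2`.
#' @return A new [wolf_params()] with `kg1` and `kg2` scaled.
#' @examples
#' scale_gapdh(wolf_params(), f_fwd = 0.5, f_rev = 1)$kg1  # 161.9
#' @export
scale_gapdh <- function(params, f_fwd = 1, f_rev = 1) {
  stopifnot(is.numeric(f_fwd), is.numeric(f_rev))
  if (f_fwd < 0 || f_rev < 0) stop("scaling factors must be >= 0")
  p <- params
  p$kg1 <- params$kg1 * f_fwd
  p$kg2 <- params$kg2 * f_rev
  validate_wolf_params(p)
  p
}

# experiment design: forward/reverse GAPDH scaling fractions
.gapdh_suite_design <- data.frame(
  label = c("WT", "ExpA", "ExpB", "ExpC", "ExpD", "ExpE"),
  f_fwd = c(1, 1, 1, 0.5, 0.5, 0.3),
  f_rev = c(1, 0.5, 0, 1, 0.5, 1))

#' GAPDH activity-scaling experiment suite
#'
#' Runs the six-member in-silico GAPDH titration: wild type plus five
#' experiments scaling the forward/reverse GAPDH rate constants to
#' 100/50, 100/0, 50/100, 50/50 and 30/100 percent. Each member is
#' integrated for `t_end` minutes and the NADH limit-cycle amplitude and
#' period are extracted with the calibrated feature settings. The
#' 30%-forward member sits close to the Hopf bifurcation
#' (near-oscillation-death); its features are measured over the final
#' third of the integration, and if fewer than `min_peaks` peaks remain
#' its period is estimated spectrally and flagged.
#'
#' @param params reference [wolf_params()].
#' @param t_end integration horizon, minutes.
#' @param discard transient discard for the non-critical members, minutes.
#' @param dt_out output grid, minutes.
#' @param species species whose features are reported (NADH by default).
#' @param min_peaks minimum peak count for the peak-based period.
#' @param ... further arguments to [simulate_wolf()].
#' @return Data frame with one row per member: `label`, `f_fwd`, `f_rev`,
#'   `amplitude` (mM), `period_s`, `oscillatory`, `period_method`
#'   (`"peaks"` or `"spectral"`).
#' @examples
#' \donttest{
#' run_gapdh_suite(wolf_params())
#' }
#' @export
run_gapdh_suite <- function(params = wolf_params(), t_end = 30,
                            discard = 10, dt_out = 0.001, species = "N2",
                            min_peaks = 4, ...) {
  design <- .gapdh_suite_design
  rows <- lapply(seq_len(nrow(design)), function(i) {
    p <- scale_gapdh(params, design$f_fwd[i], design$f_rev[i])
    traj <- simulate_wolf(p, t_end = t_end, dt_out = dt_out, ...)
    # near-death member: measure over the final third only
    disc <- if (design$label[i] == "ExpE") t_end * 2 / 3 else discard
    f <- oscillation_features(traj, species, discard = disc,
                              min_peaks = min_peaks)
    period <- f$period
    method <- "peaks"
    if (!f$oscillatory && f$amplitude > 0 && f$n_peaks < min_peaks) {
      # too few peaks for interval regression: spectral fallback
      w <- steady_window(traj, disc)
      x <- stats::resid(stats::lm(w[[species]] ~ w$time_min))
      spec <- dft(x, dt = dt_out * 60)
      period <- tryCatch(1 / dominant_frequency(spec),
                         error = function(e) NA_real_)
      method <- "spectral"
    }
    data.frame(label = design$label[i], f_fwd = design$f_fwd[i],
               f_rev = design$f_rev[i], amplitude = f$amplitude,
               period_s = period, oscillatory = f$oscillatory,
               period_method = method)
  })
  do.call(rbind, rows)
}

#' Paired perturbation scans of a sensitive and an insensitive parameter
#'
#' Runs the 0-10% incremental perturbation scan for a pair of parameters
#' (by default the HK-PFK ATP-inhibition constant `r1ki1`, the most
#' sensitive parameter, and the glycerol-branch constant `r8k`, one of the
#' least sensitive) and returns the two scan tables stacked, ready for an
#' overlay plot of period against increment.
#'
#' @inheritParams perturbation_scan
#' @param param_ids the two (or more) parameters to scan.
#' @param max,step scan range: increments `seq(0, max, by = step)`.
#' @return Data frame as [perturbation_scan()], rows for all parameters.
#' @examples
#' \donttest{
#' scans <- run_scan_pair(wolf_params())
#' tapply(scans$period_s, scans$parameter, function(p) diff(range(p)))
#' }
#' @export
run_scan_pair <- function(params = wolf_params(),
                          param_ids = c("r1ki1", "r8k"),
                          max = 0.10, step = 0.01, species = "N2",
                          t_end = 20, discard = 10, dt_out = 0.001, ...) {
  increments <- seq(0, max, by = step)
  do.call(rbind, lapply(param_ids, function(id)
    perturbation_scan(params, id, increments = increments,
                      species = species, t_end = t_end, discard = discard,
                      dt_out = dt_out, ...)))
}
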