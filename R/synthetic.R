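#' Phenotype of a synthetic NADH trace
#'
#' Ground-truth description of the oscillation phenotype a synthetic
#' trace should display: whether it oscillates, at what period and
#' relative amplitude, for how long, and whether the post-glucose NADH
#' spike and the post-glucose drop are present.
#'
#' @param label strain-like label.
#' @param oscillatory logical flag.
#' @param period oscillation period, s (required when oscillatory).
#' @param amplitude_frac oscillation amplitude as a fraction of the
#'   baseline intensity.
#' @param duration_min duration of sustained oscillation, minutes (the
#'   envelope plateau; may exceed the trace length).
#' @param spike post-glucose NADH spike present.
#' @param drop post-glucose NADH drop present.
#' @return A `trace_phenotype` list.
#' @export
trace_phenotype <- function(label, oscillatory, period = NA_real_,
                            amplitude_frac = 0, duration_min = 0,
                            spike = TRUE, drop = FALSE) {
  if (oscillatory &&
      !(isTRUE(period > 0) && amplitude_frac > 0 && duration_min > 0))
    stop("an oscillatory phenotype needs period > 0, amplitude_frac > 0 ",
         "and duration_min > 0")
  structure(list(label = label, oscillatory = oscillatory, period = period,
                 amplitude_frac = amplitude_frac,
                 duration_min = duration_min, spike = spike, drop = drop),
            class = "trace_phenotype")
}

#' Full specification of a synthetic NADH trace
#'
#' Collects the phenotype and all shape parameters of the deterministic
#' signal model plus the noise level. The deterministic signal is
#' \deqn{I(t) = baseline + drift t + spike e^{-(t-t_g)/relax}
#'   - drop(1 - e^{-(t-t_g)/relax}) + env(t) A \sin(2\pi (t-t_k-onset)/P)
#' }{I(t) = baseline + drift*t + spike-term - drop-term + env(t)*A*sin(...)}
#' with the spike/drop terms active after glucose addition, the
#' oscillation active after `kcn_time + onset_delay`, and `env` a plateau
#' of the phenotype's duration followed by an exponential taper. Gaussian
#' measurement noise of SD `noise_sd` is added on top.
#'
#' @param phenotype a [trace_phenotype()].
#' @param baseline baseline intensity, a.u. (default keeps presets within
#'   the protocol's 10-30 a.u. band).
#' @param spike_height,spike_relax post-glucose spike height (a.u.) and
#'   relaxation time (s).
#' @param drop_depth depth of the post-glucose drop, a.u.
#' @param onset_delay oscillation onset delay after KCN, s.
#' @param taper_time exponential envelope taper time constant, s.
#' @param noise_sd Gaussian measurement noise SD, a.u.
#' @param drift_slope linear intensity drift, a.u./s.
#' @param duration trace duration, s (default 1320 s = 22 min).
#' @param rate sampling rate, Hz (default 10).
#' @param glucose_time,kcn_time event times, s (protocol defaults 60/140).
#' @param seed default RNG seed used by [generate_trace()].
#' @return A `synthetic_trace_spec` list.
#' @export
synthetic_trace_spec <- function(phenotype, baseline = 18,
                                 spike_height = 6, spike_relax = 30,
                                 drop_depth = 4, onset_delay = 30,
                                 taper_time = 60, noise_sd = 0.05,
                                 drift_slope = -5e-4, duration = 1320,
                                 rate = 10, glucose_time = 60,
                                 kcn_time = 140, seed = 1L) {
  stopifnot(inherits(phenotype, "trace_phenotype"))
  if (duration <= kcn_time) stop("duration must exceed kcn_time")
  if (rate <= 0) stop("sample rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(phenotype = phenotype, baseline = baseline,
                 spike_height = spike_height, spike_relax = spike_relax,
                 drop_depth = drop_depth, onset_delay = onset_delay,
                 taper_time = taper_time, noise_sd = noise_sd,
                 drift_slope = drift_slope, duration = duration,
                 rate = rate, glucose_time = glucose_time,
                 kcn_time = kcn_time, seed = as.integer(seed)),
            class = "synthetic_trace_spec")
}

# preset table: oscillation phenotypes per strain.
# Wild-type periods are the published values (26.05 s BY4743, 27.67 s
# X2180). Mutant amplitudes/durations encode the reported qualitative
# ordering only: hxk2 < hxk1 < WT in amplitude, hxk2 longest-lasting and
# slowest; pfk1/tdh1/tdh2 near-wild-type; pfk2, tdh3, pde2, ira2
# non-oscillatory, pfk2 additionally spike-less with a post-glucose drop.
.trace_presets <- list(
  by4743 = list(TRUE,  26.05, 0.12, 17,  TRUE,  FALSE),
  x2180  = list(TRUE,  27.67, 0.12, 17,  TRUE,  FALSE),
  hxk1   = list(TRUE,  26.05, 0.06, 25,  TRUE,  FALSE),
  hxk2   = list(TRUE,  30.00, 0.03, 35,  TRUE,  FALSE),
  pfk1   = list(TRUE,  25.50, 0.10, 17,  TRUE,  FALSE),
  tdh1   = list(TRUE,  26.05, 0.12, 17,  TRUE,  FALSE),
  tdh2   = list(TRUE,  26.05, 0.11, 17,  TRUE,  FALSE),
  pfk2   = list(FALSE, NA,    0,    0,   FALSE, TRUE),
  tdh3   = list(FALSE, NA,    0,    0,   TRUE,  FALSE),
  pde2   = list(FALSE, NA,    0,    0,   TRUE,  FALSE),
  ira2   = list(FALSE, NA,    0,    0,   TRUE,  FALSE))

#' Strain-phenotype presets for the synthetic trace generator
#'
#' Returns a ready-to-use [synthetic_trace_spec()] for one of the
#' documented strain presets: the wild types `by4743` (period 26.05 s)
#' and `x2180` (27.67 s); the reduced-amplitude, longer-lasting
#' hexokinase deletions `hxk1` and `hxk2` (hxk2 more extreme and slower);
#' the near-wild-type `pfk1`, `tdh1`, `tdh2`; and the non-oscillatory
#' `pfk2` (no post-glucose spike, with a post-glucose drop), `tdh3`,
#' `pde2` and `ira2`. Mutant amplitude/duration values encode the
#' reported qualitative ordering, not measured quantities.
#'
#' @param label one of the preset names (see Details).
#' @param noise_frac Gaussian noise SD as a fraction of the wild-type
#'   oscillation amplitude in a.u. (default 0.02).
#' @param ... overrides passed on to [synthetic_trace_spec()].
#' @return A `synthetic_trace_spec`.
#' @examples
#' trace_preset("by4743")$phenotype$period  # 26.05
#' @export
trace_preset <- function(label, noise_frac = 0.02, ...) {
  if (!label %in% names(.trace_presets))
    stop("unknown preset '", label, "'; available: ",
         paste(names(.trace_presets), collapse = ", "))
  pr <- .trace_presets[[label]]
  ph <- trace_phenotype(label, oscillatory = pr[[1]], period = pr[[2]],
                        amplitude_frac = pr[[3]], duration_min = pr[[4]],
                        spike = pr[[5]], drop = pr[[6]])
  baseline <- 18
  wt_amp <- 0.12 * baseline
  synthetic_trace_spec(ph, baseline = baseline,
                       spike_height = if (ph$spike) 6 else 0,
                       drop_depth = if (ph$drop) 4 else 0,
                       noise_sd = noise_frac * wt_amp, ...)
}

# deterministic (noise-free) signal of a spec on a time grid
.trace_signal <- function(spec, t) {
  ph <- spec$phenotype
  I <- spec$baseline + spec$drift_slope * t
  g <- t >= spec$glucose_time
  if (spec$spike_height > 0)
    I[g] <- I[g] + spec$spike_height *
      exp(-(t[g] - spec$glucose_time) / spec$spike_relax)
  if (spec$drop_depth > 0)
    I[g] <- I[g] - spec$drop_depth *
      (1 - exp(-(t[g] - spec$glucose_time) / spec$spike_relax))
  if (ph$oscillatory) {
    t0 <- spec$kcn_time + spec$onset_delay
    plateau_end <- t0 + ph$duration_min * 60
    osc <- t >= t0
    env <- ifelse(t <= plateau_end, 1,
                  exp(-(t - plateau_end) / spec$taper_time))
    A <- ph$amplitude_frac * spec$baseline
    I[osc] <- I[osc] + (env * A * sin(2 * pi * (t - t0) / ph$period))[osc]
  }
  I
}

#' Generate a synthetic NADH fluorescence trace
#'
#' Evaluates the deterministic signal model of a [synthetic_trace_spec()]
#' on the uniform sampling grid and adds Gaussian measurement noise. The
#' trace is deterministic given the spec and seed. The generator's ground
#' truth (period, amplitude in a.u., oscillation window) is attached as
#' attribute `"ground_truth"`.
#'
#' @param spec a `synthetic_trace_spec`.
#' @param seed RNG seed; defaults to the spec's own seed.
#' @param replicate replicate id stored in the trace metadata.
#' @return An [nadh_trace()] with ground-truth attribute.
#' @examples
#' tr <- generate_trace(trace_preset("by4743"), seed = 7)
#' range(tr$intensity)  # within the 10-30 a.u. band
#' @export
generate_trace <- function(spec, seed = spec$seed, replicate = 1L) {
  stopifnot(inherits(spec, "synthetic_trace_spec"))
  t <- seq(0, spec$duration, by = 1 / spec$rate)
  I <- .trace_signal(spec, t)
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    I <- I + stats::rnorm(length(I), sd = spec$noise_sd)
  }
  tr <- nadh_trace(t, I, glucose_time = spec$glucose_time,
                   kcn_time = spec$kcn_time,
                   strain = spec$phenotype$label, replicate = replicate)
  ph <- spec$phenotype
  t0 <- spec$kcn_time + spec$onset_delay
  attr(tr, "ground_truth") <- list(
    oscillatory = ph$oscillatory, period = ph$period,
    amplitude_au = ph$amplitude_frac * spec$baseline,
    t_onset = if (ph$oscillatory) t0 else NA_real_,
    t_plateau_end = if (ph$oscillatory)
      min(t0 + ph$duration_min * 60, spec$duration) else NA_real_,
    seed = seed)
  tr
}

#' Generate a cohort of synthetic traces with a manifest
#'
#' Generates `n_replicates` independent traces per preset label, with
#' per-trace sub-seeds derived deterministically from the master seed,
#' and a manifest of the ground truth. Optionally writes each trace (CSV
#' plus metadata sidecar) and the manifest to a directory.
#'
#' @param labels preset labels (see [trace_preset()]).
#' @param n_replicates replicates per label (>= 1).
#' @param seed master seed.
#' @param noise_frac noise level passed to [trace_preset()].
#' @param dir optional output directory for `trace_<label>_<rep>.csv`
#'   files and `manifest.csv`.
#' @param ... overrides passed to [trace_preset()].
#' @return A list with `traces` (list of [nadh_trace()]) and `manifest`
#'   (data frame: label, replicate, seed, oscillatory, period,
#'   amplitude_au, file).
#' @examples
#' coh <- generate_cohort(c("by4743", "pfk2"), n_replicates = 2, seed = 1)
#' coh$manifest
#' @export
generate_cohort <- function(labels, n_replicates = 3, seed = 1,
                            noise_frac = 0.02, dir = NULL, ...) {
  stopifnot(n_replicates >= 1)
  n <- length(labels) * n_replicates
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  traces <- vector("list", n)
  rows <- vector("list", n)
  k <- 0L
  for (lab in labels) {
    spec <- trace_preset(lab, noise_frac = noise_frac, ...)
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      tr <- generate_trace(spec, seed = sub_seeds[k], replicate = r)
      traces[[k]] <- tr
      gt <- attr(tr, "ground_truth")
      file <- if (is.null(dir)) NA_character_ else
        sprintf("trace_%s_%d.csv", lab, r)
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        write_trace(tr, file.path(dir, file))
      }
      rows[[k]] <- data.frame(label = lab, replicate = r,
                              seed = sub_seeds[k],
                              oscillatory = gt$oscillatory,
                              period = gt$period,
                              amplitude_au = gt$amplitude_au, file = file)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(traces = traces, manifest = manifest)
}
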