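# package-internal state (simulation call counter, used to verify that
# sensitivity routines run the advertised number of integrations)
.glycosc_state <- new.env(parent = emptyenv())
.glycosc_state$n_sim <- 0L

.count_sim <- function() {
  .glycosc_state$n_sim <- .glycosc_state$n_sim + 1L
}

.sim_features <- function(params, species, t_end, discard, dt_out,
                          mode = "range", ...) {
  .count_sim()
  traj <- simulate_wolf(params, t_end = t_end, dt_out = dt_out, ...)
  out <- lapply(species, function(sp)
    oscillation_features(traj, sp, discard = discard, mode = mode))
  names(out) <- species
  out
}

.perturbed_params <- function(params, field, delta) {
  p <- params
  p[[field]] <- p[[field]] + delta
  validate_wolf_params(p)
  p
}

.feature_record <- function(quantity, symbol, species, p_ref, delta,
                            f_ref, f_pert) {
  ref <- if (quantity == "amplitude") f_ref$amplitude else f_ref$period
  pert <- if (quantity == "amplitude") f_pert$amplitude else f_pert$period
  death <- !f_ref$oscillatory || !f_pert$oscillatory
  if (death || is.na(ref) || is.na(pert) || ref == 0) {
    s_raw <- s_norm <- NA_real_
  } else {
    s_raw <- (pert - ref) / delta
    s_norm <- (p_ref / ref) * s_raw
  }
  list(parameter = symbol, species = species, quantity = quantity,
       ref = ref, pert = pert, p_ref = p_ref, delta = delta,
       s_raw = s_raw, s_norm = s_norm, oscillation_death = death)
}

#' Finite-difference sensitivity of oscillation amplitude or period
#'
#' Perturbs one parameter by a fractional step (default +1%), re-simulates
#' the model with identical solver settings and transient discard, and
#' returns the non-normalised sensitivity
#' `s = (A(p + dp) - A(p)) / dp` together with its dimensionless
#' normalisation `s_norm = (p / A(p)) * s`, for the amplitude
#' (`amplitude_sensitivity()`) or the period (`period_sensitivity()`) of
#' one species. Exactly two simulations are run. If either the reference
#' or the perturbed model has lost its limit cycle the record is flagged
#' `oscillation_death` and the sensitivities are reported as missing
#' (`NA`), not as zero.
#'
#' @param params reference [wolf_params()].
#' @param param_id parameter to perturb; a reaction-indexed symbol
#'   (`"r1ki1"`, ...) or internal field name (`"Ki"`, ...).
#' @param species state variable whose feature is measured.
#' @param delta_frac signed fractional perturbation (default `+0.01`).
#' @param t_end,discard,dt_out simulation horizon, transient discard and
#'   output grid (minutes), shared by both runs.
#' @param ... further arguments to [simulate_wolf()].
#' @return A `sensitivity_record` list: `parameter`, `species`,
#'   `quantity`, reference and perturbed feature values, `p_ref`, `delta`
#'   (absolute), `s_raw`, `s_norm`, `oscillation_death`.
#' @examples
#' \donttest{
#' amplitude_sensitivity(wolf_params(), "r1ki1", "N2")
#' }
#' @export
amplitude_sensitivity <- function(params = wolf_params(), param_id,
                                  species = "N2", delta_frac = 0.01,
                                  t_end = 20, discard = 10,
                                  dt_out = 0.001, ...) {
  .sensitivity_one("amplitude", params, param_id, species, delta_frac,
                   t_end, discard, dt_out, ...)
}

#' @rdname amplitude_sensitivity
#' @export
period_sensitivity <- function(params = wolf_params(), param_id,
                               species = "N2", delta_frac = 0.01,
                               t_end = 20, discard = 10,
                               dt_out = 0.001, ...) {
  .sensitivity_one("period", params, param_id, species, delta_frac,
                   t_end, discard, dt_out, ...)
}

.sensitivity_one <- function(quantity, params, param_id, species,
                             delta_frac, t_end, discard, dt_out, ...) {
  stopifnot(delta_frac != 0)
  field <- .resolve_param_id(param_id)
  symbol <- names(.param_symbol_map)[.param_symbol_map == field][1]
  p_ref <- params[[field]]
  delta <- p_ref * delta_frac
  if (delta == 0) stop("parameter '", symbol, "' is zero; fractional ",
                       "perturbation is degenerate")
  f_ref <- .sim_features(params, species, t_end, discard, dt_out, ...)[[1]]
  f_pert <- .sim_features(.perturbed_params(params, field, delta),
                          species, t_end, discard, dt_out, ...)[[1]]
  rec <- .feature_record(quantity, symbol, species, p_ref, delta,
                         f_ref, f_pert)
  structure(rec, class = "sensitivity_record")
}

#' @export
print.sensitivity_record <- function(x, ...) {
  cat(sprintf("%s sensitivity of %s to %s (delta = %.4g):\n",
              x$quantity, x$species, x$parameter, x$delta))
  if (x$oscillation_death)
    cat("  oscillation death under perturbation; sensitivities missing\n")
  else
    cat(sprintf("  ref %.6g -> pert %.6g; s_raw = %.6g, s_norm = %.6g\n",
                x$ref, x$pert, x$s_raw, x$s_norm))
  invisible(x)
}

#' Full normalized sensitivity table over parameters and species
#'
#' Computes amplitude and period sensitivities of every species with
#' respect to every scannable rate constant (the 15 reaction-indexed
#' parameters; optionally also `q` and `phi`), sharing one reference
#' simulation and one perturbed simulation per parameter (16 integrations
#' for the default set). Parameters are ranked by the mean across species
#' of `|s_norm|`. Per-record oscillation death is recorded and never
#' aborts the table.
#'
#' @inheritParams amplitude_sensitivity
#' @param param_ids parameters to scan (symbols or field names); default
#'   the 15 rate constants.
#' @param species species set; default all nine state variables.
#' @return A `sensitivity_table` list with elements `records` (long data
#'   frame: parameter, species, quantity, ref, pert, delta, s_raw, s_norm,
#'   oscillation_death) and `summary` (per parameter and quantity: mean
#'   and SD of `|s_norm|` across species, and rank).
#' @examples
#' \donttest{
#' st <- sensitivity_table(wolf_params())
#' head(st$summary)
#' }
#' @export
sensitivity_table <- function(params = wolf_params(), delta_frac = 0.01,
                              param_ids = names(wolf_param_symbols(TRUE)),
                              species = .species_names,
                              t_end = 20, discard = 10, dt_out = 0.001,
                              ...) {
  stopifnot(delta_frac != 0)
  f_ref <- .sim_features(params, species, t_end, discard, dt_out, ...)
  recs <- list()
  for (id in param_ids) {
    field <- .resolve_param_id(id)
    symbol <- names(.param_symbol_map)[.param_symbol_map == field][1]
    p_ref <- params[[field]]
    delta <- p_ref * delta_frac
    f_pert <- tryCatch(
      .sim_features(.perturbed_params(params, field, delta), species,
                    t_end, discard, dt_out, ...),
      error = function(e) NULL)
    for (sp in species) {
      for (qty in c("amplitude", "period")) {
        rec <- if (is.null(f_pert)) {
          list(parameter = symbol, species = sp, quantity = qty,
               ref = NA_real_, pert = NA_real_, p_ref = p_ref,
               delta = delta, s_raw = NA_real_, s_norm = NA_real_,
               oscillation_death = TRUE)
        } else {
          .feature_record(qty, symbol, sp, p_ref, delta,
                          f_ref[[sp]], f_pert[[sp]])
        }
        recs[[length(recs) + 1L]] <- rec
      }
    }
  }
  records <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  summary <- do.call(rbind, lapply(split(
    records, list(records$parameter, records$quantity), drop = TRUE),
    function(d) data.frame(
      parameter = d$parameter[1], quantity = d$quantity[1],
      mean_abs_s_norm = mean(abs(d$s_norm), na.rm = TRUE),
      sd_abs_s_norm = stats::sd(abs(d$s_norm), na.rm = TRUE),
      n_death = sum(d$oscillation_death))))
  summary <- summary[order(summary$quantity,
                           -summary$mean_abs_s_norm), ]
  summary$rank <- stats::ave(-summary$mean_abs_s_norm, summary$quantity,
                             FUN = rank)
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary,
                 delta_frac = delta_frac),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("Normalized sensitivity table (delta_frac = %g)\n",
              x$delta_frac))
  amp <- x$summary[x$summary$quantity == "amplitude", ]
  cat("Amplitude ranking (mean |s_norm| across species):\n")
  print(amp[, c("parameter", "mean_abs_s_norm", "sd_abs_s_norm", "rank")],
        row.names = FALSE)
  invisible(x)
}

#' Incremental perturbation scan of one parameter
#'
#' Scales one parameter through a sequence of fractional increments
#' (default 0% to +10% in 1% steps, the 0% reference included) and
#' records the oscillation features of one species at each value.
#' Oscillation death at an increment is recorded and the scan continues.
#'
#' @inheritParams amplitude_sensitivity
#' @param increments fractional increments (may be signed); 0 gives the
#'   reference row.
#' @return Data frame: `parameter`, `increment`, `value` (the scaled
#'   parameter), `amplitude`, `period_s`, `oscillatory`, `n_peaks`.
#' @examples
#' \donttest{
#' perturbation_scan(wolf_params(), "r8k", increments = c(0, 0.05, 0.10))
#' }
#' @export
perturbation_scan <- function(params = wolf_params(), param_id,
                              increments = seq(0, 0.10, by = 0.01),
                              species = "N2", t_end = 20, discard = 10,
                              dt_out = 0.001, ...) {
  stopifnot(all(is.finite(increments)))
  field <- .resolve_param_id(param_id)
  symbol <- names(.param_symbol_map)[.param_symbol_map == field][1]
  rows <- lapply(increments, function(inc) {
    p <- params
    p[[field]] <- params[[field]] * (1 + inc)
    f <- .sim_features(p, species, t_end, discard, dt_out, ...)[[1]]
    data.frame(parameter = symbol, increment = inc, value = p[[field]],
               amplitude = f$amplitude, period_s = f$period,
               oscillatory = f$oscillatory, n_peaks = f$n_peaks)
  })
  do.call(rbind, rows)
}
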