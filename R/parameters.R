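#' Kinetic parameters of the Wolf glycolysis model
#'
#' Constructs the parameter set of the nine-state Wolf model of anaerobic
#' yeast glycolysis. Defaults are the published rate constants of the model
#' together with the standard reference conditions: glucose influx
#' `J0 = 50` mM/min, a combined NAD+/NADH pool of 1.00 mM and a combined
#' ADP/ATP pool of 4.00 mM. The ATP-inhibition cooperativity `q = 4` and the
#' intracellular-to-extracellular volume ratio `phi = 0.1` come from the
#' original model formulation.
#'
#' Internal field names map to the conventional reaction-indexed symbols of
#' the published model as follows: `k1` = r1k1, `Ki` = r1ki1, `k2` = r2k,
#' `kg1` = r3k1, `kg2` = r3k2, `kp1` = r3k3, `kp2` = r3k4, `k4` = r4k,
#' `k5` = r5k, `k6` = r6k, `k7` = r7k, `k8` = r8k, `k9` = r9k, `J0` = r11v,
#' `kappa` = jKappa. Config files use the reaction-indexed symbols (see
#' [read_wolf_params()]).
#'
#' @param k1 HK-PFK rate constant, mM^-1 min^-1.
#' @param Ki HK-PFK ATP-inhibition constant, mM.
#' @param q ATP-inhibition cooperativity exponent (dimensionless).
#' @param k2 aldolase rate constant, min^-1.
#' @param kg1,kg2 GAPDH forward/reverse rate constants, mM^-1 min^-1.
#' @param kp1,kp2 PGK forward/reverse rate constants, mM^-1 min^-1.
#' @param k4 lumped PK rate constant, mM^-1 min^-1.
#' @param k5 PDC rate constant, min^-1 (first-order decarboxylation).
#' @param k6 ADH rate constant, mM^-1 min^-1.
#' @param k7 ATPase rate constant, min^-1.
#' @param k8 glycerol-branch rate constant, mM^-1 min^-1.
#' @param k9 extracellular acetaldehyde degradation (CYA) rate constant,
#'   min^-1.
#' @param J0 glucose influx, mM min^-1.
#' @param kappa acetaldehyde exchange rate constant, min^-1.
#' @param phi intracellular-to-extracellular volume ratio (0 < phi <= 1).
#' @param Ntot total NAD+ + NADH pool, mM.
#' @param Atot total ADP + ATP pool, mM.
#'
#' @return An object of class `wolf_params`: a named list of the 19 fields.
#' @examples
#' p <- wolf_params()
#' p$Ki
#' @export
wolf_params <- function(k1 = 550, Ki = 1, q = 4, k2 = 9.8,
                        kg1 = 323.8, kg2 = 57823.1,
                        kp1 = 76411.1, kp2 = 23.7,
                        k4 = 80, k5 = 9.7, k6 = 2000, k7 = 28,
                        k8 = 85.7, k9 = 80, J0 = 50, kappa = 375,
                        phi = 0.1, Ntot = 1, Atot = 4) {
  p <- list(k1 = k1, Ki = Ki, q = q, k2 = k2, kg1 = kg1, kg2 = kg2,
            kp1 = kp1, kp2 = kp2, k4 = k4, k5 = k5, k6 = k6, k7 = k7,
            k8 = k8, k9 = k9, J0 = J0, kappa = kappa, phi = phi,
            Ntot = Ntot, Atot = Atot)
  p <- lapply(p, as.numeric)
  class(p) <- "wolf_params"
  validate_wolf_params(p)
  p
}

#' Validate a Wolf parameter set
#'
#' Checks the parameter invariants: all rate constants finite and
#' non-negative, `Ki > 0`, `q >= 1`, `0 < phi <= 1`, positive pools.
#'
#' @param p a [wolf_params()] object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_wolf_params <- function(p) {
  stopifnot(inherits(p, "wolf_params"))
  v <- unlist(p)
  if (!all(is.finite(v)))
    stop("non-finite parameter value: ",
         paste(names(v)[!is.finite(v)], collapse = ", "))
  rate <- c("k1", "k2", "kg1", "kg2", "kp1", "kp2", "k4", "k5", "k6",
            "k7", "k8", "k9", "J0", "kappa")
  if (any(v[rate] < 0))
    stop("negative rate constant: ",
         paste(rate[v[rate] < 0], collapse = ", "))
  if (p$Ki <= 0) stop("Ki must be > 0")
  if (p$q < 1) stop("q must be >= 1")
  if (p$phi <= 0 || p$phi > 1) stop("phi must be in (0, 1]")
  if (p$Ntot <= 0) stop("Ntot must be > 0")
  if (p$Atot <= 0) stop("Atot must be > 0")
  invisible(p)
}

#' @export
print.wolf_params <- function(x, ...) {
  cat("Wolf glycolysis model parameters\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 6), " = ", format(v)),
      sep = "\n")
  invisible(x)
}

# reaction-indexed config symbol <-> internal field name
.param_symbol_map <- c(r1k1 = "k1", r1ki1 = "Ki", r2k = "k2",
                       r3k1 = "kg1", r3k2 = "kg2", r3k3 = "kp1",
                       r3k4 = "kp2", r4k = "k4", r5k = "k5", r6k = "k6",
                       r7k = "k7", r8k = "k8", r9k = "k9", r11v = "J0",
                       jKappa = "kappa", q = "q", phi = "phi",
                       Ntot = "Ntot", Atot = "Atot")

#' Parameter symbols of the Wolf model
#'
#' The reaction-indexed symbols under which the 15 rate constants (plus
#' `q`, `phi` and the two pools) are written in config files, and their
#' mapping onto the internal [wolf_params()] field names.
#'
#' @param scannable if `TRUE`, return only the 15 rate-constant symbols
#'   scanned by the sensitivity analysis (pools, `q` and `phi` excluded).
#' @return A named character vector, names are config symbols and values
#'   the internal field names.
#' @export
wolf_param_symbols <- function(scannable = FALSE) {
  if (scannable)
    .param_symbol_map[!.param_symbol_map %in% c("q", "phi", "Ntot", "Atot")]
  else
    .param_symbol_map
}

# resolve a parameter id given as config symbol or internal field name
.resolve_param_id <- function(id) {
  if (id %in% names(.param_symbol_map)) return(unname(.param_symbol_map[id]))
  if (id %in% .param_symbol_map) return(id)
  stop("unknown parameter id '", id, "'; use one of: ",
       paste(names(.param_symbol_map), collapse = ", "))
}

#' Read / write Wolf model parameters as a flat config file
#'
#' Parameters are serialized as a flat key/value mapping keyed by the
#' reaction-indexed symbols (`r1k1`, `r1ki1`, ..., `r11v`, `jKappa`) plus
#' `q`, `phi`, `Ntot`, `Atot`. JSON is read with \pkg{jsonlite}; files
#' ending in `.yml`/`.yaml` are read with \pkg{yaml} if available.
#'
#' @param path file path.
#' @param p a [wolf_params()] object (for writing).
#' @return `read_wolf_params()` returns a [wolf_params()] object;
#'   `write_wolf_params()` returns `path` invisibly.
#' @export
read_wolf_params <- function(path) {
  is_yaml <- grepl("\\.ya?ml$", path, ignore.case = TRUE)
  vals <- if (is_yaml) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML config requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals <- unlist(vals)
  unknown <- setdiff(names(vals), names(.param_symbol_map))
  if (length(unknown))
    stop("unknown parameter key(s) in config: ",
         paste(unknown, collapse = ", "))
  p <- wolf_params()
  p[.param_symbol_map[names(vals)]] <- as.numeric(vals)
  class(p) <- "wolf_params"
  validate_wolf_params(p)
  p
}

#' @rdname read_wolf_params
#' @export
write_wolf_params <- function(p, path) {
  validate_wolf_params(p)
  inv <- stats::setNames(names(.param_symbol_map), .param_symbol_map)
  out <- as.list(stats::setNames(unlist(p), inv[names(p)]))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML config requires the 'yaml' package")
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
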