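#' State vector of the Wolf glycolysis model
#'
#' Builds and validates the nine-species state of the model. Species
#' (all mM): `S1` glucose, `S2` fructose-1,6-bisphosphate, `S3` the triose
#' phosphate pool (GAP + DHAP), `S4` the 3-phosphoglycerate pool, `S5`
#' pyruvate, `S6` intracellular acetaldehyde, `S6x` extracellular
#' acetaldehyde, `N2` NADH and `A3` ATP. NAD+ and ADP are implicit as
#' `Ntot - N2` and `Atot - A3`.
#'
#' @param S1,S2,S3,S4,S5,S6,S6x,N2,A3 species concentrations, mM.
#' @param params a [wolf_params()] object used to check the pool bounds
#'   `N2 <= Ntot`, `A3 <= Atot`.
#' @return A named numeric vector of length 9 in canonical order.
#' @export
wolf_state <- function(S1, S2, S3, S4, S5, S6, S6x, N2, A3,
                       params = wolf_params()) {
  s <- c(S1 = S1, S2 = S2, S3 = S3, S4 = S4, S5 = S5, S6 = S6,
         S6x = S6x, N2 = N2, A3 = A3)
  if (!all(is.finite(s))) stop("non-finite state value")
  if (any(s < 0))
    stop("negative concentration: ", paste(names(s)[s < 0], collapse = ", "))
  if (N2 > params$Ntot) stop("N2 exceeds the NAD pool Ntot")
  if (A3 > params$Atot) stop("A3 exceeds the adenine pool Atot")
  s
}

.species_names <- c("S1", "S2", "S3", "S4", "S5", "S6", "S6x", "N2", "A3")

#' Default initial state for model integration
#'
#' A fixed, strictly positive state near the oscillatory attractor. The
#' model's reported features are computed on the limit cycle after
#' transient discard, so the precise choice is immaterial; it is fixed
#' here for reproducibility.
#'
#' @param params a [wolf_params()] object (pool bounds).
#' @return A named numeric state vector (see [wolf_state()]).
#' @export
default_initial_state <- function(params = wolf_params()) {
  wolf_state(S1 = 1.1, S2 = 5.1, S3 = 0.55, S4 = 0.67, S5 = 8.3,
             S6 = 0.08, S6x = 0.02, N2 = 0.41, A3 = 2.4, params = params)
}

#' Reaction rates of the Wolf model
#'
#' Evaluates the ten fluxes (mM/min) at a given state:
#' \describe{
#'   \item{v1}{lumped HK-PFK, `k1*S1*A3 / (1 + (A3/Ki)^q)` (allosteric ATP
#'     inhibition with cooperativity `q`)}
#'   \item{v2}{aldolase, `k2*S2`}
#'   \item{v3}{lumped GAPDH-PGK (reversible, quasi-steady-state elimination
#'     of 1,3-bisphosphoglycerate):
#'     `(kg1*kp1*S3*(Ntot-N2)*(Atot-A3) - kg2*kp2*S4*N2*A3) /
#'      (kg2*N2 + kp1*(Atot-A3))`}
#'   \item{v4}{lumped PGM-ENO-PK, `k4*S4*(Atot-A3)`}
#'   \item{v5}{PDC, `k5*S5`}
#'   \item{v6}{ADH, `k6*S6*N2`}
#'   \item{v7}{ATPase, `k7*A3`}
#'   \item{v8}{glycerol branch, `k8*S3*N2`}
#'   \item{v9}{extracellular acetaldehyde degradation (CYA), `k9*S6x`}
#'   \item{Jex}{acetaldehyde exchange, `kappa*(S6 - S6x)`}
#' }
#' `v3` and `Jex` may be negative (reversible reaction / exchange flux);
#' all other fluxes are non-negative for any valid state.
#'
#' @param state a named state vector (see [wolf_state()]).
#' @param params a [wolf_params()] object.
#' @return Named numeric vector `v1..v9`, `Jex`.
#' @examples
#' reaction_rates(default_initial_state(), wolf_params())
#' @export
reaction_rates <- function(state, params = wolf_params()) {
  s <- state[.species_names]
  if (anyNA(s) || !all(is.finite(s)))
    stop("state must contain finite values for all nine species")
  p <- params
  N1 <- p$Ntot - s[["N2"]]  # NAD+
  A2 <- p$Atot - s[["A3"]]  # ADP
  den <- p$kg2 * s[["N2"]] + p$kp1 * A2
  if (den <= 0)
    stop("degenerate state: GAPDH-PGK denominator is zero ",
         "(no NADH and a fully phosphorylated adenine pool, ",
         "N2 = 0 and A3 = Atot simultaneously)")
  c(v1 = p$k1 * s[["S1"]] * s[["A3"]] / (1 + (s[["A3"]] / p$Ki)^p$q),
    v2 = p$k2 * s[["S2"]],
    v3 = (p$kg1 * p$kp1 * s[["S3"]] * N1 * A2 -
            p$kg2 * p$kp2 * s[["S4"]] * s[["N2"]] * s[["A3"]]) / den,
    v4 = p$k4 * s[["S4"]] * A2,
    v5 = p$k5 * s[["S5"]],
    v6 = p$k6 * s[["S6"]] * s[["N2"]],
    v7 = p$k7 * s[["A3"]],
    v8 = p$k8 * s[["S3"]] * s[["N2"]],
    v9 = p$k9 * s[["S6x"]],
    Jex = p$kappa * (s[["S6"]] - s[["S6x"]]))
}

#' Time derivatives of the Wolf model state
#'
#' Assembles the stoichiometric combination of the reaction rates:
#' `dS1 = J0 - v1`, `dS2 = v1 - v2`, `dS3 = 2*v2 - v3 - v8`,
#' `dS4 = v3 - v4`, `dS5 = v4 - v5`, `dS6 = v5 - v6 - Jex`,
#' `dS6x = phi*Jex - v9`, `dN2 = v3 - v6 - v8`,
#' `dA3 = -2*v1 + v3 + v4 - v7`.
#'
#' @inheritParams reaction_rates
#' @return Named numeric vector of the nine derivatives, mM/min.
#' @export
wolf_derivatives <- function(state, params = wolf_params()) {
  v <- reaction_rates(state, params)
  c(S1 = params$J0 - v[["v1"]],
    S2 = v[["v1"]] - v[["v2"]],
    S3 = 2 * v[["v2"]] - v[["v3"]] - v[["v8"]],
    S4 = v[["v3"]] - v[["v4"]],
    S5 = v[["v4"]] - v[["v5"]],
    S6 = v[["v5"]] - v[["v6"]] - v[["Jex"]],
    S6x = params$phi * v[["Jex"]] - v[["v9"]],
    N2 = v[["v3"]] - v[["v6"]] - v[["v8"]],
    A3 = -2 * v[["v1"]] + v[["v3"]] + v[["v4"]] - v[["v7"]])
}

#' Integrate the Wolf model
#'
#' Integrates the nine-state ODE system with a stiff-capable solver
#' (\pkg{deSolve} `lsoda`) on a uniform output grid. Model time is in
#' minutes throughout (the rate constants are per minute); reported
#' periods elsewhere in the package are converted to seconds.
#'
#' @param params a [wolf_params()] object.
#' @param init initial state, default [default_initial_state()].
#' @param t_end integration horizon, minutes (> 0).
#' @param dt_out output grid spacing, minutes (default 0.001, fine enough
#'   for sub-second peak interpolation).
#' @param rtol,atol solver relative/absolute tolerances.
#' @param method \pkg{deSolve} integration method.
#' @return A `wolf_trajectory`: a data frame with column `time_min` and
#'   one column per species, with the parameters attached as attribute
#'   `"params"`.
#' @examples
#' \donttest{
#' traj <- simulate_wolf(wolf_params(), t_end = 5)
#' head(traj)
#' }
#' @export
simulate_wolf <- function(params = wolf_params(),
                          init = default_initial_state(params),
                          t_end = 30, dt_out = 0.001,
                          rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  validate_wolf_params(params)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0")
  if (!is.numeric(dt_out) || dt_out <= 0) stop("dt_out must be > 0")
  init <- init[.species_names]
  if (anyNA(init)) stop("init must name all nine species")
  times <- seq(0, t_end, by = dt_out)
  rhs <- function(t, y, p) list(wolf_derivatives_fast(y, p))
  out <- deSolve::ode(y = init, times = times, func = rhs, parms = params,
                      method = method, rtol = rtol, atol = atol)
  if (nrow(out) < length(times)) {
    stop(sprintf("ODE solver failed near t = %.4f min (step-size collapse)",
                 out[nrow(out), 1]))
  }
  traj <- as.data.frame(out)
  names(traj)[1] <- "time_min"
  # solver round-off tolerance on non-negativity and pool bounds
  tol <- 1e-6
  sp <- as.matrix(traj[, .species_names])
  if (min(sp) < -tol || max(traj$N2) > params$Ntot + tol ||
      max(traj$A3) > params$Atot + tol)
    stop("trajectory violates non-negativity or pool bounds beyond 1e-6 mM")
  attr(traj, "params") <- params
  class(traj) <- c("wolf_trajectory", "data.frame")
  traj
}

# vectorised internal rhs; same formulas as wolf_derivatives() but without
# per-call validation (the solver calls it millions of times)
wolf_derivatives_fast <- function(y, p) {
  S1 <- y[[1]]; S2 <- y[[2]]; S3 <- y[[3]]; S4 <- y[[4]]; S5 <- y[[5]]
  S6 <- y[[6]]; S6x <- y[[7]]; N2 <- y[[8]]; A3 <- y[[9]]
  N1 <- p$Ntot - N2
  A2 <- p$Atot - A3
  v1 <- p$k1 * S1 * A3 / (1 + (A3 / p$Ki)^p$q)
  v2 <- p$k2 * S2
  v3 <- (p$kg1 * p$kp1 * S3 * N1 * A2 - p$kg2 * p$kp2 * S4 * N2 * A3) /
    (p$kg2 * N2 + p$kp1 * A2)
  v4 <- p$k4 * S4 * A2
  v5 <- p$k5 * S5
  v6 <- p$k6 * S6 * N2
  v7 <- p$k7 * A3
  v8 <- p$k8 * S3 * N2
  v9 <- p$k9 * S6x
  Jex <- p$kappa * (S6 - S6x)
  c(p$J0 - v1, v1 - v2, 2 * v2 - v3 - v8, v3 - v4, v4 - v5,
    v5 - v6 - Jex, p$phi * Jex - v9, v3 - v6 - v8, -2 * v1 + v3 + v4 - v7)
}

#' @export
print.wolf_trajectory <- function(x, ...) {
  cat(sprintf("Wolf model trajectory: %d samples, t = [%g, %g] min\n",
              nrow(x), x$time_min[1], x$time_min[nrow(x)]))
  print(utils::head(as.data.frame(x), 3))
  cat("...\n")
  invisible(x)
}

#' Read / write a model trajectory as CSV
#'
#' Full-precision CSV with header
#' `time_min,S1,S2,S3,S4,S5,S6,S6x,N2,A3`.
#'
#' @param traj a `wolf_trajectory` (see [simulate_wolf()]).
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `wolf_trajectory` (without parameter
#'   attribute unless supplied).
#' @param params optionally, the [wolf_params()] to attach on read.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[, c("time_min", .species_names)]
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, params = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_min", .species_names)
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (!is.null(params)) attr(df, "params") <- params
  class(df) <- c("wolf_trajectory", "data.frame")
  df
}
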