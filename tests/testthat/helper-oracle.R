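# Independent brute-force oracles, written before the package internals
# they check and kept deliberately naive.

# derivative oracle: the nine rate laws and the stoichiometry written out
# longhand, scalar arithmetic only
oracle_derivs <- function(s, p) {
  N1 <- p$Ntot - s[["N2"]]
  A2 <- p$Atot - s[["A3"]]
  v1 <- p$k1 * s[["S1"]] * s[["A3"]] / (1 + (s[["A3"]] / p$Ki)^p$q)
  v2 <- p$k2 * s[["S2"]]
  v3 <- (p$kg1 * p$kp1 * s[["S3"]] * N1 * A2 -
           p$kg2 * p$kp2 * s[["S4"]] * s[["N2"]] * s[["A3"]]) /
    (p$kg2 * s[["N2"]] + p$kp1 * A2)
  v4 <- p$k4 * s[["S4"]] * A2
  v5 <- p$k5 * s[["S5"]]
  v6 <- p$k6 * s[["S6"]] * s[["N2"]]
  v7 <- p$k7 * s[["A3"]]
  v8 <- p$k8 * s[["S3"]] * s[["N2"]]
  v9 <- p$k9 * s[["S6x"]]
  Jex <- p$kappa * (s[["S6"]] - s[["S6x"]])
  c(S1 = p$J0 - v1,
    S2 = v1 - v2,
    S3 = 2 * v2 - v3 - v8,
    S4 = v3 - v4,
    S5 = v4 - v5,
    S6 = v5 - v6 - Jex,
    S6x = p$phi * Jex - v9,
    N2 = v3 - v6 - v8,
    A3 = -2 * v1 + v3 + v4 - v7)
}

# direct O(N^2) DFT sum, 1-based bins
oracle_dft <- function(x) {
  N <- length(x)
  vapply(seq_len(N), function(k) {
    sum(x * exp(-1i * 2 * pi * (k - 1) * (seq_len(N) - 1) / N))
  }, complex(1))
}

# a random valid model state (strictly inside the pool bounds)
random_state <- function(params = wolf_params()) {
  wolf_state(S1 = runif(1, 0, 5), S2 = runif(1, 0, 10),
             S3 = runif(1, 0, 2), S4 = runif(1, 0, 2),
             S5 = runif(1, 0, 10), S6 = runif(1, 0, 1),
             S6x = runif(1, 0, 1),
             N2 = runif(1, 0.01, params$Ntot * 0.99),
             A3 = runif(1, 0.01, params$Atot * 0.99),
             params = params)
}

# a short default-model trajectory shared across tests (built once)
shared_traj <- local({
  traj <- NULL
  function() {
    if (is.null(traj)) traj <<- simulate_wolf(wolf_params(), t_end = 20)
    traj
  }
})
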