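test_that("reaction rates vanish on the zero state and obey exchange symmetry", {
  p <- wolf_params()
  zero <- stats::setNames(rep(0, 9), c("S1","S2","S3","S4","S5","S6","S6x","N2","A3"))
  v <- reaction_rates(zero, p)
  expect_equal(unname(v), rep(0, 10))

  s <- random_state(p)
  s[["S6x"]] <- s[["S6"]]
  expect_equal(reaction_rates(s, p)[["Jex"]], 0)
})

test_that("HK-PFK rate matches hand evaluation of the inhibition kinetics", {
  # S1 = 1, A3 = 1, k1 = 550, Ki = 1, q = 4: v1 = 550/(1 + 1) = 275
  s <- stats::setNames(c(1, 0, 0, 0, 0, 0, 0, 0, 1),
                       c("S1","S2","S3","S4","S5","S6","S6x","N2","A3"))
  v <- reaction_rates(s, wolf_params())
  expect_equal(v[["v1"]], 275)
})

test_that("the degenerate fully-oxidised, fully-phosphorylated state is rejected", {
  p <- wolf_params()
  # the GAPDH-PGK denominator kg2*N2 + kp1*(Atot - A3) vanishes exactly
  # when N2 = 0 and A3 = Atot
  s <- stats::setNames(c(1, 1, 1, 1, 1, 1, 1, 0, p$Atot),
                       c("S1","S2","S3","S4","S5","S6","S6x","N2","A3"))
  expect_error(reaction_rates(s, p), "degenerate")
  expect_error(reaction_rates(replace(s, 1, NaN), p), "finite")
})

test_that("derivatives are the stated stoichiometric combination of the fluxes", {
  p <- wolf_params()
  zero <- stats::setNames(rep(0, 9), c("S1","S2","S3","S4","S5","S6","S6x","N2","A3"))
  d0 <- wolf_derivatives(zero, p)
  expect_equal(d0[["S1"]], p$J0)
  expect_equal(unname(d0[-1]), rep(0, 8))

  set.seed(101)
  for (i in 1:10) {
    s <- random_state(p)
    v <- reaction_rates(s, p)
    d <- wolf_derivatives(s, p)
    expect_equal(d[["N2"]], v[["v3"]] - v[["v6"]] - v[["v8"]],
                 tolerance = 1e-12)
    expect_equal(d[["S3"]], 2 * v[["v2"]] - v[["v3"]] - v[["v8"]],
                 tolerance = 1e-12)
    expect_equal(d[["A3"]],
                 -2 * v[["v1"]] + v[["v3"]] + v[["v4"]] - v[["v7"]],
                 tolerance = 1e-12)
  }
})

test_that("derivatives agree with the brute-force oracle at a fixed state and 100 random states", {
  p <- wolf_params()
  ref <- wolf_state(1.1, 5.1, 0.55, 0.67, 8.3, 0.08, 0.02, 0.41, 2.4)
  expect_equal(wolf_derivatives(ref, p), oracle_derivs(ref, p),
               tolerance = 1e-10)
  set.seed(7)
  for (i in 1:100) {
    s <- random_state(p)
    expect_equal(wolf_derivatives(s, p), oracle_derivs(s, p),
                 tolerance = 1e-10)
  }
})

test_that("default initial state is valid, fixed, and immaterial for the limit cycle", {
  s1 <- default_initial_state()
  s2 <- default_initial_state()
  expect_identical(s1, s2)
  expect_true(all(s1 > 0))
  p <- wolf_params()
  expect_lt(s1[["N2"]], p$Ntot)
  expect_lt(s1[["A3"]], p$Atot)

  per1 <- period_of(shared_traj(), "N2")
  init2 <- pmin(s1 * 1.1, c(rep(Inf, 7), p$Ntot, p$Atot))
  names(init2) <- names(s1)
  per2 <- period_of(simulate_wolf(p, init = init2, t_end = 20), "N2")
  expect_lt(abs(per1 - per2) / per1, 0.001)
})

test_that("integration respects non-negativity and pool bounds and is deterministic", {
  p <- wolf_params()
  traj <- shared_traj()
  sp <- as.matrix(as.data.frame(traj)[, -1])
  expect_gte(min(sp), -1e-6)
  expect_lte(max(traj$N2), p$Ntot + 1e-6)
  expect_lte(max(traj$A3), p$Atot + 1e-6)

  a <- simulate_wolf(p, t_end = 2)
  b <- simulate_wolf(p, t_end = 2)
  expect_identical(as.data.frame(a), as.data.frame(b))

  expect_error(simulate_wolf(p, t_end = -1), "t_end")
  expect_error(simulate_wolf(p, dt_out = 0), "dt_out")
})

test_that("default parameters sustain a limit cycle; zero glucose influx kills it", {
  f <- oscillation_features(shared_traj(), "N2")
  expect_true(f$oscillatory)
  expect_gte(f$n_peaks, 10)
  pk <- find_peaks(steady_window(shared_traj(), 10)$time_min,
                   steady_window(shared_traj(), 10)$N2)
  expect_lt(stats::sd(diff(pk)) / mean(diff(pk)), 0.01)

  dead <- oscillation_features(
    simulate_wolf(wolf_params(J0 = 0), t_end = 20), "N2")
  expect_false(dead$oscillatory)
})

test_that("pool totals act as parameters: perturbing them changes the dynamics", {
  per_ref <- period_of(shared_traj(), "N2")
  p2 <- wolf_params(Ntot = 1.2, Atot = 4.2)
  per2 <- period_of(simulate_wolf(p2, t_end = 20), "N2")
  expect_gt(abs(per2 - per_ref) / per_ref, 1e-4)
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(wolf_params(Ki = 0), "Ki")
  expect_error(wolf_params(q = 0.5), "q")
  expect_error(wolf_params(phi = 0), "phi")
  expect_error(wolf_params(k2 = -1), "negative")
  expect_error(wolf_params(Ntot = -1), "Ntot")
  expect_silent(validate_wolf_params(wolf_params()))
})

test_that("parameter config round-trips through JSON and YAML with reaction-indexed keys", {
  p <- wolf_params(Ki = 0.9, J0 = 45)
  f_json <- tempfile(fileext = ".json")
  write_wolf_params(p, f_json)
  keys <- names(jsonlite::read_json(f_json))
  expect_true(all(c("r1k1", "r1ki1", "r11v", "jKappa", "q", "phi") %in% keys))
  expect_equal(read_wolf_params(f_json), p)

  f_yaml <- tempfile(fileext = ".yaml")
  write_wolf_params(p, f_yaml)
  expect_equal(read_wolf_params(f_yaml), p)

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(nonsense = 1), bad, auto_unbox = TRUE)
  expect_error(read_wolf_params(bad), "unknown parameter")
})

test_that("trajectory CSV round-trips at full precision", {
  traj <- simulate_wolf(wolf_params(), t_end = 0.5, dt_out = 0.01)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(as.data.frame(back), as.data.frame(traj)[, names(back)],
               tolerance = 1e-15)
  expect_error(read_trajectory(textConnection("a,b\n1,2")), "columns")
})
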