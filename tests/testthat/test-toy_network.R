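# Toy circuit: configuration factors, drift, environment balance.

test_that("configuration factors follow the dominance rule", {
  th <- theta_toy
  expect_equal(configuration_factors(5, 0, th), list(h_p = 2.4, h_i = 0.5))
  expect_equal(configuration_factors(0, 5, th), list(h_p = 1, h_i = 1))
  expect_equal(configuration_factors(0, 0, th), list(h_p = 1, h_i = 1))
  # ties resolve to the baseline configuration
  expect_equal(configuration_factors(3, 3, th), list(h_p = 1, h_i = 1))
})

test_that("toy drift reproduces the printed rate arithmetic", {
  th <- theta_toy
  env0 <- list(I_ext = 0)
  # signal generation k_1 * P * precursor = 1 * 6 * 10
  d <- toy_drift(c(0, 0, 0), env0, th, precursor = 10)
  expect_equal(d[1], 60)
  expect_equal(d[2], 0)
  # degradation + dilution of S at S = 1 (inhibitor-dominant configuration)
  d1 <- toy_drift(c(1, 2, 0), env0, th, precursor = 0)
  expect_equal(d1[1], -th[["gamma"]] * 2 - 0.994 - 0.006)
  # empty cell, no sources anywhere
  expect_equal(
    toy_drift(c(0, 0, 0), env0, th, precursor = 0)[1:2],
    c(0, 0)
  )
  # product generation switches with the configuration factor
  on <- toy_drift(c(10, 0, 0), env0, th)
  off <- toy_drift(c(0, 10, 0), env0, th)
  expect_equal(on[3], 50 * 2.4)
  expect_equal(off[3], 50 * 1)
  expect_error(toy_drift(c(-1, 0, 0), env0, th), "negative")
})

test_that("extracellular inhibitor balance is linear in cell density", {
  th <- theta_toy
  x <- c(4, 0.01, 30)
  env <- list(I_ext = 55)
  base <- toy_env_source(x, env, th, n_density_frac = 0.2)
  expect_equal(toy_env_source(x, env, th, n_density_frac = 0.4), 2 * base)
  expect_equal(toy_env_source(x, env, th, n_density_frac = 0), 0)
  # aggregate over a 10-cell ensemble equals the explicit summation
  set.seed(9)
  X <- matrix(runif(30, 0, 20), nrow = 3)
  agg <- toy_env_source(X, env, th)
  manual <- vapply(
    seq_len(10),
    function(i) toy_env_source(X[, i], env, th), numeric(1)
  )
  expect_equal(agg, manual)
  expect_error(toy_env_source(x, env, th, n_density_frac = -1), "nonnegative")
})

test_that("annihilation forces signal/inhibitor dominance exclusivity", {
  # along stochastic trajectories min(S, I) stays near zero after the
  # initial race (fast irreversible binding)
  sim <- quiet_sim(simulate_single_cells(theta_toy,
    n_cells = 150, t_final = 120,
    dt = 0.01, seed = 5
  ))
  fin <- sim$snapshots[sim$snapshots$t >= 60, ]
  expect_lt(stats::quantile(pmin(fin$S, fin$I), 0.95), 0.5)
  expect_gt(mean(pmax(fin$S, fin$I)), 5)
})

test_that("deterministic toy model is bistable and theta_i = 1 removes it", {
  cen <- find_steady_states(theta_toy, 10,
    n_starts = 60,
    search_box = c(1e-6, 1e3), seed = 2
  )
  expect_equal(sum(cen$states$stability == "stable"), 2)
  # product branches at k_p * h_p / (k_dX + mu)
  X_branches <- sort(cen$states$X[cen$states$stability == "stable"])
  expect_equal(X_branches, c(50, 120), tolerance = 1e-6)

  cen1 <- find_steady_states(set_parameters(theta_toy, theta_i = 1), 10,
    n_starts = 60, search_box = c(1e-6, 1e3), seed = 2
  )
  expect_equal(sum(cen1$states$stability == "stable"), 1)
})
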