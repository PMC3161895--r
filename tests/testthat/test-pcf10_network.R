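# pCF10 single-cell network: DNA-loop repression, PrgB production, drift,
# and the per-cell environment source.

test_that("repressed DNA fraction has the binding-equilibrium limits", {
  th <- theta_pcf10
  expect_equal(repressed_dna_fraction(0, 0, th), 0)
  expect_equal(repressed_dna_fraction(0, 25, th), 0)
  expect_equal(repressed_dna_fraction(12, 0, th), 1)
  # saturation in I at fixed C
  expect_equal(repressed_dna_fraction(1e9, 10, th), 1, tolerance = 1e-6)
  # monotone nondecreasing in inhibitor, nonincreasing in pheromone
  I_grid <- seq(1, 500, length.out = 40)
  f_I <- repressed_dna_fraction(I_grid, 10, th)
  expect_true(all(diff(f_I) >= 0))
  C_grid <- seq(0, 200, length.out = 40)
  f_C <- repressed_dna_fraction(100, C_grid, th)
  expect_true(all(diff(f_C) <= 0))
  expect_true(all(f_I >= 0 & f_I <= 1))
  # symmetric-concentration point evaluates the printed constants directly
  expect_equal(
    repressed_dna_fraction(10, 10, th),
    1 / (1 + th[["K_3,8"]]),
    tolerance = 1e-12
  )
  expect_error(repressed_dna_fraction(-1, 0, th), "nonnegative")
})

test_that("PrgB production matches both published variants", {
  th <- theta_pcf10
  expect_equal(prgb_production(10, th, "linear"), 0.1) # K_1,5 * Q_L
  expect_equal(prgb_production(0, th, "linear"), 0)
  # sigmoid tail at zero ~ basal rate; saturation at basal + maximal
  expect_equal(prgb_production(0, th, "sigmoid"), th[["K_1,7"]],
    tolerance = 1e-10
  )
  expect_equal(prgb_production(1e4, th, "sigmoid"),
    th[["K_1,7"]] + th[["K_1,9"]],
    tolerance = 1e-12
  )
  # midpoint of the switch sits at the threshold concentration
  expect_equal(
    prgb_production(th[["K_1,8"]], th, "sigmoid"),
    th[["K_1,7"]] + th[["K_1,9"]] / 2
  )
  q <- seq(0, 40, length.out = 30)
  expect_true(all(diff(prgb_production(q, th, "sigmoid")) >= 0))
  expect_error(prgb_production(10, th, "bogus"))
})

test_that("drift transport terms behave as first-order import", {
  th <- theta_pcf10
  env0 <- list(I_ext = 0, C_ext = 0)
  d0 <- pcf10_drift(rep(0, 6), env0, th, "linear", k = 5)
  expect_equal(d0[4], 0) # no inhibitor import, nothing to degrade
  expect_equal(d0[5], 0)
  env10 <- list(I_ext = 0, C_ext = 10)
  d10 <- pcf10_drift(rep(0, 6), env10, th, "linear", k = 5)
  expect_equal(d10[5], 2.57e-3) # K_2,8 * C_ext
  expect_error(pcf10_drift(c(-1, 0, 0, 0, 0, 0), env0, th), "negative")
  expect_error(pcf10_drift(c(NaN, 0, 0, 0, 0, 0), env0, th), "non-finite")
})

test_that("doubling copy number doubles transcription and nothing else", {
  th <- theta_pcf10
  x <- c(12, 3, 40, 200, 8, 20)
  env <- list(I_ext = 90, C_ext = 8)
  d1 <- pcf10_drift(x, env, th, "sigmoid", k = 3)
  d2 <- pcf10_drift(x, env, th, "sigmoid", k = 6)
  # transcription production terms double: isolate them by subtracting the
  # k-independent removal/production parts evaluated at k = 0 equivalents
  removal <- c(
    -(th[["K_4,1"]] + th[["mu_hat"]]) * x[1],
    -(th[["K_4,2"]] + th[["mu_hat"]]) * x[2],
    -(th[["K_4,3"]] + th[["mu_hat"]]) * x[3]
  )
  prod1 <- d1[1:3] - removal
  prod2 <- d2[1:3] - removal
  expect_equal(prod2, 2 * prod1)
  # transport and protein equations are untouched by k
  expect_equal(d1[4:6], d2[4:6])
})

test_that("environment source aggregates as an explicit per-cell sum", {
  th <- theta_pcf10
  set.seed(42)
  X <- matrix(runif(6 * 12, 0, 50), nrow = 6)
  env <- list(I_ext = 75, C_ext = 5)
  per_cell <- pcf10_env_source(X, env, th)
  expect_length(per_cell, 12)
  manual <- vapply(
    seq_len(12),
    function(i) pcf10_env_source(X[, i], env, th), numeric(1)
  )
  expect_equal(per_cell, manual)
  expect_equal(mean(per_cell), sum(manual) / 12)
  # I_ext = 0: no uptake, source nonnegative
  expect_true(all(pcf10_env_source(X, list(I_ext = 0, C_ext = 5), th) >= 0))
})
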