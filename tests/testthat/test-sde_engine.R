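# Euler-Maruyama kernel and chemical-Langevin amplitudes.

test_that("chemical-Langevin amplitudes follow the volume-scaled formula", {
  stoich <- diag(2)
  expect_equal(
    langevin_amplitudes(stoich, c(0, 0), 1e-15),
    c(0, 0)
  )
  r <- 0.25
  amp <- langevin_amplitudes(matrix(1), r, 1e-15)
  expect_equal(amp^2, r / (1e-9 * 6.02214076e23 * 1e-15))
  # quadrupling the volume halves every amplitude
  expect_equal(
    langevin_amplitudes(stoich, c(1, 2), 4e-15),
    langevin_amplitudes(stoich, c(1, 2), 1e-15) / 2
  )
  # masked species have identically zero amplitude
  expect_equal(
    langevin_amplitudes(stoich, c(1, 2), 1e-15, mask = c(TRUE, FALSE))[2],
    0
  )
  # stoichiometry enters squared
  amp2 <- langevin_amplitudes(matrix(2), r, 1e-15)
  expect_equal(amp2, 2 * amp)
  expect_error(langevin_amplitudes(stoich, c(-1, 0), 1e-15), "nonnegative")
})

test_that("zero-noise integration is the explicit Euler path", {
  drift <- function(x, t) -0.3 * x + 1
  path <- integrate_sde(drift, NULL, c(y = 2), c(0, 5), dt = 0.1)
  y <- 2
  for (i in seq_len(50)) y <- y + (-0.3 * y + 1) * 0.1
  expect_equal(path$y[nrow(path)], y)
  expect_equal(path$t[nrow(path)], 5)
  expect_identical(attr(path, "clipped"), 0L)
})

test_that("OU stationary variance matches sigma^2 / (2 theta)", {
  # 1e4 independent OU components integrated as one vector state
  th <- 0.8
  sig <- 0.5
  n <- 1e4
  path <- integrate_sde(
    function(x, t) -th * x, function(x, t) sig,
    x0 = rep(0, n), t_span = c(0, 12 / th), dt = 0.02, seed = 99,
    record_every = 300L, clip_negative = FALSE
  )
  v_exact <- sig^2 / (2 * th)
  v_hat <- var(as.numeric(path[nrow(path), -1]))
  se <- v_exact * sqrt(2 / (n - 1)) # SE of a variance estimate
  expect_lt(abs(v_hat - v_exact), 3 * se)
})

test_that("weak error on the OU mean halves with the step", {
  th <- 1
  n <- 2e4
  run <- function(dt) {
    p <- integrate_sde(
      function(x, t) -th * x, function(x, t) 0.3,
      x0 = rep(1, n), t_span = c(0, 1), dt = dt, seed = 7,
      record_every = round(1 / dt), clip_negative = FALSE
    )
    mean(as.numeric(p[nrow(p), -1]))
  }
  err1 <- abs(run(0.1) - exp(-1))
  err2 <- abs(run(0.05) - exp(-1))
  expect_gt(err1 / err2, 1.4)
  expect_lt(err1 / err2, 3)
})

test_that("identical seeds give identical paths; clipping is counted", {
  f <- function(x, t) -x
  g <- function(x, t) 1
  p1 <- integrate_sde(f, g, c(a = 1), c(0, 2), 0.01, seed = 5)
  p2 <- integrate_sde(f, g, c(a = 1), c(0, 2), 0.01, seed = 5)
  expect_identical(p1, p2)
  p3 <- integrate_sde(f, g, c(a = 1), c(0, 2), 0.01, seed = 6)
  expect_false(identical(p1$a, p3$a))
  # an OU pinned near zero with clipping on must clip
  p4 <- integrate_sde(function(x, t) -10 * x, g, c(a = 0), c(0, 2), 0.01,
    seed = 1
  )
  expect_gt(attr(p4, "clipped"), 0)
  expect_true(all(p4$a >= 0))
  expect_error(integrate_sde(f, g, c(a = 1), c(0, 1), dt = -1), "positive")
})

test_that("compiled ensemble stepper matches the R reference bitwise", {
  # deterministic part: C++ stepper vs R Euler loop (machine precision)
  th <- theta_nobi
  p <- pbmcell:::.pcf10_par_vector(th)
  x0 <- matrix(rep(c(1, 1, 1, 1, 0, 1), 3), ncol = 3)
  res <- pbmcell:::.pcf10_advance_cpp(
    x0, c(2L, 5L, 9L), 1, rep(1, 3), 8, p, 0L,
    rep(FALSE, 6), 2, 500L, TRUE, FALSE, FALSE
  )
  ref <- pcf10_euler_r(x0, c(2, 5, 9), 1, 8, th, "sigmoid", 2, 500)
  expect_equal(res$x, ref$x, tolerance = 1e-12)
  expect_equal(res$I_ext, ref$I_ext, tolerance = 1e-12)

  # stochastic part: same Wiener stream reproduced in R
  set.seed(31)
  mask <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  res_n <- pbmcell:::.pcf10_advance_cpp(
    x0, c(2L, 5L, 9L), 1, rep(1, 3), 8, p, 0L,
    mask, 2, 4L, TRUE, FALSE, FALSE
  )
  set.seed(31)
  x <- x0
  Ie <- 1
  mu <- th[["mu_hat"]]
  omega <- concentration_to_copies(1, th[["V_cell"]])
  for (s in 1:4) {
    env <- list(I_ext = Ie, C_ext = 8)
    d <- pcf10_drift(x, env, th, "sigmoid", c(2, 5, 9))
    for (i in 1:3) {
      prod_b <- prgb_production(x[2, i], th, "sigmoid")
      rate_b <- prod_b + th[["K_4,9"]] * x[6, i]
      step <- d[, i] * 2
      step[6] <- step[6] + sqrt(rate_b / omega) * sqrt(2) * rnorm(1)
      x[, i] <- pmax(x[, i] + step, 0)
    }
    src <- pcf10_env_source(x, env, th)
    Ie <- max(Ie + (mean(src) - (th[["K_4,5"]] + mu) * Ie) * 2, 0)
  }
  expect_equal(res_n$x, x, tolerance = 1e-12)
})
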