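# Population simulator: copy-number schemes, division/resampling,
# environment coupling, reproducibility, mean-field scaling.

test_that("copy-number distributions match the partitioning argument", {
  het <- initial_copy_number_distribution("heterogeneous", k_max = 9)
  expect_equal(sum(het$prob), 1)
  expect_equal(sum(het$k * het$prob), 5) # mean copy number exactly 5
  fx <- initial_copy_number_distribution("fixed", k = 5)
  expect_equal(fx$k, 5L)
  expect_equal(fx$prob, 1)
  deg <- initial_copy_number_distribution("heterogeneous", k_max = 1)
  expect_equal(deg$k, 1L)
  expect_equal(deg$prob, 1)
  expect_error(initial_copy_number_distribution("fixed", k = 0), ">= 1")
})

test_that("division keeps ensemble size and copy numbers intact", {
  set.seed(4)
  n <- 10000
  ens <- list(
    x = matrix(runif(6 * n), nrow = 6),
    k = sample(1:9, n, replace = TRUE)
  )
  mu_dt <- 0.01
  out <- divide_and_resample(ens, dt = 1, mu = mu_dt)
  expect_equal(ncol(out$x), n)
  expect_true(all(out$k %in% 1:9))
  # births are Binomial(n, mu dt): within 5 standard errors
  se <- sqrt(n * mu_dt * (1 - mu_dt))
  expect_lt(abs(out$n_divisions - n * mu_dt), 5 * se)
  # daughters inherit the parent copy number exactly: run one certain
  # division on a single-class ensemble
  ens5 <- list(x = matrix(1, 6, 50), k = rep(5L, 50))
  out5 <- divide_and_resample(ens5, dt = 1, mu = 1 - 1e-12)
  expect_true(all(out5$k == 5L))
})

test_that("shared-environment update equals the brute-force per-cell sum", {
  th <- theta_pcf10
  p <- pbmcell:::.pcf10_par_vector(th)
  set.seed(8)
  n <- 40
  x0 <- matrix(runif(6 * n, 0, 60), nrow = 6)
  kvec <- sample(1:9, n, replace = TRUE)
  Ie0 <- 120
  res <- pbmcell:::.pcf10_advance_cpp(
    x0, as.integer(kvec), Ie0, rep(Ie0, n),
    13.5, p, 1L, rep(FALSE, 6), 1, 1L, TRUE, FALSE, FALSE
  )
  # advance the cells alone, then apply the environment balance by explicit
  # summation over the updated ensemble
  env <- list(I_ext = Ie0, C_ext = 13.5)
  d <- pcf10_drift(x0, env, th, "linear", kvec)
  x1 <- pmax(x0 + d, 0)
  vol_ratio <- th[["phi_cell"]] / (1 - th[["phi_cell"]])
  secr <- th[["K_1,6"]] * (x1[1, ] + x1[2, ])
  Ie1 <- Ie0 + vol_ratio * sum(secr) / n -
    (vol_ratio * th[["K_2,6"]] + th[["K_4,5"]] + th[["mu_hat"]]) * Ie0
  expect_equal(res$x, x1, tolerance = 1e-13)
  expect_equal(res$I_ext, Ie1, tolerance = 1e-13)
})

test_that("zero-noise ensemble follows the stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  th <- theta_pcf10
  rhs <- function(t, z, parms) {
    env <- list(I_ext = z[7], C_ext = 13.5)
    list(c(
      pcf10_drift(z[1:6], env, th, "linear", k = 5),
      pcf10_env_source(z[1:6], env, th) -
        (th[["K_4,5"]] + th[["mu_hat"]]) * z[7]
    ))
  }
  z0 <- c(1, 1, 1, 1, 0, 1, 1)
  ode <- deSolve::lsoda(z0, c(0, 2e4), rhs, NULL, rtol = 1e-9, atol = 1e-9)
  p <- pbmcell:::.pcf10_par_vector(th)
  res <- pbmcell:::.pcf10_advance_cpp(
    matrix(z0[1:6], ncol = 1), 5L, z0[7], z0[7], 13.5, p, 1L,
    rep(FALSE, 6), 1, 2e4L, TRUE, FALSE, FALSE
  )
  final <- c(res$x[, 1], res$I_ext)
  expect_equal(final, unname(ode[2, -1]), tolerance = 2e-3)
})

test_that("one-cell PBM and single-cell model coincide path-for-path", {
  args <- list(
    theta = theta_pcf10, variant = "linear", n_cells = 1,
    t_final = 2000, dt = 2, noise = "protein", C_ext = 13.5,
    copy_scheme = "fixed", k = 5, seed = 21
  )
  a <- quiet_sim(do.call(simulate_pbm, args))
  b <- quiet_sim(do.call(simulate_single_cells, args))
  expect_equal(a$snapshots$B, b$snapshots$B, tolerance = 1e-12)
})

test_that("runs are bit-reproducible for a fixed seed", {
  args <- list(
    theta = theta_toy, n_cells = 60, t_final = 30, dt = 0.01,
    seed = 13
  )
  a <- quiet_sim(do.call(simulate_pbm, args))
  b <- quiet_sim(do.call(simulate_pbm, args))
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$env, b$env)
  c_ <- quiet_sim(do.call(simulate_pbm, modifyList(args, list(seed = 14))))
  expect_false(identical(a$snapshots$X, c_$snapshots$X))
})

test_that("shared-environment fluctuations shrink with ensemble size", {
  # replicate variance of the final shared I_ext across seeds ~ 1/N
  final_Iext <- function(n, seed) {
    quiet_sim(simulate_pbm(theta_pcf10,
      variant = "linear", n_cells = n,
      t_final = 4000, dt = 5, noise = "protein_peptides", C_ext = 13.5,
      copy_scheme = "fixed", k = 5, seed = seed
    ))$final$I_ext
  }
  v_small <- var(vapply(1:6, function(s) final_Iext(30, s), numeric(1)))
  v_large <- var(vapply(1:6, function(s) final_Iext(270, s), numeric(1)))
  expect_gt(v_small / v_large, 2) # ~9 expected at 9x the cells
})

test_that("heterogeneous initial assignment is stratified and complete", {
  sim <- quiet_sim(simulate_pbm(theta_nobi,
    variant = "sigmoid", n_cells = 90,
    t_final = 50, dt = 5, noise = "none", C_ext = 0,
    copy_scheme = "heterogeneous", seed = 2, division = FALSE
  ))
  k0 <- sim$snapshots$k[sim$snapshots$t == 0]
  expect_equal(as.integer(table(k0)), rep(10L, 9))
  expect_equal(mean(k0), 5)
})
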