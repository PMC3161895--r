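# Steady-state location, stability classification, bifurcation scans.

test_that("census residuals meet the root tolerance", {
  cen <- find_steady_states(theta_pcf10, 13.5,
    variant = "linear", k = 5,
    n_starts = 150, seed = 1
  )
  expect_gte(nrow(cen$states), 3)
  fn <- pbmcell:::.closed_system(theta_pcf10, 13.5, "linear", 5)
  for (i in seq_len(nrow(cen$states))) {
    z <- as.numeric(cen$states[i, 1:7])
    expect_lt(max(abs(fn(z))), 1e-9)
  }
})

test_that("bistable census at 13.5 nM: two stable states and a saddle", {
  cen <- find_steady_states(theta_pcf10, 13.5,
    variant = "linear", k = 5,
    n_starts = 150, seed = 1
  )
  expect_equal(sum(cen$states$stability == "stable"), 2)
  expect_equal(sum(cen$states$stability == "unstable"), 1)
  # off and on branches are well separated in PrgB
  B_stable <- sort(cen$states$B[cen$states$stability == "stable"])
  expect_lt(B_stable[1], 60)
  expect_gt(B_stable[2], 100)
})

test_that("stability labels agree with perturbed deterministic relaxation", {
  cen <- find_steady_states(theta_pcf10, 13.5,
    variant = "linear", k = 5,
    n_starts = 150, seed = 1
  )
  fn <- pbmcell:::.closed_system(theta_pcf10, 13.5, "linear", 5)
  relax <- function(z0, t_end = 4e5, dt = 10) {
    z <- z0
    for (s in seq_len(t_end / dt)) z <- pmax(z + fn(z) * dt, 0)
    z
  }
  stable <- cen$states[cen$states$stability == "stable", ]
  for (i in seq_len(nrow(stable))) {
    z <- as.numeric(stable[i, 1:7])
    zr <- relax(z * 1.01)
    expect_lt(max(abs(zr - z) / pmax(z, 1)), 1e-3)
  }
  saddle <- as.numeric(cen$states[cen$states$stability == "unstable", 1:7][1, ])
  zr <- relax(saddle * 1.01)
  expect_gt(max(abs(zr - saddle) / pmax(saddle, 1)), 0.1)
})

test_that("setting K_4,2 = K_4,1 excludes bistability over the pheromone range", {
  grid <- seq(0, 50, by = 10)
  for (variant in c("linear", "sigmoid")) {
    scan <- bifurcation_scan(theta_nobi, grid,
      variant = variant, k = 5,
      n_starts = 60, seed = 1
    )
    g <- glance(scan)
    expect_true(all(g$n_stable == 1), label = variant)
    expect_true(all(is.na(g$bistable_lo)))
  }
})

test_that("zero pheromone gives a single low-PrgB off state", {
  for (variant in c("linear", "sigmoid")) {
    cen <- find_steady_states(theta_pcf10, 0,
      variant = variant, k = 5,
      n_starts = 60, seed = 1
    )
    expect_equal(sum(cen$states$stability == "stable"), 1)
    expect_lt(cen$states$B[cen$states$stability == "stable"], 10)
  }
})

test_that("the bistable window brackets 13.5 nM on a dense scan", {
  scan <- bifurcation_scan(theta_pcf10, seq(12, 14.5, by = 0.5),
    variant = "linear", k = 5, n_starts = 80, seed = 1
  )
  g <- glance(scan)
  expect_gte(g$bistable_lo[1], 12)
  expect_gte(g$bistable_hi[1], 13.5)
  expect_true(all(g$n_stable[g$control_value %in% c(12.5, 13.5)] == 2))
})

test_that("census roots agree with an independent solver", {
  skip_if_not_installed("pracma")
  cen <- find_steady_states(theta_toy, 10,
    n_starts = 60,
    search_box = c(1e-6, 1e3), seed = 2
  )
  fn <- pbmcell:::.closed_system(theta_toy, 10)
  stable <- cen$states[cen$states$stability == "stable", ]
  for (i in seq_len(nrow(stable))) {
    z <- as.numeric(stable[i, 1:4])
    alt <- pracma::fsolve(fn, z * 1.05)$x
    expect_equal(alt, z, tolerance = 1e-5)
  }
})

test_that("empty search yields a diagnostic, not an error", {
  cen <- find_steady_states(theta_toy, 10, n_starts = 0, seed = 1)
  expect_equal(nrow(cen$states), 0)
  expect_match(cen$diagnostic, "no root")
  expect_error(
    bifurcation_scan(theta_toy, c(1, 3, 2)),
    "monotone"
  )
})

test_that("on/off threshold is the geometric midpoint convention", {
  scan <- bifurcation_scan(theta_nobi, c(0, 18, 36),
    variant = "sigmoid",
    k = 5, n_starts = 40, seed = 1
  )
  thr <- on_off_threshold(scan)
  tab <- tidy(scan)
  B <- tab$B[tab$stability == "stable"]
  expect_equal(thr, exp(mean(log(range(B)))))
  expect_gt(thr, min(B))
  expect_lt(thr, max(B))
})
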