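# Shared fixtures: parameter sets are loaded once; simulations in tests run
# at reduced scale and may legitimately warn about non-stationarity, which
# the quiet() wrapper silences where the test is not about stationarity.

theta_pcf10 <- load_parameters("pcf10")
theta_toy <- load_parameters("toy")
# bistability-exclusion variant used throughout
theta_nobi <- set_parameters(theta_pcf10, `K_4,2` = 0.001)

quiet_sim <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("stationar|clipping", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

final_snapshot <- function(sim, variable = NULL) {
  if (is.null(variable)) variable <- if (sim$model_id == "pcf10") "B" else "X"
  sim$snapshots[[variable]][sim$snapshots$t == max(sim$snapshots$t)]
}

# R-side Euler reference for the coupled pCF10 ensemble (brute-force oracle
# mirroring the compiled stepper's splitting, deterministic part only)
pcf10_euler_r <- function(x, k, I_ext, C_ext, theta, variant, dt, n_steps) {
  mu <- theta[["mu_hat"]]
  vol_ratio <- theta[["phi_cell"]] / (1 - theta[["phi_cell"]])
  for (s in seq_len(n_steps)) {
    env <- list(I_ext = I_ext, C_ext = C_ext)
    d <- pcf10_drift(x, env, theta, variant, k)
    x <- pmax(x + d * dt, 0)
    src <- pcf10_env_source(x, env, theta)
    I_ext <- max(
      I_ext + (mean(src) - (theta[["K_4,5"]] + mu) * I_ext) * dt, 0
    )
  }
  list(x = x, I_ext = I_ext)
}
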