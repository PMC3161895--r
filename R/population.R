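# Constant-number Monte Carlo population simulator.
#
# N sample-path cells advance by Euler-Maruyama; the extracellular inhibitor
# is either one shared balance driven by the empirical ensemble mean of the
# per-cell exchange (the population balance model) or a private copy per
# cell (the isolated single-cell stochastic model). Division replaces a
# uniformly chosen cell per birth, realizing the constant-population-density
# assumption without tracking volume.

.pcf10_par_vector <- function(theta) {
  v <- vapply(c(
    "K_1,1", "K_1,2", "K_1,3", "K_1,4", "K_1,5", "K_1,6", "K_1,7", "K_1,8",
    "K_1,9", "K_2,6", "K_2,8", "K_3,5", "K_3,8", "K_3,9", "K_4,1", "K_4,2",
    "K_4,3", "K_4,5", "K_4,6", "K_4,8", "K_4,9", "mu_hat", "n", "phi_cell",
    "V_cell"
  ), function(nm) theta[[nm]], numeric(1))
  unname(v)
}

.toy_par_vector <- function(theta) {
  v <- vapply(c(
    "k_1", "k_dS", "k_p", "k_dX", "k_u", "k_dI", "k_i", "mu", "V_cell",
    "theta_p", "theta_i", "gamma", "phi_cell"
  ), function(nm) theta[[nm]], numeric(1))
  unname(v)
}

#' Initial plasmid copy-number distribution
#'
#' `"fixed"` places all mass at `k`; `"heterogeneous"` is uniform over
#' `{1, ..., k_max}` — the stationary copy-number distribution under even
#' plasmid partitioning at division, whose default `k_max = 9` yields a mean
#' copy number of 5.
#'
#' @param scheme `"fixed"` or `"heterogeneous"`.
#' @param k Copy number for the fixed scheme (default 5).
#' @param k_max Upper copy number for the heterogeneous scheme (default 9).
#' @return A tibble with columns `k` and `prob` (summing to one).
#' @export
initial_copy_number_distribution <- function(scheme = c("fixed", "heterogeneous"),
                                             k = 5, k_max = 9) {
  scheme <- match.arg(scheme)
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  if (scheme == "fixed") {
    if (k < 1) stop("copy number must be >= 1", call. = FALSE)
    tibble::tibble(k = as.integer(k), prob = 1)
  } else {
    tibble::tibble(
      k = seq_len(k_max),
      prob = rep(1 / k_max, k_max)
    )
  }
}

# Stratified copy-number assignment: cell counts per class match the
# distribution as closely as integers allow (shuffled for exchangeability).
.assign_copy_numbers <- function(dist, n_cells) {
  counts <- floor(dist$prob * n_cells)
  rem <- n_cells - sum(counts)
  if (rem > 0) {
    extra <- order(dist$prob * n_cells - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  pool <- rep(dist$k, counts)
  pool[sample.int(length(pool))]
}

#' Division with constant-number resampling
#'
#' Each cell divides with probability `mu * dt`; both daughters carry the
#' parent's intracellular state and copy number exactly (plasmids double
#' just before division and split evenly). For every birth one uniformly
#' chosen cell is discarded, keeping the ensemble size constant — the
#' Monte-Carlo surrogate for dilution at constant population density.
#'
#' @param ensemble List with `x` (species-by-cells matrix), `k` (per-cell
#'   copy numbers or other inherited attribute), and optionally
#'   `I_ext_private`.
#' @param dt Time interval (must satisfy `mu * dt << 1`).
#' @param mu Specific growth rate (per time unit).
#' @return The ensemble with `n_divisions` attached.
#' @export
divide_and_resample <- function(ensemble, dt, mu) {
  n <- ncol(ensemble$x)
  born <- which(runif(n) < mu * dt)
  for (i in born) {
    victim <- sample.int(n, 1)
    ensemble$x[, victim] <- ensemble$x[, i]
    ensemble$k[victim] <- ensemble$k[i]
    if (!is.null(ensemble$I_ext_private)) {
      ensemble$I_ext_private[victim] <- ensemble$I_ext_private[i]
    }
  }
  ensemble$n_divisions <- length(born)
  ensemble
}

# Deterministic off-state initialization for pCF10: relax the coupled system
# at zero pheromone with noise off, per copy-number class, then one noisy
# burn-in interval at zero pheromone.
.pcf10_off_init <- function(kvec, theta, variant, dt, shared_env,
                            t_relax = 6e4, t_burn = 2e3, mask = rep(FALSE, 6)) {
  n <- length(kvec)
  x <- matrix(1, nrow = 6, ncol = n)
  x[5, ] <- 0 # no pheromone, no intracellular cCF10
  p <- .pcf10_par_vector(theta)
  res <- .pcf10_advance_cpp(
    x, as.integer(kvec), 1.0, rep(1.0, n), 0.0, p,
    as.integer(variant == "linear"), rep(FALSE, 6), dt,
    as.integer(ceiling(t_relax / dt)), shared_env, FALSE, FALSE
  )
  res2 <- .pcf10_advance_cpp(
    res$x, res$k, res$I_ext, res$I_ext_private, 0.0, p,
    as.integer(variant == "linear"), mask, dt,
    as.integer(ceiling(t_burn / dt)), shared_env, FALSE, FALSE
  )
  list(x = res2$x, k = res2$k, I_ext = res2$I_ext, I_ext_private = res2$I_ext_private)
}

.simulate_engine <- function(theta, mode, variant = "sigmoid",
                             n_cells = 1000, t_final, dt,
                             noise = "protein", C_ext = 0, precursor = 10,
                             copy_scheme = "fixed", k = 5, k_max = 9,
                             P = NULL, init = NULL, snapshot_every = NULL,
                             seed = 1L, division = TRUE,
                             resample = NULL) {
  model_id <- theta$model_id
  shared_env <- mode == "pbm"
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (t_final <= 0 || dt <= 0) stop("t_final and dt must be positive", call. = FALSE)
  if (is.null(snapshot_every)) snapshot_every <- t_final / 20
  labels <- if (model_id == "pcf10") .pcf10_state_labels else .toy_state_labels

  if (is.null(resample)) {
    heterogeneous <- (model_id == "pcf10" && copy_scheme == "heterogeneous") ||
      (model_id == "toy" && !is.null(P) && length(unique(P)) > 1)
    resample <- if (heterogeneous) "within_class" else "uniform"
  }
  resample <- match.arg(resample, c("within_class", "uniform"))
  within_class <- resample == "within_class"

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  if (model_id == "pcf10") {
    mask <- if (is.character(noise)) pcf10_noise_mask(noise) else as.logical(noise)
    p <- .pcf10_par_vector(theta)
    if (is.null(init)) {
      dist <- initial_copy_number_distribution(copy_scheme, k = k, k_max = k_max)
      kvec <- .assign_copy_numbers(dist, n_cells)
      st <- .pcf10_off_init(kvec, theta, variant, dt, shared_env, mask = mask)
    } else {
      st <- init
      if (is.null(st$I_ext_private)) st$I_ext_private <- rep(st$I_ext, ncol(st$x))
      if (is.null(st$I_ext)) st$I_ext <- mean(st$I_ext_private)
    }
    attr_vec <- as.integer(st$k)
  } else {
    mask <- if (is.character(noise)) toy_noise_mask(noise) else as.logical(noise)
    p <- .toy_par_vector(theta)
    if (is.null(init)) {
      Pvec <- if (is.null(P)) rep(theta[["P"]], n_cells) else rep(P, length.out = n_cells)
      # resting balance before precursor addition: empty cells, environment
      # at the naive-configuration inhibitor level k_i / k_u
      st <- list(
        x = matrix(0, nrow = 3, ncol = n_cells), P = Pvec,
        I_ext = theta[["k_i"]] / theta[["k_u"]],
        I_ext_private = rep(theta[["k_i"]] / theta[["k_u"]], n_cells)
      )
    } else {
      st <- init
      if (is.null(st$I_ext_private)) st$I_ext_private <- rep(st$I_ext, ncol(st$x))
      if (is.null(st$I_ext)) st$I_ext <- mean(st$I_ext_private)
    }
    attr_vec <- st$P
  }

  n_chunks <- max(1L, round(t_final / snapshot_every))
  steps_per_chunk <- max(1L, round(snapshot_every / dt))
  snaps <- vector("list", n_chunks + 1L)
  envs <- vector("list", n_chunks + 1L)
  snapshot_tbl <- function(t, x, attr_vec) {
    tb <- tibble::as_tibble(setNames(as.data.frame(t(x)), labels))
    tb <- dplyr::mutate(tb,
      t = t, cell = seq_len(ncol(x)),
      !!(if (model_id == "pcf10") "k" else "P") := attr_vec,
      .before = 1
    )
    tb
  }
  env_tbl <- function(t, st) {
    tibble::tibble(
      t = t,
      I_ext = if (shared_env) st$I_ext else mean(st$I_ext_private),
      I_ext_sd = if (shared_env) 0 else sd(st$I_ext_private)
    )
  }
  snaps[[1]] <- snapshot_tbl(0, st$x, attr_vec)
  envs[[1]] <- env_tbl(0, st)
  clipped <- 0
  divisions <- 0
  total_steps <- 0
  for (chunk in seq_len(n_chunks)) {
    if (model_id == "pcf10") {
      res <- .pcf10_advance_cpp(
        st$x, as.integer(st$k), st$I_ext, st$I_ext_private, C_ext, p,
        as.integer(variant == "linear"), mask, dt, steps_per_chunk,
        shared_env, division, within_class
      )
      st <- list(
        x = res$x, k = res$k, I_ext = res$I_ext,
        I_ext_private = res$I_ext_private
      )
      attr_vec <- as.integer(res$k)
    } else {
      res <- .toy_advance_cpp(
        st$x, st$P, st$I_ext, st$I_ext_private, precursor, p, mask, dt,
        steps_per_chunk, shared_env, division, within_class
      )
      st <- list(
        x = res$x, P = res$P, I_ext = res$I_ext,
        I_ext_private = res$I_ext_private
      )
      attr_vec <- res$P
    }
    if (any(!is.finite(st$x))) {
      stop("non-finite state after chunk ", chunk, call. = FALSE)
    }
    clipped <- clipped + res$clipped
    divisions <- divisions + res$divisions
    total_steps <- total_steps + steps_per_chunk * n_cells
    snaps[[chunk + 1]] <- snapshot_tbl(chunk * steps_per_chunk * dt, st$x, attr_vec)
    envs[[chunk + 1]] <- env_tbl(chunk * steps_per_chunk * dt, st)
  }

  clip_frac <- clipped / (total_steps * length(labels))
  if (clip_frac > 0.01) {
    warning(
      sprintf(
        "negativity clipping engaged on %.1f%% of steps; consider a smaller dt",
        100 * clip_frac
      ),
      call. = FALSE
    )
  }

  out <- structure(
    list(
      model_id = model_id, mode = mode, variant = variant,
      snapshots = dplyr::bind_rows(snaps), env = dplyr::bind_rows(envs),
      final = st,
      clipped = clipped, clip_fraction = clip_frac, divisions = divisions,
      config = list(
        model_id = model_id, mode = mode, variant = variant,
        n_cells = n_cells, t_final = t_final, dt = dt,
        noise = noise, C_ext = C_ext, precursor = precursor,
        copy_scheme = copy_scheme, k = k, k_max = k_max, P = P,
        snapshot_every = snapshot_every, seed = seed, division = division,
        resample = resample
      )
    ),
    class = "population_sim"
  )

  readout <- if (model_id == "pcf10") "B" else "X"
  stat <- tryCatch(
    stationarity_check(out, variable = readout),
    error = function(e) NULL
  )
  out$stationary <- if (is.null(stat)) NA else stat$stationary
  if (isFALSE(out$stationary)) {
    warning("population readout not stationary over the final windows; ",
      "consider a longer horizon",
      call. = FALSE
    )
  }
  out
}

#' Simulate the population balance model (shared environment)
#'
#' Advances `n_cells` chemical-Langevin sample-path cells coupled through
#' one shared extracellular inhibitor balance: each step the cells move with
#' the environment frozen, then the environment moves with the ensemble
#' -average secretion/uptake (the empirical-mean surrogate for the
#' population-balance expectation), then divisions resample the constant
#' -size ensemble.
#'
#' The default initial condition is the deterministic zero-pheromone
#' off-state (per copy-number class) plus one noisy burn-in interval for the
#' pCF10 model, and the empty-cell resting balance (`I_ext = k_i/k_u`) for
#' the toy model.
#'
#' @param theta `parameter_set` (`"pcf10"` or `"toy"`).
#' @param variant PrgB production variant (pCF10).
#' @param n_cells Ensemble size.
#' @param t_final Simulation horizon (s for pCF10, min for toy).
#' @param dt Euler-Maruyama step (default 1 s pCF10, 0.01 min toy).
#' @param noise Noise mask: a name understood by [pcf10_noise_mask()] /
#'   [toy_noise_mask()] or a logical vector per species.
#' @param C_ext Extracellular pheromone concentration (nM, pCF10).
#' @param precursor Add-in precursor level (toy).
#' @param copy_scheme `"fixed"` or `"heterogeneous"` (pCF10).
#' @param k,k_max Copy number / ceiling for the two schemes.
#' @param P Per-subpopulation membrane protein levels (toy); recycled over
#'   cells. `NULL` = the packaged value for every cell.
#' @param init Optional initial ensemble (a `population_sim`'s `$final`
#'   element, or a list with `x`, `k`/`P`, `I_ext`).
#' @param snapshot_every Snapshot interval (default `t_final / 20`).
#' @param seed Integer seed; identical seeds give bit-identical runs.
#' @param division Enable division/resampling (default TRUE).
#' @param resample Victim scope for the constant-number discard:
#'   `"within_class"` (default for heterogeneous runs) discards within the
#'   parent's copy-number class / subpopulation, preserving the class
#'   marginal that the population balance holds fixed; `"uniform"` is the
#'   plain uniformly-chosen victim.
#' @return A `population_sim` object; [tidy()] gives the long snapshot
#'   table, [glance()] a one-row run summary, `$env` the environment
#'   trajectory.
#' @export
simulate_pbm <- function(theta, variant = c("sigmoid", "linear"),
                         n_cells = 1000, t_final = NULL, dt = NULL,
                         noise = if (theta$model_id == "pcf10") "protein" else "all",
                         C_ext = 0, precursor = 10,
                         copy_scheme = c("fixed", "heterogeneous"), k = 5,
                         k_max = 9, P = NULL, init = NULL,
                         snapshot_every = NULL, seed = 1L, division = TRUE,
                         resample = NULL) {
  variant <- match.arg(variant)
  copy_scheme <- match.arg(copy_scheme)
  if (is.null(t_final)) t_final <- if (theta$model_id == "pcf10") 2e5 else 2e3
  if (is.null(dt)) dt <- if (theta$model_id == "pcf10") 1 else 0.01
  .simulate_engine(theta, "pbm", variant, n_cells, t_final, dt, noise, C_ext,
    precursor, copy_scheme, k, k_max, P, init, snapshot_every, seed,
    division, resample
  )
}

#' Simulate the isolated single-cell stochastic model
#'
#' Identical to [simulate_pbm()] except that every cell carries a private
#' copy of the extracellular inhibitor advanced by its own stochastic
#' exchange only: cells are statistically independent, and the environment
#' a cell experiences is its singular one. For one cell the two couplings
#' coincide.
#'
#' @inheritParams simulate_pbm
#' @return A `population_sim` object.
#' @export
simulate_single_cells <- function(theta, variant = c("sigmoid", "linear"),
                                  n_cells = 1000, t_final = NULL, dt = NULL,
                                  noise = if (theta$model_id == "pcf10") "protein" else "all",
                                  C_ext = 0, precursor = 10,
                                  copy_scheme = c("fixed", "heterogeneous"),
                                  k = 5, k_max = 9, P = NULL, init = NULL,
                                  snapshot_every = NULL, seed = 1L,
                                  division = TRUE, resample = NULL) {
  variant <- match.arg(variant)
  copy_scheme <- match.arg(copy_scheme)
  if (is.null(t_final)) t_final <- if (theta$model_id == "pcf10") 2e5 else 2e3
  if (is.null(dt)) dt <- if (theta$model_id == "pcf10") 1 else 0.01
  .simulate_engine(theta, "single_cell", variant, n_cells, t_final, dt, noise,
    C_ext, precursor, copy_scheme, k, k_max, P, init, snapshot_every, seed,
    division, resample
  )
}

#' @export
print.population_sim <- function(x, ...) {
  cat(
    "<population_sim>", x$model_id, x$mode, "-", x$config$n_cells,
    "cells to t =", x$config$t_final, "\n"
  )
  print(glance(x))
  invisible(x)
}

#' @rdname simulate_pbm
#' @param x A `population_sim`.
#' @param ... Unused.
#' @method tidy population_sim
#' @export
tidy.population_sim <- function(x, ...) {
  x$snapshots
}

#' @rdname simulate_pbm
#' @method glance population_sim
#' @export
glance.population_sim <- function(x, ...) {
  readout <- if (x$model_id == "pcf10") "B" else "X"
  fin <- x$snapshots[x$snapshots$t == max(x$snapshots$t), ][[readout]]
  tibble::tibble(
    model_id = x$model_id, mode = x$mode, n_cells = x$config$n_cells,
    t_final = x$config$t_final,
    readout_mean = mean(fin), readout_sd = sd(fin),
    clip_fraction = x$clip_fraction, divisions = x$divisions,
    stationary = x$stationary
  )
}
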