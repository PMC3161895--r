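# Deterministic steady states of the coupled cell + environment system.
#
# The environment is closed self-consistently: the extracellular inhibitor is
# an unknown solved jointly with the intracellular state, its balance taken
# at dI_ext/dt = 0. Roots are located by multistart damped Newton in
# log-space (which enforces positivity and matches the log-uniform start
# sampling), with finite-difference Jacobians, and classified by the
# eigenvalues of the coupled Jacobian.

# Right-hand side of the closed (cell + I_ext) system as a function of the
# full unknown vector z.
.closed_system <- function(theta, control, variant = "sigmoid", k = 5,
                           P = NULL) {
  if (theta$model_id == "pcf10") {
    mu <- theta[["mu_hat"]]
    K45 <- theta[["K_4,5"]]
    function(z) {
      env <- list(I_ext = z[7], C_ext = control)
      c(
        pcf10_drift(z[1:6], env, theta, variant, k),
        pcf10_env_source(z[1:6], env, theta) - (K45 + mu) * z[7]
      )
    }
  } else {
    if (is.null(P)) P <- theta[["P"]]
    function(z) {
      env <- list(I_ext = z[4])
      c(
        toy_drift(z[1:3], env, theta, precursor = control, P = P),
        toy_env_source(z[1:3], env, theta)
      )
    }
  }
}

# Damped Newton in u = log(z). Returns z at the root or NULL.
.newton_log <- function(fn, z0, tol = 1e-11, max_iter = 80) {
  u <- log(pmax(z0, 1e-12))
  m <- length(u)
  fval <- tryCatch(fn(exp(u)), error = function(e) NULL)
  if (is.null(fval) || any(!is.finite(fval))) {
    return(NULL)
  }
  for (iter in seq_len(max_iter)) {
    nf <- max(abs(fval))
    if (nf < tol) break
    J <- matrix(0, m, m)
    h <- 1e-6
    for (j in seq_len(m)) {
      up <- u
      up[j] <- up[j] + h
      fp <- tryCatch(fn(exp(up)), error = function(e) rep(NA_real_, m))
      J[, j] <- (fp - fval) / h
    }
    if (any(!is.finite(J))) {
      return(NULL)
    }
    step <- tryCatch(solve(J, -fval), error = function(e) NULL)
    if (is.null(step)) {
      return(NULL)
    }
    step <- pmin(pmax(step, -5), 5) # trust region in log units
    lambda <- 1
    improved <- FALSE
    for (half in 1:25) {
      u_try <- u + lambda * step
      f_try <- tryCatch(fn(exp(u_try)), error = function(e) NULL)
      if (!is.null(f_try) && all(is.finite(f_try)) &&
        max(abs(f_try)) < nf) {
        u <- u_try
        fval <- f_try
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      return(NULL)
    }
  }
  if (max(abs(fval)) < tol) exp(u) else NULL
}

# Finite-difference Jacobian of fn at z (linear space, relative step).
.fd_jacobian <- function(fn, z, rel = 1e-6) {
  m <- length(z)
  f0 <- fn(z)
  J <- matrix(0, m, m)
  for (j in seq_len(m)) {
    h <- rel * max(abs(z[j]), 1e-8)
    zp <- z
    zp[j] <- zp[j] + h
    J[, j] <- (fn(zp) - f0) / h
  }
  J
}

.dedupe_roots <- function(roots, radius = 1e-4) {
  keep <- list()
  for (r in roots) {
    dup <- FALSE
    for (s in keep) {
      if (max(abs(r - s) / pmax(abs(r), abs(s), 1)) < radius) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, list(r))
  }
  keep
}

#' Locate and classify the steady states of the coupled cell+environment system
#'
#' Multistart root finding (log-uniform starts over `search_box`, damped
#' Newton with finite-difference Jacobians) for the deterministic single-cell
#' model closed with its extracellular inhibitor balance at equilibrium.
#' Roots are deduplicated (relative max-norm radius 1e-4) and classified by
#' the real parts of the coupled Jacobian's eigenvalues: stable (all
#' `Re < -1e-10`), unstable (some `Re > 1e-10`), marginal otherwise.
#'
#' @param theta `parameter_set` (`"pcf10"` or `"toy"`).
#' @param control Control value: extracellular pheromone `C_ext` (nM) for
#'   pCF10, add-in precursor level for the toy model.
#' @param variant PrgB production variant (pCF10 only).
#' @param k Plasmid copy number (pCF10 only).
#' @param P Membrane protein level (toy only; default Table value).
#' @param n_starts Number of multistart points (default 200).
#' @param tol Newton residual tolerance; every reported state satisfies
#'   `max(abs(drift)) < tol`.
#' @param search_box Two-element positive vector `c(lo, hi)`: log-uniform
#'   sampling range for every coordinate.
#' @param seed Integer seed for the multistart sampling (deterministic
#'   census).
#' @return A `steady_state_census` object; [tidy()] gives one row per state
#'   with its coordinates, `I_ext`, `stability` and leading eigenvalue real
#'   part; [glance()] gives counts. An empty census (no root found) is
#'   returned with a diagnostic attribute, not an error.
#' @export
find_steady_states <- function(theta, control, variant = c("sigmoid", "linear"),
                               k = 5, P = NULL, n_starts = 200, tol = 1e-10,
                               search_box = c(1e-6, 1e4), seed = 1L) {
  variant <- match.arg(variant)
  fn <- .closed_system(theta, control, variant, k, P)
  m <- if (theta$model_id == "pcf10") 7L else 4L
  labels <- if (theta$model_id == "pcf10") {
    c(.pcf10_state_labels, "I_ext")
  } else {
    c(.toy_state_labels, "I_ext")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  starts <- matrix(
    exp(runif(n_starts * m, log(search_box[1]), log(search_box[2]))),
    nrow = m
  )

  roots <- list()
  for (i in seq_len(ncol(starts))) {
    r <- .newton_log(fn, starts[, i], tol = tol)
    if (!is.null(r)) roots <- c(roots, list(r))
  }
  roots <- .dedupe_roots(roots)

  states <- lapply(roots, function(z) {
    J <- .fd_jacobian(fn, z)
    ev <- eigen(J, only.values = TRUE)$values
    lead <- max(Re(ev))
    stability <- if (all(Re(ev) < -1e-10)) {
      "stable"
    } else if (lead > 1e-10) {
      "unstable"
    } else {
      "marginal"
    }
    list(z = z, stability = stability, leading_re = lead)
  })

  tab <- if (length(states) == 0) {
    tibble::as_tibble(c(
      setNames(
        rep(list(numeric(0)), length(labels)),
        labels
      ),
      list(stability = character(0), leading_re = numeric(0))
    ))
  } else {
    dplyr::bind_rows(lapply(states, function(s) {
      row <- c(as.list(setNames(s$z, labels)),
        stability = s$stability, leading_re = s$leading_re
      )
      tibble::as_tibble(row)
    }))
  }
  structure(
    list(
      control_value = control, states = tab, model_id = theta$model_id,
      variant = variant, k = k,
      diagnostic = if (length(states) == 0) {
        "no root found in search box"
      } else {
        NA_character_
      }
    ),
    class = "steady_state_census"
  )
}

#' @export
print.steady_state_census <- function(x, ...) {
  cat(
    "<steady_state_census>", x$model_id, "at control =", x$control_value,
    "\n"
  )
  if (nrow(x$states) == 0) cat(" ", x$diagnostic, "\n") else print(x$states)
  invisible(x)
}

#' Steady-state census over a grid of the control variable
#'
#' Runs [find_steady_states()] at every point of a monotone control grid
#' (extracellular pheromone for pCF10, precursor for the toy model) and
#' reports the maximal contiguous bistable interval (grid points with at
#' least two stable states), possibly empty.
#'
#' @inheritParams find_steady_states
#' @param control_grid Monotone numeric grid of control values.
#' @return A `bifurcation_scan` object; [tidy()] gives one row per
#'   (control value, state); [glance()] one row per control value with
#'   stable/unstable counts plus the bistable interval.
#' @export
bifurcation_scan <- function(theta, control_grid,
                             variant = c("sigmoid", "linear"), k = 5,
                             P = NULL, n_starts = 80, tol = 1e-10,
                             search_box = c(1e-6, 1e4), seed = 1L) {
  variant <- match.arg(variant)
  if (is.unsorted(control_grid) && is.unsorted(rev(control_grid))) {
    stop("control_grid must be monotone", call. = FALSE)
  }
  censuses <- lapply(control_grid, function(cv) {
    find_steady_states(theta, cv,
      variant = variant, k = k, P = P,
      n_starts = n_starts, tol = tol, search_box = search_box, seed = seed
    )
  })
  n_stable <- vapply(censuses, function(cen) {
    sum(cen$states$stability == "stable")
  }, integer(1))
  bistable <- n_stable >= 2
  interval <- c(NA_real_, NA_real_)
  if (any(bistable)) {
    runs <- rle(bistable)
    ends <- cumsum(runs$lengths)
    starts_i <- ends - runs$lengths + 1
    wi <- which(runs$values)
    longest <- wi[which.max(runs$lengths[wi])]
    interval <- c(
      control_grid[starts_i[longest]],
      control_grid[ends[longest]]
    )
  }
  structure(
    list(
      censuses = censuses, control_grid = control_grid,
      bistable_interval = interval, model_id = theta$model_id,
      variant = variant, k = k
    ),
    class = "bifurcation_scan"
  )
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(
    "<bifurcation_scan>", x$model_id, "over", length(x$control_grid),
    "control values\n"
  )
  print(glance(x))
  invisible(x)
}

#' On/off PrgB threshold from the model's own steady-state structure
#'
#' When the scan is bistable anywhere, the log-scale midpoint between the
#' lowest and highest stable PrgB coordinates over the bistable region; when
#' monostable throughout, the geometric midpoint between the lowest and
#' highest stable PrgB across the whole control grid. Ties the "on state"
#' label to the model rather than to an arbitrary constant.
#'
#' @param scan A `bifurcation_scan` for the pCF10 model.
#' @return Scalar threshold (nM PrgB).
#' @export
on_off_threshold <- function(scan) {
  stopifnot(inherits(scan, "bifurcation_scan"), scan$model_id == "pcf10")
  tab <- tidy(scan)
  stable <- tab[tab$stability == "stable", ]
  if (nrow(stable) == 0) stop("scan has no stable states", call. = FALSE)
  per_point <- table(stable$control_value)
  bistable_cv <- as.numeric(names(per_point)[per_point >= 2])
  use <- if (length(bistable_cv) > 0) {
    stable[stable$control_value %in% bistable_cv, ]
  } else {
    stable
  }
  exp(mean(log(range(use$B))))
}
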