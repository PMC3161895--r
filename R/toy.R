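# Toy gene circuit: precursor + membrane protein -> intracellular signal S;
# xp gene -> product X, xi gene -> (secreted) inhibitor, both modulated by a
# DNA configuration factor set by whether signal or inhibitor dominates; fast
# irreversible S + I annihilation; inhibitor pooled extracellularly.
# State (arb.u./volume): S, I, X. Time in minutes.

.toy_state_labels <- c("S", "I", "X")

#' DNA configuration factors of the toy circuit
#'
#' When the signal dominates (`S > I`) the xp gene is activated and the xi
#' gene repressed: factors `(theta_p, theta_i) = (2.4, 0.5)`. Otherwise —
#' inhibitor dominating, ties, or the empty state — the baseline `(1, 1)`.
#' The fast irreversible annihilation makes the `S = I` boundary
#' measure-zero, so the tie-break is immaterial to the dynamics.
#'
#' @param S,I Intracellular signal / inhibitor (arb.u./volume), nonnegative.
#' @param theta `parameter_set` for the toy model.
#' @return List with vectors `h_p` and `h_i`.
#' @export
configuration_factors <- function(S, I, theta) {
  on <- S > I
  list(
    h_p = ifelse(on, theta[["theta_p"]], 1),
    h_i = ifelse(on, theta[["theta_i"]], 1)
  )
}

#' Deterministic drift of the toy single-cell circuit
#'
#' `dS/dt = k_1 P F - gamma S I - (k_dS + mu) S`;
#' `dI/dt = k_u I_ext - gamma S I - (k_dI + mu) I`;
#' `dX/dt = k_p h_p(S, I) - (k_dX + mu) X`,
#' with `F` the constant add-in precursor concentration and `gamma` the
#' large finite annihilation rate standing in for the irreversible
#' signal-inhibitor binding.
#'
#' @param state Numeric vector `(S, I, X)` or 3-row matrix (cells in columns).
#' @param env List with `I_ext` (extracellular inhibitor, arb.u./volume).
#' @param theta `parameter_set` for the toy model.
#' @param precursor Add-in signal precursor concentration (default 10).
#' @param P Membrane protein level, scalar or per-cell (default the packaged
#'   value `theta[["P"]]`).
#' @return Derivative in the same shape as `state` (arb.u./volume/min).
#' @export
toy_drift <- function(state, env, theta, precursor = 10, P = theta[["P"]]) {
  x <- if (is.matrix(state)) state else matrix(state, nrow = 3)
  if (nrow(x) != 3) stop("toy state must have 3 species", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite state", call. = FALSE)
  if (any(x < 0)) stop("negative concentration in state", call. = FALSE)
  h <- configuration_factors(x[1, ], x[2, ], theta)
  ann <- theta[["gamma"]] * x[1, ] * x[2, ]
  mu <- theta[["mu"]]
  d <- rbind(
    theta[["k_1"]] * P * precursor - ann - (theta[["k_dS"]] + mu) * x[1, ],
    theta[["k_u"]] * env$I_ext - ann - (theta[["k_dI"]] + mu) * x[2, ],
    theta[["k_p"]] * h$h_p - (theta[["k_dX"]] + mu) * x[3, ]
  )
  if (is.matrix(state)) d else drop(d)
}

#' Extracellular inhibitor balance of the toy circuit
#'
#' The system volume is fixed and cells occupy the volume fraction
#' `phi = n_density * V_cell`, so
#' `dI_ext/dt = phi * (k_i h_i(S, I) - k_u I_ext)` aggregated over cells
#' (mean of `h_i` for an ensemble). No dilution term, unlike the pCF10
#' environment. `n_density = 0` leaves only the (zero) cellular exchange.
#'
#' @inheritParams toy_drift
#' @param n_density_frac Volume fraction `n_density * V_cell` occupied by
#'   cells (default `theta[["phi_cell"]]`). Scales both exchange terms.
#' @return Per-cell dI_ext/dt contribution (vector for matrix input).
#' @export
toy_env_source <- function(state, env, theta,
                           n_density_frac = theta[["phi_cell"]]) {
  if (n_density_frac < 0) stop("cell density must be nonnegative", call. = FALSE)
  x <- if (is.matrix(state)) state else matrix(state, nrow = 3)
  h <- configuration_factors(x[1, ], x[2, ], theta)
  n_density_frac * (theta[["k_i"]] * h$h_i - theta[["k_u"]] * env$I_ext)
}

# CLE diffusion amplitudes for the toy model. Unit convention: Table 3's
# "volume per cell 1E-15 (volume)" is read as 1 arb.u./volume == 1 molecule
# per 1e-15 volume, so Omega = V_cell / 1e-15 molecules per concentration
# unit. Annihilation appears as an independent channel on S and I.
.toy_noise_amplitudes <- function(state, env, theta, precursor, P, mask) {
  x <- if (is.matrix(state)) state else matrix(state, nrow = 3)
  omega <- theta[["V_cell"]] / 1e-15
  h <- configuration_factors(x[1, ], x[2, ], theta)
  ann <- theta[["gamma"]] * x[1, ] * x[2, ]
  rates <- rbind(
    theta[["k_1"]] * P * precursor + ann + theta[["k_dS"]] * x[1, ],
    theta[["k_u"]] * env$I_ext + ann + theta[["k_dI"]] * x[2, ],
    theta[["k_p"]] * h$h_p + theta[["k_dX"]] * x[3, ]
  )
  amp <- sqrt(rates / omega) * mask
  if (is.matrix(state)) amp else drop(amp)
}

#' Noise mask helper for the toy model
#'
#' @param which `"all"` (default: every species fluctuates) or `"none"`.
#' @return Logical vector over `(S, I, X)`.
#' @export
toy_noise_mask <- function(which = c("all", "none")) {
  which <- match.arg(which)
  setNames(rep(which == "all", 3), .toy_state_labels)
}
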