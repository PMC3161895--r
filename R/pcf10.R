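# pCF10 single-cell reaction network.
#
# State vector (nM): Q_S, Q_L, AntiQ, I_i (intracellular iCF10),
# C_i (intracellular cCF10), B (PrgB). Transcription of prgQ and Anti-Q is a
# mixture of loop-form and open-form rates weighted by the repressed DNA
# fraction; nascent transcript is partitioned into Q_S (Anti-Q-bound) versus
# Q_L (free) by the Anti-Q binding equilibrium K_3,5, and each Q_S made
# consumes one Anti-Q (antisense titration). Transcription scales linearly
# with plasmid copy number k.

.pcf10_state_labels <- c("Q_S", "Q_L", "AntiQ", "I_i", "C_i", "B")

#' Fraction of plasmid DNA in the looped (repressed) configuration
#'
#' Competitive exchange between the iCF10-PrgX looped complex and
#' cCF10-PrgX-opened DNA with binding order `n`:
#' \deqn{f_{loop} = \frac{1}{1 + K_{3,8}\,(C_i/I_i)^n}.}
#' With no intracellular inhibitor there is no iCF10-PrgX tetramer and hence
#' no loop (`f = 0`); with inhibitor but no pheromone the loop saturates
#' (`f = 1`). `f` is nondecreasing in `I_i` and nonincreasing in `C_i`.
#'
#' The printed source typesets the binding expression as an image; this
#' RECONSTRUCTED form satisfies every stated property of it (monotonicity,
#' limits, order-4 dependence, dimensionless K_3,8) and reproduces the
#' published steady-state and population behaviour. It is the single largest
#' reconstruction risk of the package; see the methods vignette.
#'
#' @param I_i Intracellular inhibitor iCF10 (nM), nonnegative.
#' @param C_i Intracellular pheromone cCF10 (nM), nonnegative.
#' @param theta `parameter_set` supplying `K_3,8` and `n`.
#' @return Fraction in \[0, 1\]; vectorized over `I_i`/`C_i`.
#' @export
repressed_dna_fraction <- function(I_i, C_i, theta) {
  if (any(I_i < 0) || any(C_i < 0)) {
    stop("repressed_dna_fraction: concentrations must be nonnegative",
      call. = FALSE
    )
  }
  K38 <- theta[["K_3,8"]]
  n <- theta[["n"]]
  # I_i = 0: no tetramer, no loop, for any C_i (including C_i = 0).
  # C_i = 0, I_i > 0: nothing to exchange the loop away, f = 1.
  out <- ifelse(I_i == 0, 0, 1 / (1 + K38 * (C_i / I_i)^n))
  pmin(pmax(out, 0), 1)
}

#' PrgB production rate
#'
#' Sigmoid variant: basal rate plus a logistic switch in `Q_L` centred at the
#' threshold `K_1,8` with steepness `K_3,9`,
#' \eqn{K_{1,7} + K_{1,9} / (1 + e^{-K_{3,9}(Q_L - K_{1,8})})}; used for the
#' steady-state and copy-number-heterogeneity studies. Linear variant:
#' \eqn{K_{1,5} Q_L}; used for the bistability-versus-bimodality contrast.
#'
#' @param Q_L Long prgQ transcript concentration (nM), nonnegative.
#' @param theta `parameter_set`.
#' @param variant `"sigmoid"` or `"linear"`.
#' @return Production rate (nM/s), vectorized over `Q_L`.
#' @export
prgb_production <- function(Q_L, theta, variant = c("sigmoid", "linear")) {
  variant <- match.arg(variant)
  if (any(Q_L < 0)) stop("Q_L must be nonnegative", call. = FALSE)
  if (variant == "linear") {
    theta[["K_1,5"]] * Q_L
  } else {
    theta[["K_1,7"]] +
      theta[["K_1,9"]] / (1 + exp(-theta[["K_3,9"]] * (Q_L - theta[["K_1,8"]])))
  }
}

# Shared algebra of the transcription block: loop fraction, total prgQ and
# Anti-Q transcription (copy-number proportional), Anti-Q-bound fraction of
# nascent transcript. Vectorized over cells (state given as columns).
.pcf10_transcription <- function(I_i, C_i, AntiQ, k, theta) {
  f <- repressed_dna_fraction(I_i, C_i, theta)
  b <- theta[["K_3,5"]] * AntiQ / (1 + theta[["K_3,5"]] * AntiQ)
  list(
    f = f,
    b = b,
    T_Q = k * (theta[["K_1,1"]] * f + theta[["K_1,2"]] * (1 - f)),
    T_A = k * (theta[["K_1,3"]] * f + theta[["K_1,4"]] * (1 - f))
  )
}

#' Deterministic drift of the pCF10 single-cell network
#'
#' Time derivative (nM/s) of `(Q_S, Q_L, AntiQ, I_i, C_i, B)` for a cell with
#' plasmid copy number `k` in environment `env`. Each species carries
#' production, first-order degradation (`K_4,*`) and growth dilution
#' (`mu_hat`). Inhibitor import is `K_2,6 * I_ext`, pheromone import
#' `K_2,8 * C_ext`.
#'
#' @param state Numeric vector of the 6 species (nM), or a 6-row matrix with
#'   one column per cell.
#' @param env List with `I_ext` and `C_ext` (nM).
#' @param theta `parameter_set` for the pCF10 model.
#' @param variant PrgB production variant, see [prgb_production()].
#' @param k Plasmid copy number (positive integer), scalar or per-cell.
#' @return Derivative in the same shape as `state`.
#' @export
pcf10_drift <- function(state, env, theta, variant = c("sigmoid", "linear"),
                        k = 5) {
  variant <- match.arg(variant)
  x <- if (is.matrix(state)) state else matrix(state, nrow = 6)
  if (nrow(x) != 6) stop("pcf10 state must have 6 species", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite state", call. = FALSE)
  if (any(x < 0)) stop("negative concentration in state", call. = FALSE)
  if (any(k < 1)) stop("plasmid copy number must be >= 1", call. = FALSE)
  tr <- .pcf10_transcription(x[4, ], x[5, ], x[3, ], k, theta)
  mu <- theta[["mu_hat"]]
  d <- rbind(
    tr$T_Q * tr$b - (theta[["K_4,1"]] + mu) * x[1, ],
    tr$T_Q * (1 - tr$b) - (theta[["K_4,2"]] + mu) * x[2, ],
    tr$T_A - tr$T_Q * tr$b - (theta[["K_4,3"]] + mu) * x[3, ],
    theta[["K_2,6"]] * env$I_ext - (theta[["K_4,6"]] + mu) * x[4, ],
    theta[["K_2,8"]] * env$C_ext - (theta[["K_4,8"]] + mu) * x[5, ],
    prgb_production(x[2, ], theta, variant) - (theta[["K_4,9"]] + mu) * x[6, ]
  )
  if (is.matrix(state)) d else drop(d)
}

#' Per-cell contribution to the extracellular inhibitor balance
#'
#' Returns secretion minus uptake in nM/s of extracellular concentration:
#' iCF10 is translated from both prgQ transcripts and secreted directly,
#' `K_1,6 * (Q_S + Q_L)`, and taken up at `K_2,6 * I_ext`. With the cell
#' volume fraction held at 0.5 the cellular and extracellular volumes are
#' equal, so molar exchange maps one-to-one between the compartments.
#' Extracellular degradation (`K_4,5`) and the growth dilution term are
#' applied at the aggregate level by the environment integrator.
#'
#' @inheritParams pcf10_drift
#' @return Scalar (or per-cell vector) dI_ext/dt contribution.
#' @export
pcf10_env_source <- function(state, env, theta) {
  x <- if (is.matrix(state)) state else matrix(state, nrow = 6)
  vol_ratio <- theta[["phi_cell"]] / (1 - theta[["phi_cell"]])
  vol_ratio * (theta[["K_1,6"]] * (x[1, ] + x[2, ]) -
    theta[["K_2,6"]] * env$I_ext)
}

# Chemical-Langevin diffusion amplitudes (nM / sqrt(s)) per species.
# Channels: production and first-order degradation of each species; growth
# dilution is volume expansion, not a reaction, and carries no noise.
.pcf10_noise_amplitudes <- function(state, env, theta, variant, k, mask) {
  x <- if (is.matrix(state)) state else matrix(state, nrow = 6)
  omega <- concentration_to_copies(1, theta[["V_cell"]]) # molecules per nM
  tr <- .pcf10_transcription(x[4, ], x[5, ], x[3, ], k, theta)
  rates <- rbind(
    tr$T_Q * tr$b + theta[["K_4,1"]] * x[1, ],
    tr$T_Q * (1 - tr$b) + theta[["K_4,2"]] * x[2, ],
    tr$T_A + tr$T_Q * tr$b + theta[["K_4,3"]] * x[3, ],
    theta[["K_2,6"]] * env$I_ext + theta[["K_4,6"]] * x[4, ],
    theta[["K_2,8"]] * env$C_ext + theta[["K_4,8"]] * x[5, ],
    prgb_production(x[2, ], theta, variant) + theta[["K_4,9"]] * x[6, ]
  )
  amp <- sqrt(rates / omega) * mask
  if (is.matrix(state)) amp else drop(amp)
}

#' Named noise masks for the pCF10 model
#'
#' `"protein"` restricts stochasticity to PrgB (the copy-number
#' heterogeneity study); `"protein_peptides"` adds the two peptides iCF10 and
#' cCF10 (the bistability contrast study); `"all"` and `"none"` as named.
#'
#' @param which One of `"protein"`, `"protein_peptides"`, `"all"`, `"none"`.
#' @return Logical vector over `(Q_S, Q_L, AntiQ, I_i, C_i, B)`.
#' @export
pcf10_noise_mask <- function(which = c("protein", "protein_peptides", "all", "none")) {
  which <- match.arg(which)
  m <- switch(which,
    protein = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    protein_peptides = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    all = rep(TRUE, 6),
    none = rep(FALSE, 6)
  )
  setNames(m, .pcf10_state_labels)
}
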