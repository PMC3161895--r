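# Ito SDE machinery: chemical-Langevin amplitudes and Euler-Maruyama
# integration. The generic R integrator below is the reference kernel (used
# directly for small problems and as the cross-check for the compiled
# ensemble steppers); the hot ensemble loops live in src/steppers.cpp.

#' Chemical-Langevin diffusion amplitudes from reaction-channel rates
#'
#' For a reaction network with stoichiometry matrix `stoich` (species x
#' channels) and per-channel macroscopic rates (concentration/time), the
#' concentration-space chemical Langevin equation gives each species the
#' diffusion amplitude
#' \deqn{a_s = \sqrt{\sum_c \nu_{sc}^2 \, r_c / \Omega},}
#' where `Omega` is the molecules-per-concentration-unit factor of the cell
#' volume (`N_A V` scaled to the concentration unit). Masked-off species
#' have identically zero amplitude.
#'
#' @param stoich Species-by-channels stoichiometry matrix.
#' @param rates Per-channel rates (nonnegative, length = ncol(stoich)).
#' @param volume Cell volume in litres.
#' @param mask Logical per-species noise mask (default all on).
#' @param conc_unit `"nM"` (default; `Omega = 1e-9 N_A V`) or `"count"`
#'   (`Omega = V / 1e-15`, the toy model's arbitrary-unit convention).
#' @return Per-species amplitude vector (concentration / sqrt(time)).
#' @export
langevin_amplitudes <- function(stoich, rates, volume,
                                mask = rep(TRUE, nrow(stoich)),
                                conc_unit = c("nM", "count")) {
  conc_unit <- match.arg(conc_unit)
  if (any(rates < 0)) stop("channel rates must be nonnegative", call. = FALSE)
  if (volume <= 0) stop("volume must be positive", call. = FALSE)
  omega <- if (conc_unit == "nM") {
    concentration_to_copies(1, volume)
  } else {
    volume / 1e-15
  }
  amp <- sqrt(as.numeric(stoich^2 %*% rates) / omega)
  amp * as.numeric(mask)
}

#' Euler-Maruyama integration of an Ito SDE
#'
#' Fixed-step explicit Euler-Maruyama with diagonal noise:
#' `x <- x + drift_fn(x, t) dt + noise_fn(x, t) sqrt(dt) N(0,1)`,
#' clipping negative excursions to zero after each step (clip activations
#' are counted and reported; frequent clipping at the chosen `dt` warrants a
#' smaller step). Bit-reproducible for a fixed seed. With `noise_fn = NULL`
#' (or an all-zero amplitude) the path is the explicit-Euler deterministic
#' solution.
#'
#' @param drift_fn `function(x, t)` returning dx/dt.
#' @param noise_fn `function(x, t)` returning per-species diffusion
#'   amplitudes, or `NULL` for a deterministic path.
#' @param x0 Initial state vector (named names are carried through).
#' @param t_span `c(t0, t1)`.
#' @param dt Positive step size.
#' @param seed Optional integer seed (`set.seed` applied locally).
#' @param record_every Record every `record_every`-th step (default 1).
#' @param clip_negative Clip to zero after each step (default TRUE).
#' @return A tibble with `t`, one column per state variable, and attributes
#'   `clipped` (number of clipped components) and `n_steps`.
#' @examples
#' ou <- integrate_sde(
#'   function(x, t) -0.5 * x, function(x, t) 0.3, x0 = c(x = 1),
#'   t_span = c(0, 10), dt = 0.01, seed = 1
#' )
#' @export
integrate_sde <- function(drift_fn, noise_fn, x0, t_span, dt, seed = NULL,
                          record_every = 1L, clip_negative = TRUE) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  n_steps <- ceiling((t_span[2] - t_span[1]) / dt)
  m <- length(x0)
  labels <- if (is.null(names(x0))) paste0("x", seq_len(m)) else names(x0)
  n_rec <- floor(n_steps / record_every) + 1L
  out <- matrix(NA_real_, nrow = n_rec, ncol = m + 1)
  x <- as.numeric(x0)
  t <- t_span[1]
  out[1, ] <- c(t, x)
  clipped <- 0L
  rec <- 1L
  sdt <- sqrt(dt)
  for (step in seq_len(n_steps)) {
    d <- drift_fn(x, t)
    if (any(!is.finite(d))) {
      stop(
        "non-finite drift at step ", step, " (species ",
        paste(labels[!is.finite(d)], collapse = ", "), ")",
        call. = FALSE
      )
    }
    x_new <- x + d * dt
    if (!is.null(noise_fn)) {
      a <- noise_fn(x, t)
      x_new <- x_new + a * sdt * rnorm(m)
    }
    if (any(!is.finite(x_new))) {
      stop(
        "non-finite state at step ", step, " (species ",
        paste(labels[!is.finite(x_new)], collapse = ", "), ")",
        call. = FALSE
      )
    }
    if (clip_negative && any(x_new < 0)) {
      clipped <- clipped + sum(x_new < 0)
      x_new <- pmax(x_new, 0)
    }
    x <- x_new
    t <- t_span[1] + step * dt
    if (step %% record_every == 0L) {
      rec <- rec + 1L
      out[rec, ] <- c(t, x)
    }
  }
  res <- tibble::as_tibble(setNames(
    as.data.frame(out[seq_len(rec), , drop = FALSE]),
    c("t", labels)
  ))
  attr(res, "clipped") <- clipped
  attr(res, "n_steps") <- n_steps
  res
}
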