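# Packaged experiment recipes: desk-scale reproductions of the study's
# headline figures. Cell counts default to 1000-2000 instead of the
# 30,000-45,000 of the originals (`full = TRUE` restores those); modality
# conclusions are insensitive to ensemble size (the shared-environment
# fluctuation shrinks ~1/N, see the methods vignette).

#' Run a packaged experiment recipe
#'
#' Available recipes:
#' \describe{
#'   \item{`fig3a`}{Steady-state scan of the pCF10 system (Table values,
#'     k = 5, sigmoid PrgB): bistable window.}
#'   \item{`fig3b`}{Same scan with `K_4,2 = K_4,1`: bistability excluded —
#'     one stable state at every grid point.}
#'   \item{`fig4`}{Heterogeneous-copy-number PBM (`K_4,2 = K_4,1 = 0.001`,
#'     sigmoid, protein-only noise) across a pheromone grid: stationary
#'     distribution sweeps off -> bimodal -> all-on. Bimodality without
#'     bistability.}
#'   \item{`fig5`}{Single-cell model versus PBM at 13.5 nM pheromone
#'     (linear PrgB, protein+peptide noise, k = 5): bimodal versus unimodal.
#'     Unimodality despite bistability.}
#'   \item{`fig6`}{PBM initialized from the single-cell bimodal ensemble:
#'     the two modes merge into one.}
#'   \item{`fig8`}{Toy circuit: single-cell model bimodal, PBM unimodal.}
#'   \item{`fig9`}{Toy circuit with the xi-gene configuration factor
#'     neutralized (`theta_i = 1`, no feedback, hence no bistability) and
#'     five membrane-protein subpopulations: bimodal product distribution
#'     from population heterogeneity, across a precursor sweep.}
#' }
#'
#' @param name Recipe name (see Details).
#' @param n_cells Ensemble size (default 1000).
#' @param seed Integer seed.
#' @param full Use the original publication-scale cell counts (slow).
#' @param dt Euler-Maruyama step; default 5 s (pCF10) / 0.01 min (toy) at
#'   desk scale.
#' @return A list of class `pbm_recipe` with the underlying result objects
#'   and a `summary` tibble; most elements are `bifurcation_scan` or
#'   `population_sim` objects with their own `tidy()`/`autoplot()` methods.
#' @export
run_recipe <- function(name = c(
                         "fig3a", "fig3b", "fig4", "fig5", "fig6", "fig8",
                         "fig9"
                       ),
                       n_cells = 1000, seed = 1L, full = FALSE, dt = NULL) {
  name <- match.arg(name)
  th <- load_parameters("pcf10")
  th_nobi <- set_parameters(th, `K_4,2` = 0.001)
  if (full) n_cells <- switch(name,
    fig4 = 45000, fig5 = 30000, fig6 = 30000, fig8 = 30000, fig9 = 35000,
    n_cells
  )
  if (is.null(dt)) dt <- 5

  out <- switch(name,
    fig3a = {
      scan <- bifurcation_scan(th, seq(0, 30, by = 1),
        variant = "sigmoid",
        k = 5, n_starts = 60, seed = seed
      )
      list(
        scan = scan,
        summary = glance(scan)
      )
    },
    fig3b = {
      th_ex <- set_parameters(th, `K_4,2` = th[["K_4,1"]])
      scan <- bifurcation_scan(th_ex, seq(0, 50, by = 2),
        variant = "sigmoid",
        k = 5, n_starts = 60, seed = seed
      )
      list(scan = scan, summary = glance(scan))
    },
    fig4 = {
      grid <- seq(0, 36, by = 3)
      scan <- bifurcation_scan(th_nobi, grid,
        variant = "sigmoid", k = 5,
        n_starts = 40, seed = seed
      )
      thr <- on_off_threshold(scan)
      sims <- lapply(grid, function(C) {
        simulate_pbm(th_nobi,
          variant = "sigmoid", n_cells = n_cells,
          t_final = 2e5, dt = dt, noise = "protein", C_ext = C,
          copy_scheme = "heterogeneous", seed = seed
        )
      })
      summary <- dplyr::bind_rows(lapply(seq_along(grid), function(i) {
        s <- summarize_distribution(sims[[i]], threshold = thr)
        tibble::tibble(
          C_ext = grid[i], fraction_on = s$fraction_on,
          n_modes = s$n_modes, stationary = s$stationary
        )
      }))
      all_on <- summary$C_ext[summary$fraction_on >= 0.99]
      list(
        sims = sims, threshold = thr, summary = summary,
        all_on_concentration = if (length(all_on)) min(all_on) else NA_real_
      )
    },
    fig5 = {
      single <- simulate_single_cells(th,
        variant = "linear",
        n_cells = n_cells, t_final = 2e5, dt = dt,
        noise = "protein_peptides", C_ext = 13.5, copy_scheme = "fixed",
        k = 5, seed = seed
      )
      pbm <- simulate_pbm(th,
        variant = "linear", n_cells = n_cells,
        t_final = 2e5, dt = dt, noise = "protein_peptides", C_ext = 13.5,
        copy_scheme = "fixed", k = 5, seed = seed
      )
      summary <- dplyr::bind_rows(
        dplyr::mutate(glance(summarize_distribution(single)), run = "single_cell"),
        dplyr::mutate(glance(summarize_distribution(pbm)), run = "pbm")
      )
      list(single = single, pbm = pbm, summary = summary)
    },
    fig6 = {
      single <- simulate_single_cells(th,
        variant = "linear",
        n_cells = n_cells, t_final = 2e5, dt = dt,
        noise = "protein_peptides", C_ext = 13.5, copy_scheme = "fixed",
        k = 5, seed = seed
      )
      merged <- simulate_pbm(th,
        variant = "linear", n_cells = n_cells,
        t_final = 2e5, dt = dt, noise = "protein_peptides", C_ext = 13.5,
        copy_scheme = "fixed", k = 5, init = single$final, seed = seed + 1
      )
      summary <- dplyr::bind_rows(
        dplyr::mutate(glance(summarize_distribution(single)), run = "initial_bimodal"),
        dplyr::mutate(glance(summarize_distribution(merged)), run = "pbm_merged")
      )
      list(single = single, merged = merged, summary = summary)
    },
    fig8 = {
      tht <- load_parameters("toy")
      tdt <- if (dt > 0.1) 0.01 else dt
      single <- simulate_single_cells(tht,
        n_cells = n_cells, t_final = 500,
        dt = tdt, seed = seed
      )
      pbm <- simulate_pbm(tht,
        n_cells = n_cells, t_final = 500, dt = tdt,
        seed = seed
      )
      summary <- dplyr::bind_rows(
        dplyr::mutate(glance(summarize_distribution(single)), run = "single_cell"),
        dplyr::mutate(glance(summarize_distribution(pbm)), run = "pbm")
      )
      list(single = single, pbm = pbm, summary = summary)
    },
    fig9 = {
      tht9 <- set_parameters(load_parameters("toy"), theta_i = 1)
      tdt <- if (dt > 0.1) 0.01 else dt
      Psub <- c(2, 4, 6, 10, 14)
      sweep <- c(6, 10, 14, 24)
      sims <- lapply(sweep, function(f) {
        simulate_pbm(tht9,
          n_cells = n_cells, t_final = 500, dt = tdt,
          P = Psub, precursor = f, seed = seed
        )
      })
      summary <- dplyr::bind_rows(lapply(seq_along(sweep), function(i) {
        dplyr::mutate(glance(summarize_distribution(sims[[i]])),
          precursor = sweep[i], .before = 1
        )
      }))
      list(sims = sims, P = Psub, precursor_sweep = sweep, summary = summary)
    }
  )
  structure(c(out, list(name = name, seed = seed, n_cells = n_cells)),
    class = "pbm_recipe"
  )
}

#' @export
print.pbm_recipe <- function(x, ...) {
  cat("<pbm_recipe>", x$name, "(seed", paste0(x$seed, ")"), "\n")
  print(x$summary)
  invisible(x)
}
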