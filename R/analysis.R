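# Population distribution diagnostics: KDE mode counting, on/off fractions,
# stationarity of the snapshot series.

#' Count the modes of a sample distribution
#'
#' Gaussian kernel density estimate (Silverman's bandwidth rule by default)
#' followed by local-maximum detection; a maximum only counts as a mode if
#' its topographic prominence — its density height minus the key saddle
#' separating it from a higher maximum — is at least `min_prominence` times
#' the global density maximum, so shallow KDE ripples on a single hump are
#' not counted. Deterministic for fixed input and invariant under affine
#' rescaling of the samples.
#'
#' @param samples Numeric vector, at least 100 values.
#' @param bandwidth_rule Bandwidth selector passed to [stats::density()]
#'   (default `"nrd0"`, Silverman's rule), or a numeric bandwidth.
#' @param min_prominence Relative prominence floor for a countable mode
#'   (fraction of the global density maximum, default 0.05).
#' @param n_grid Density evaluation grid size.
#' @return A list with `n_modes`, `mode_locations` (sorted) and
#'   `prominences` (same order).
#' @examples
#' count_modes(c(rnorm(500), rnorm(500, 10)))$n_modes # 2
#' @export
count_modes <- function(samples, bandwidth_rule = "nrd0",
                        min_prominence = 0.05, n_grid = 512) {
  if (length(samples) < 100) {
    stop("need at least 100 samples to count modes", call. = FALSE)
  }
  if (sd(samples) == 0) {
    return(list(
      n_modes = 1L, mode_locations = samples[1],
      prominences = Inf
    ))
  }
  d <- density(samples, bw = bandwidth_rule, n = n_grid)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  # include boundary maxima (mass piled at a clipped edge)
  if (y[1] > y[2]) is_max[1] <- TRUE
  if (y[n] > y[n - 1]) is_max[n] <- TRUE
  peaks <- which(is_max)
  if (length(peaks) == 0) peaks <- which.max(y)
  prominence <- vapply(peaks, function(p) {
    hp <- y[p]
    # walk outwards to the nearest strictly higher ground on each side,
    # tracking the lowest point passed; the key saddle is the higher of the
    # two minima, and the global maximum keeps its full height
    left <- y[seq_len(p - 1)]
    right <- if (p < n) y[(p + 1):n] else numeric(0)
    saddle_side <- function(side_rev) {
      # side_rev: densities walking away from the peak
      higher <- which(side_rev > hp)
      if (length(higher) == 0) {
        return(NA_real_)
      }
      min(side_rev[seq_len(higher[1])])
    }
    sl <- saddle_side(rev(left))
    sr <- saddle_side(right)
    if (is.na(sl) && is.na(sr)) {
      return(hp)
    }
    hp - max(sl, sr, na.rm = TRUE)
  }, numeric(1))
  keep <- prominence >= min_prominence * max(y)
  ord <- order(d$x[peaks[keep]])
  list(
    n_modes = sum(keep),
    mode_locations = d$x[peaks[keep]][ord],
    prominences = prominence[keep][ord]
  )
}

#' Fraction of cells in the on state
#'
#' Fraction of samples strictly above `threshold`. See [on_off_threshold()]
#' for the model-derived PrgB threshold convention.
#'
#' @param samples Numeric vector (e.g. final-snapshot PrgB levels).
#' @param threshold Finite threshold.
#' @return Fraction in \[0, 1\]; monotone nonincreasing in `threshold`.
#' @export
fraction_on <- function(samples, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  mean(samples > threshold)
}

#' Sliding-window stationarity check of a snapshot series
#'
#' Splits the per-snapshot summary series (mean and standard deviation of a
#' readout across cells, or a plain numeric series) into `n_windows` equal
#' blocks and requires the relative change of both the windowed mean and the
#' windowed standard deviation between consecutive blocks to stay below
#' `tol`. A pseudo-steady population passes even though single paths keep
#' fluctuating.
#'
#' @param x A `population_sim`, or a numeric vector (one value per
#'   snapshot).
#' @param variable Readout column for a `population_sim` (default PrgB /
#'   product).
#' @param n_windows Number of windows (>= 3).
#' @param tol Relative-change tolerance (default 0.05).
#' @param tail_fraction For a `population_sim`, the trailing fraction of the
#'   snapshot series examined (default 0.6: the leading 40% is treated as
#'   transient).
#' @return List with `stationary` (logical) and `drift` (largest relative
#'   change observed).
#' @export
stationarity_check <- function(x, variable = NULL, n_windows = 4, tol = 0.05,
                               tail_fraction = 0.6) {
  if (n_windows < 3) stop("need at least 3 windows", call. = FALSE)
  if (inherits(x, "population_sim")) {
    if (is.null(variable)) variable <- if (x$model_id == "pcf10") "B" else "X"
    snaps <- x$snapshots
    ts <- sort(unique(snaps$t))
    ts <- ts[ts >= (1 - tail_fraction) * max(ts)]
    mean_series <- vapply(ts, function(tt) mean(snaps[[variable]][snaps$t == tt]), numeric(1))
    sd_series <- vapply(ts, function(tt) sd(snaps[[variable]][snaps$t == tt]), numeric(1))
  } else {
    mean_series <- as.numeric(x)
    sd_series <- NULL
  }
  n <- length(mean_series)
  if (n < n_windows) stop("fewer snapshots than windows", call. = FALSE)
  idx <- split(seq_len(n), cut(seq_len(n), n_windows, labels = FALSE))
  rel_change <- function(series) {
    w <- vapply(idx, function(i) mean(series[i]), numeric(1))
    scale <- max(abs(w), 1e-12)
    max(abs(diff(w))) / scale
  }
  drift <- rel_change(mean_series)
  if (!is.null(sd_series) && any(sd_series > 0)) {
    drift <- max(drift, rel_change(sd_series))
  }
  list(stationary = drift < tol, drift = drift)
}

#' Distribution summary of a population snapshot
#'
#' Histogram, KDE mode count, on-fraction and stationarity flag for one
#' readout of a `population_sim` at a chosen time (default the final
#' snapshot).
#'
#' @param sim A `population_sim`.
#' @param variable Readout column (default PrgB / product).
#' @param threshold On/off threshold; `NULL` skips `fraction_on`.
#' @param at Snapshot time (default last).
#' @param breaks Histogram breaks (passed to [graphics::hist()] logic via
#'   [base::cut()]); default 30 equal bins.
#' @param ... Passed to [count_modes()].
#' @return A `distribution_summary`: list with `n`, `histogram` (tibble of
#'   bin edges and counts), `n_modes`, `mode_locations`, `fraction_on`,
#'   `stationary`.
#' @export
summarize_distribution <- function(sim, variable = NULL, threshold = NULL,
                                   at = NULL, breaks = 30, ...) {
  stopifnot(inherits(sim, "population_sim"))
  if (is.null(variable)) variable <- if (sim$model_id == "pcf10") "B" else "X"
  ts <- unique(sim$snapshots$t)
  if (is.null(at)) at <- max(ts)
  samples <- sim$snapshots[[variable]][sim$snapshots$t == at]
  edges <- seq(min(samples), max(samples), length.out = breaks + 1)
  if (min(samples) == max(samples)) edges <- c(min(samples) - 0.5, max(samples) + 0.5)
  counts <- tabulate(
    findInterval(samples, edges, rightmost.closed = TRUE),
    nbins = length(edges) - 1
  )
  modes <- count_modes(samples, ...)
  structure(
    list(
      n = length(samples),
      variable = variable, at = at,
      histogram = tibble::tibble(
        lower = edges[-length(edges)], upper = edges[-1], count = counts
      ),
      n_modes = modes$n_modes, mode_locations = modes$mode_locations,
      fraction_on = if (is.null(threshold)) NA_real_ else fraction_on(samples, threshold),
      threshold = if (is.null(threshold)) NA_real_ else threshold,
      stationary = sim$stationary
    ),
    class = "distribution_summary"
  )
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(
    "<distribution_summary>", x$variable, "at t =", x$at, ": n =", x$n,
    "\n  modes:", x$n_modes, "at",
    paste(signif(x$mode_locations, 4), collapse = ", "), "\n"
  )
  if (!is.na(x$fraction_on)) {
    cat("  fraction on (>", signif(x$threshold, 4), "):", x$fraction_on, "\n")
  }
  invisible(x)
}

#' @rdname summarize_distribution
#' @param x A `distribution_summary`.
#' @param ... Unused.
#' @method glance distribution_summary
#' @export
glance.distribution_summary <- function(x, ...) {
  tibble::tibble(
    variable = x$variable, at = x$at, n = x$n, n_modes = x$n_modes,
    fraction_on = x$fraction_on, stationary = x$stationary
  )
}
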