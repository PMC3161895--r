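# broom-style verbs for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname load_parameters
#' @param x Object to tidy.
#' @param ... Unused.
#' @method tidy parameter_set
#' @export
tidy.parameter_set <- function(x, ...) {
  tibble::tibble(
    name = names(x$entries),
    value = vapply(x$entries, function(e) e$value, numeric(1)),
    units = vapply(x$entries, function(e) e$units, character(1))
  )
}

#' @rdname find_steady_states
#' @param x A `steady_state_census`.
#' @param ... Unused.
#' @method tidy steady_state_census
#' @export
tidy.steady_state_census <- function(x, ...) {
  if (nrow(x$states) == 0) {
    return(dplyr::mutate(x$states, control_value = numeric(0), .before = 1))
  }
  dplyr::mutate(x$states, control_value = x$control_value, .before = 1)
}

#' @rdname find_steady_states
#' @method glance steady_state_census
#' @export
glance.steady_state_census <- function(x, ...) {
  tibble::tibble(
    control_value = x$control_value,
    n_states = nrow(x$states),
    n_stable = sum(x$states$stability == "stable"),
    n_unstable = sum(x$states$stability == "unstable"),
    n_marginal = sum(x$states$stability == "marginal")
  )
}

#' @rdname bifurcation_scan
#' @param x A `bifurcation_scan`.
#' @param ... Unused.
#' @method tidy bifurcation_scan
#' @export
tidy.bifurcation_scan <- function(x, ...) {
  dplyr::bind_rows(lapply(x$censuses, tidy))
}

#' @rdname bifurcation_scan
#' @method glance bifurcation_scan
#' @export
glance.bifurcation_scan <- function(x, ...) {
  out <- dplyr::bind_rows(lapply(x$censuses, glance))
  out$bistable_lo <- x$bistable_interval[1]
  out$bistable_hi <- x$bistable_interval[2]
  out
}
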