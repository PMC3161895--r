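#' @useDynLib pbmcell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats density rnorm runif sd setNames
NULL

# Required parameter names per model; load_parameters() enforces presence.
.pcf10_required <- c(
  "K_1,1", "K_1,2", "K_1,3", "K_1,4", "K_1,5", "K_1,6", "K_1,7", "K_1,8",
  "K_1,9", "K_2,6", "K_2,8", "K_3,5", "K_3,8", "K_3,9", "K_4,1", "K_4,2",
  "K_4,3", "K_4,5", "K_4,6", "K_4,8", "K_4,9", "mu_hat", "n", "phi_cell",
  "V_cell"
)

.toy_required <- c(
  "k_1", "k_dS", "k_p", "k_dX", "k_u", "k_dI", "k_i", "P", "mu", "V_cell",
  "theta_p", "theta_i", "gamma", "phi_cell"
)

# Names allowed to be zero but never negative; every numeric entry must be
# finite. "n" must be a positive integer order.
.validate_parameter_set <- function(ps) {
  req <- switch(ps$model_id,
    pcf10 = .pcf10_required,
    toy = .toy_required,
    stop("unknown model_id: ", ps$model_id, call. = FALSE)
  )
  have <- names(ps$entries)
  missing <- setdiff(req, have)
  if (length(missing) > 0) {
    stop("parameter set for '", ps$model_id, "' is missing required key(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  dup <- have[duplicated(have)]
  if (length(dup) > 0) {
    stop("duplicated parameter key(s): ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  vals <- vapply(ps$entries, function(e) e$value, numeric(1))
  if (any(!is.finite(vals))) {
    stop("non-finite parameter value(s): ",
      paste(have[!is.finite(vals)], collapse = ", "),
      call. = FALSE
    )
  }
  if (any(vals < 0)) {
    stop("negative rate constant(s): ",
      paste(have[vals < 0], collapse = ", "),
      call. = FALSE
    )
  }
  units <- vapply(ps$entries, function(e) e$units, character(1))
  if (any(!nzchar(units))) {
    stop("empty units string for: ", paste(have[!nzchar(units)], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(ps)
}

#' Load and validate a model parameter set
#'
#' Reads a flat `name: value  # units` parameter file (the packaged fixtures
#' `"pcf10"` and `"toy"` carry the published rate constants for the pCF10
#' conjugation switch and the toy gene circuit) and returns a validated
#' `parameter_set` object. All rate and degradation constants must be
#' nonnegative and every required name for the model must be present exactly
#' once.
#'
#' @param source Either a builtin name (`"pcf10"` or `"toy"`) or the path to a
#'   parameter file in the same format.
#' @return An object of class `parameter_set`: a list with `model_id` and
#'   `entries` (a named list of `(value, units)` pairs). Use [tidy()] for a
#'   tibble view and `[[` / [param_values()] for numeric access.
#' @examples
#' theta <- load_parameters("pcf10")
#' theta[["K_1,2"]] # 0.0876 nM/s
#' @export
load_parameters <- function(source) {
  path <- if (source %in% c("pcf10", "toy")) {
    system.file("extdata", paste0(source, ".params"),
      package = "pbmcell", mustWork = TRUE
    )
  } else {
    if (!file.exists(source)) {
      stop("parameter file not found: ", source, call. = FALSE)
    }
    source
  }
  lines <- readLines(path, warn = FALSE)
  # strip comments and blanks; continuation comment lines have no ':' payload
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & grepl(":", lines, fixed = TRUE)]
  keys <- trimws(sub(":.*$", "", lines))
  raw_vals <- trimws(sub("^[^:]*:", "", lines))

  # recover units from the original file's comment column
  orig <- readLines(path, warn = FALSE)
  unit_of <- function(key) {
    ln <- grep(paste0("^\\s*", gsub("([.,])", "\\\\\\1", key), "\\s*:"), orig,
      value = TRUE
    )[1]
    if (is.na(ln) || !grepl("#", ln)) {
      return("unspecified")
    }
    u <- trimws(sub("^[^#]*#\\s*", "", ln))
    u <- trimws(strsplit(u, "\\s\\s+")[[1]][1])
    if (nzchar(u)) u else "unspecified"
  }

  model_id <- raw_vals[keys == "model_id"]
  if (length(model_id) != 1) {
    stop("parameter file must declare model_id exactly once", call. = FALSE)
  }
  keep <- keys != "model_id"
  keys <- keys[keep]
  vals <- suppressWarnings(as.numeric(raw_vals[keep]))
  if (any(is.na(vals))) {
    stop("unparsable numeric value for: ",
      paste(keys[is.na(vals)], collapse = ", "),
      call. = FALSE
    )
  }
  entries <- setNames(
    lapply(seq_along(keys), function(i) {
      list(value = vals[i], units = unit_of(keys[i]))
    }),
    keys
  )
  ps <- structure(
    list(model_id = model_id, entries = entries),
    class = "parameter_set"
  )
  .validate_parameter_set(ps)
  ps
}

#' @export
`[[.parameter_set` <- function(x, name) {
  e <- x$entries[[name]]
  if (is.null(e)) stop("no parameter named '", name, "'", call. = FALSE)
  e$value
}

#' Numeric vector of all parameter values
#'
#' @param theta A `parameter_set`.
#' @return Named numeric vector.
#' @export
param_values <- function(theta) {
  vapply(theta$entries, function(e) e$value, numeric(1))
}

#' Replace parameter values
#'
#' Returns a copy of `theta` with the named values replaced (units retained).
#' Used e.g. to impose the bistability-exclusion condition
#' `K_4,2 = K_4,1 = 0.001`.
#'
#' @param theta A `parameter_set`.
#' @param ... Named numeric replacements, e.g. `` `K_4,2` = 0.001 ``.
#' @return A validated `parameter_set`.
#' @export
set_parameters <- function(theta, ...) {
  repl <- list(...)
  for (nm in names(repl)) {
    if (is.null(theta$entries[[nm]])) {
      theta$entries[[nm]] <- list(value = as.numeric(repl[[nm]]), units = "unspecified")
    } else {
      theta$entries[[nm]]$value <- as.numeric(repl[[nm]])
    }
  }
  .validate_parameter_set(theta)
  theta
}

#' Serialize a parameter set back to its file format
#'
#' Round trip contract: `load_parameters(write_parameters(theta, f))` has
#' bitwise-identical values.
#'
#' @param theta A `parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(theta, path) {
  lines <- c(
    paste0("model_id: ", theta$model_id),
    vapply(names(theta$entries), function(nm) {
      e <- theta$entries[[nm]]
      sprintf("%s: %s  # %s", nm, format(e$value, digits = 17), e$units)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> model_id:", x$model_id, "-", length(x$entries),
    "parameters\n"
  )
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Convert a concentration to an expected molecule count
#'
#' `conc` (nM) in a compartment of volume `V_cell` (litres) corresponds to
#' `conc * 1e-9 * N_A * V_cell` molecules. Used to check the
#' molecules-per-cell scale implied by a concentration state, and to set the
#' chemical-Langevin noise magnitude.
#'
#' @param conc Concentration in nM (nonnegative).
#' @param V_cell Compartment volume in litres (positive).
#' @return Expected molecule count (real, not rounded).
#' @examples
#' concentration_to_copies(1, 1e-15) # ~0.602 molecules
#' @export
concentration_to_copies <- function(conc, V_cell) {
  if (any(conc < 0)) stop("concentration must be nonnegative", call. = FALSE)
  if (any(V_cell <= 0)) stop("volume must be positive", call. = FALSE)
  conc * 1e-9 * 6.02214076e23 * V_cell
}
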