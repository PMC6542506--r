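# Parameter set, physiological box and [-1, 1] normalization.

#' Names of the 22 free model parameters
#'
#' Canonical ordering used throughout the package: resting potentials,
#' reversal (Nernst) potentials, maximum firing rates, firing thresholds and
#' their standard deviations, membrane time constants, PSP rate constants
#' (one excitatory, one inhibitory; each shared by its two synapse types),
#' PSP amplitudes, external excitatory input rates, and the four synaptic
#' connection counts.  The external inhibitory input rates p_ie and p_ii are
#' fixed at 0/ms and are not free parameters.
#'
#' @return Character vector of length 22.
#' @export
param_names <- function() {
  c("h_e_rest", "h_i_rest", "h_e_eq", "h_i_eq",
    "S_e_max", "S_i_max", "mu_e", "mu_i", "sigma_e", "sigma_i",
    "tau_e", "tau_i", "gamma_e", "gamma_i", "Gamma_e", "Gamma_i",
    "p_ee", "p_ei", "N_ee", "N_ie", "N_ei", "N_ii")
}

#' Default physiological parameter box
#'
#' Lower and upper bounds of the physiologically plausible range for each of
#' the 22 free parameters.  Units: potentials/thresholds/SDs/PSP amplitudes in
#' mV, time constants in ms, firing and input rates and PSP rate constants in
#' 1/ms, connection counts dimensionless.  Connection-count ranges follow the
#' source population: excitatory-source counts (N_ee, N_ei) span 2000-5000,
#' inhibitory-source counts (N_ie, N_ii) span 100-1000.  The inhibitory
#' reversal potential h_i_eq spans the hyperpolarized range -90 to -60 mV:
#' it must lie below the resting potentials for the inhibitory synaptic
#' weight to be negative at rest, i.e. for inhibition to inhibit -- without
#' this the model has no resonant feedback loop and cannot produce an alpha
#' peak.  Use [param_box()] or a config file to explore other ranges.
#'
#' @return An object of class `param_box`: list with named numeric vectors
#'   `lower` and `upper` and a named list `fixed` (the pinned external
#'   inhibitory input rates).
#' @export
default_box <- function() {
  lower <- c(h_e_rest = -80, h_i_rest = -80, h_e_eq = -20, h_i_eq = -90,
             S_e_max = 0.05, S_i_max = 0.05, mu_e = -55, mu_i = -55,
             sigma_e = 2, sigma_i = 2, tau_e = 5, tau_i = 5,
             gamma_e = 0.1, gamma_i = 0.01, Gamma_e = 0.1, Gamma_i = 0.1,
             p_ee = 0, p_ei = 0, N_ee = 2000, N_ie = 100,
             N_ei = 2000, N_ii = 100)
  upper <- c(h_e_rest = -60, h_i_rest = -60, h_e_eq = 10, h_i_eq = -60,
             S_e_max = 0.5, S_i_max = 0.5, mu_e = -40, mu_i = -40,
             sigma_e = 7, sigma_i = 7, tau_e = 150, tau_i = 150,
             gamma_e = 1.0, gamma_i = 0.5, Gamma_e = 2.0, Gamma_i = 2.0,
             p_ee = 10, p_ei = 10, N_ee = 5000, N_ie = 1000,
             N_ei = 5000, N_ii = 1000)
  param_box(lower, upper)
}

#' Construct a parameter box
#'
#' @param lower,upper Named numeric vectors over [param_names()].
#' @param fixed Named list of pinned constants (default `p_ie = 0, p_ii = 0`).
#' @return A `param_box` object.
#' @export
param_box <- function(lower, upper, fixed = list(p_ie = 0, p_ii = 0)) {
  nm <- param_names()
  lower <- lower[nm]; upper <- upper[nm]
  if (anyNA(lower) || anyNA(upper))
    stop("lower and upper must cover all 22 parameters ", call. = FALSE)
  if (any(lower >= upper))
    stop("box must have min < max for every parameter; violated for: ",
         paste(nm[lower >= upper], collapse = ", "), call. = FALSE)
  structure(list(lower = lower, upper = upper, fixed = fixed),
            class = "param_box")
}

#' Read / write a parameter box config file
#'
#' Human-editable JSON config: each key is a parameter symbol, each value a
#' `[min, max]` pair; fixed scalars (p_ie, p_ii) are single numbers.
#'
#' @param path File path.
#' @return `read_param_box()` returns a `param_box`.
#' @export
read_param_box <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- param_names()
  free <- cfg[nm]
  if (any(vapply(free, is.null, logical(1))))
    stop("config is missing parameters: ",
         paste(nm[vapply(free, is.null, logical(1))], collapse = ", "),
         call. = FALSE)
  lower <- vapply(free, function(v) v[[1]], numeric(1))
  upper <- vapply(free, function(v) v[[2]], numeric(1))
  fixed <- cfg[setdiff(names(cfg), nm)]
  fixed <- lapply(fixed, function(v) v[[1]])
  if (is.null(fixed$p_ie)) fixed$p_ie <- 0
  if (is.null(fixed$p_ii)) fixed$p_ii <- 0
  param_box(stats::setNames(lower, nm), stats::setNames(upper, nm), fixed)
}

#' @rdname read_param_box
#' @param box A `param_box`.
#' @export
write_param_box <- function(box, path) {
  cfg <- lapply(seq_along(box$lower), function(i)
    c(box$lower[[i]], box$upper[[i]]))
  names(cfg) <- names(box$lower)
  cfg <- c(cfg, box$fixed)
  jsonlite::write_json(cfg, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Construct a model parameter set
#'
#' Either pass a full named vector via `values`, or individual parameters by
#' name.  Validates positivity of rate/time constants and threshold SDs and
#' the non-degeneracy of the potential-difference weighting denominators.
#'
#' @param ... Individual named parameter values.
#' @param values Optional named numeric vector with all 22 parameters.
#' @return Named numeric vector of class `npm_params`.
#' @export
npm_params <- function(..., values = NULL) {
  nm <- param_names()
  if (is.null(values)) values <- unlist(list(...))
  v <- values[nm]
  if (anyNA(v))
    stop("missing parameters: ",
         paste(nm[is.na(v)], collapse = ", "), call. = FALSE)
  names(v) <- nm
  pos <- c("S_e_max", "S_i_max", "sigma_e", "sigma_i",
           "tau_e", "tau_i", "gamma_e", "gamma_i", "Gamma_e", "Gamma_i")
  if (any(v[pos] <= 0))
    stop("parameters must be strictly positive: ",
         paste(pos[v[pos] <= 0], collapse = ", "), call. = FALSE)
  dens <- c(abs(v["h_e_eq"] - v["h_e_rest"]), abs(v["h_i_eq"] - v["h_e_rest"]),
            abs(v["h_e_eq"] - v["h_i_rest"]), abs(v["h_i_eq"] - v["h_i_rest"]))
  if (any(dens == 0))
    stop("degenerate parameter set: a reversal potential equals a resting ",
         "potential, making a weighting denominator zero", call. = FALSE)
  structure(v, class = "npm_params")
}

#' Map a parameter set to normalized [-1, 1] coordinates
#'
#' Affine per-coordinate map taking the box minimum to -1 and the maximum to
#' +1.  All fitting, uncertainty reporting and Fisher-information derivatives
#' work in these normalized units.
#'
#' @param params `npm_params` (or named vector over [param_names()]).
#' @param box `param_box`, default [default_box()].
#' @return Numeric vector of length 22 in `[-1, 1]`.
#' @export
normalize_params <- function(params, box = default_box()) {
  nm <- param_names()
  v <- unclass(params)[nm]
  if (anyNA(v)) stop("params must be named over param_names()", call. = FALSE)
  out <- which(v < box$lower | v > box$upper)
  if (length(out))
    stop("parameter(s) outside the box: ",
         paste(nm[out], collapse = ", "), call. = FALSE)
  stats::setNames(2 * (v - box$lower) / (box$upper - box$lower) - 1, nm)
}

#' Map normalized [-1, 1] coordinates back to physical parameters
#'
#' Exact inverse of [normalize_params()] on the box interior; values outside
#' `[-1, 1]` are mapped affinely without error (finite-difference stencils may
#' step slightly outside the box).
#'
#' @param theta Numeric vector of length 22 (normalized units).
#' @param box `param_box`.
#' @return `npm_params`.
#' @export
denormalize_params <- function(theta, box = default_box()) {
  v <- box$lower + (theta + 1) / 2 * (box$upper - box$lower)
  npm_params(values = stats::setNames(v, param_names()))
}

#' Draw parameter sets uniformly from the box
#'
#' @param n Number of draws.
#' @param box `param_box`.
#' @return Matrix `n x 22` of normalized coordinates in `[-1, 1]`.
#' @export
random_theta <- function(n, box = default_box()) {
  matrix(runif(n * 22, -1, 1), nrow = n,
         dimnames = list(NULL, param_names()))
}

#' Read / write a parameter set (flat key-value CSV or JSON)
#'
#' @param params `npm_params`.
#' @param path Destination; format chosen by extension (.json or .csv).
#' @export
write_params <- function(params, path) {
  v <- as.list(unclass(params)[param_names()])
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(v, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  } else {
    df <- data.frame(parameter = names(v), value = unlist(v))
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    v <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    df <- read.csv(path)
    v <- stats::setNames(df$value, df$parameter)
  }
  npm_params(values = v)
}

#' @export
print.npm_params <- function(x, ...) {
  cat("Neural population model parameters (22 free):\n")
  print(round(unclass(x), 5))
  invisible(x)
}
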