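# Model core: sigmoid firing rate, equilibria, linearization, model spectrum.

state_names <- function() {
  c("h_e", "h_i", "I_ee", "dI_ee", "I_ie", "dI_ie",
    "I_ei", "dI_ei", "I_ii", "dI_ii")
}

.theta_phys <- function(params) as.numeric(unclass(params)[param_names()])

#' Mean population firing rate
#'
#' Sigmoidal transfer from mean soma membrane potential to mean firing rate:
#' `S(h) = S_max / (1 + exp(-scale * (h - mu) / sigma))`.  With the default
#' `scale = sqrt(2)`, `sigma` is the standard deviation of the equivalent
#' Gaussian distribution of firing thresholds.
#'
#' @param h Membrane potential (mV); vectorized.
#' @param s_max Maximum firing rate (1/ms).
#' @param mu Firing threshold (mV).
#' @param sigma Threshold standard deviation (mV), must be positive.
#' @param scale Exponent constant, defaults to the package option
#'   `alphamass.sigmoid_scale` (sqrt(2)).
#' @return Firing rate(s) in (0, s_max), units 1/ms.
#' @export
firing_rate <- function(h, s_max, mu, sigma, scale = sigmoid_scale()) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  s_max / (1 + exp(-scale * (h - mu) / sigma))
}

#' Right-hand side of the population ODE system
#'
#' The 10-dimensional first-order form of the coupled membrane/synaptic
#' equations, with state order `h_e, h_i, I_ee, dI_ee, I_ie, dI_ie, I_ei,
#' dI_ei, I_ii, dI_ii`.  Exposed mainly for testing against finite-difference
#' oracles.
#'
#' @param params `npm_params`.
#' @param state Numeric state vector of length 10.
#' @return Time derivative of the state (per ms).
#' @export
ode_rhs <- function(params, state) {
  stats::setNames(
    as.numeric(cpp_rhs(.theta_phys(params), as.numeric(state), sigmoid_scale())),
    state_names())
}

stop_unstable <- function(msg = "unstable parameter set: no linearly stable equilibrium") {
  stop(structure(class = c("alphamass_unstable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_no_equilibrium <- function(msg = "no equilibrium found in the physiological potential range") {
  stop(structure(class = c("alphamass_no_equilibrium", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Find all equilibria of the model
#'
#' Reduces the steady-state equations to a 2-d root problem in (h_e, h_i),
#' solved by damped Newton iterations from a grid of starting points, with
#' roots deduplicated at 1e-6 mV.
#'
#' @param params `npm_params`.
#' @param grid_n Starting grid is `grid_n x grid_n` over `[lo, hi]^2`.
#' @param lo,hi Potential search range (mV).
#' @return Data frame with one row per root: `h_e`, `h_i`, the four synaptic
#'   steady states, `stable`, `max_re` (largest real part of the Jacobian
#'   eigenvalues, 1/ms) and `residual` (max abs ODE right-hand side).
#' @export
equilibria <- function(params, grid_n = 12, lo = -90, hi = -10) {
  r <- cpp_equilibria(.theta_phys(params), sigmoid_scale(), grid_n, lo, hi)
  data.frame(h_e = r$roots[, 1], h_i = r$roots[, 2],
             I_ee = r$I[, 1], I_ie = r$I[, 2], I_ei = r$I[, 3], I_ii = r$I[, 4],
             stable = r$stable, max_re = r$max_re, residual = r$residual)
}

#' Find the resting-state equilibrium
#'
#' Returns the stable equilibrium used for linearization.  If several stable
#' equilibria coexist, the most hyperpolarized branch (lowest `h_e`) is
#' selected and a warning is issued.  A parameter set with roots but no
#' stable root raises a catchable condition of class `alphamass_unstable`;
#' one with no root at all raises `alphamass_no_equilibrium`.
#'
#' @inheritParams equilibria
#' @return Object of class `npm_equilibrium`: list with `h_e`, `h_i`,
#'   `I` (named synaptic steady states), `stable`, `residual`, `n_roots`,
#'   `n_stable`.
#' @export
find_equilibrium <- function(params, grid_n = 12, lo = -90, hi = -10) {
  eq <- equilibria(params, grid_n, lo, hi)
  if (nrow(eq) == 0) stop_no_equilibrium()
  st <- eq[eq$stable, , drop = FALSE]
  if (nrow(st) == 0) stop_unstable()
  if (nrow(st) > 1)
    warning("multiple stable equilibria (", nrow(st),
            "); selecting the most hyperpolarized h_e branch", call. = FALSE)
  k <- which.min(st$h_e)
  structure(list(
    h_e = st$h_e[k], h_i = st$h_i[k],
    I = c(I_ee = st$I_ee[k], I_ie = st$I_ie[k],
          I_ei = st$I_ei[k], I_ii = st$I_ii[k]),
    stable = TRUE, residual = st$residual[k],
    n_roots = nrow(eq), n_stable = nrow(st)), class = "npm_equilibrium")
}

#' Classify a parameter set by its resting-state structure
#'
#' Every parameter set falls in exactly one class: `"stable"` (has a linearly
#' stable equilibrium), `"unstable"` (equilibria exist, none stable) or
#' `"no_equilibrium"`.  The fitting layers only evaluate likelihoods on the
#' first class.
#'
#' @inheritParams equilibria
#' @return One of `"stable"`, `"unstable"`, `"no_equilibrium"`.
#' @export
classify_params <- function(params, grid_n = 12, lo = -90, hi = -10) {
  eq <- equilibria(params, grid_n, lo, hi)
  if (nrow(eq) == 0) return("no_equilibrium")
  if (any(eq$stable)) "stable" else "unstable"
}

eq_state_vector <- function(eq) {
  x <- numeric(10)
  x[1] <- eq$h_e; x[2] <- eq$h_i
  x[c(3, 5, 7, 9)] <- eq$I
  stats::setNames(x, state_names())
}

#' Linearize the model about an equilibrium
#'
#' Builds the 10-dimensional linear state space whose transfer gain from
#' fluctuations of the external drive p_ee to the excitatory potential h_e is
#' the model spectrum.  `A` is the analytic Jacobian of the ODE right-hand
#' side at the equilibrium; `B` injects p_ee perturbations into the dI_ee/dt
#' row with weight `Gamma_e * gamma_e * e`; `C` selects h_e.
#'
#' @param params `npm_params`.
#' @param eq Optional `npm_equilibrium`; found via [find_equilibrium()] if
#'   omitted.
#' @return Object of class `npm_ss`: list with `A` (10x10), `B`, `C`,
#'   `equilibrium`, `eigenvalues` and `stable`.
#' @export
linearize <- function(params, eq = NULL) {
  if (is.null(eq)) eq <- find_equilibrium(params)
  x <- eq_state_vector(eq)
  A <- cpp_jacobian(.theta_phys(params), x, sigmoid_scale())
  dimnames(A) <- list(state_names(), state_names())
  v <- unclass(params)
  B <- stats::setNames(numeric(10), state_names())
  B["dI_ee"] <- v[["Gamma_e"]] * v[["gamma_e"]] * exp(1)
  C <- stats::setNames(numeric(10), state_names())
  C["h_e"] <- 1
  ev <- eigen(A, only.values = TRUE)$values
  structure(list(A = A, B = B, C = C, equilibrium = eq,
                 eigenvalues = ev, stable = all(Re(ev) < 0)),
            class = "npm_ss")
}

#' Squared transfer gain of a linear state space
#'
#' `|C (i*omega*I - A)^-1 B|^2` at each frequency, with `omega` converted
#' from Hz to the model's internal rad/ms unit.
#'
#' @param ss `npm_ss` from [linearize()].
#' @param freqs Frequencies in Hz (nonnegative).
#' @return Nonnegative gains, one per frequency.
#' @export
transfer_gain <- function(ss, freqs) {
  if (any(freqs < 0)) stop("frequencies must be nonnegative", call. = FALSE)
  g <- as.numeric(cpp_tf_gain(ss$A, as.numeric(ss$B), as.numeric(ss$C),
                              as.numeric(freqs)))
  if (any(!is.finite(g)))
    stop_unstable("transfer gain not finite: marginally stable state space")
  g
}

#' Analytic model spectrum
#'
#' The model's predicted power spectrum (up to the profiled amplitude alpha)
#' at the given frequencies: the squared transfer gain of the linearization
#' about the stable resting state.
#'
#' @param params `npm_params`.
#' @param freqs Strictly increasing frequencies in Hz.
#' @return Positive spectral values (arbitrary power units).
#' @export
model_spectrum <- function(params, freqs) {
  if (is.unsorted(freqs, strictly = TRUE))
    stop("freqs must be strictly increasing", call. = FALSE)
  r <- cpp_spectrum(.theta_phys(params), as.numeric(freqs), sigmoid_scale())
  if (r$status == 2) stop_no_equilibrium()
  if (r$status == 1) stop_unstable()
  S <- as.numeric(r$S)
  if (any(!is.finite(S) | S <= 0))
    stop_unstable("model spectrum not finite and positive")
  S
}

# Fast path used by fitting layers: no conditions, returns list(status, S).
spectrum_status <- function(theta_phys, freqs) {
  r <- cpp_spectrum(theta_phys, freqs, sigmoid_scale())
  if (r$status == 0) {
    S <- as.numeric(r$S)
    if (any(!is.finite(S) | S <= 0)) return(list(status = 1L, S = NULL))
    return(list(status = 0L, S = S))
  }
  list(status = as.integer(r$status), S = NULL)
}

#' @export
print.npm_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium: h_e* = %.4f mV, h_i* = %.4f mV (stable, residual %.2e)\n",
              x$h_e, x$h_i, x$residual))
  cat(sprintf("  %d root(s), %d stable\n", x$n_roots, x$n_stable))
  invisible(x)
}
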