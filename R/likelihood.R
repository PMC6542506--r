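# Gamma spectral likelihood with the amplitude profiled out, and the
# least-squares cost used by the particle swarm.
#
# Each Welch spectral bin S_n is modelled as gamma with shape K (K/2 at zero
# frequency, which the 2-20 Hz band never contains) and scale
# Theta_n = alpha * S_hat_n / K, so its mean is alpha * S_hat_n.  alpha is
# profiled analytically: least-squares (for the PSO cost) or maximum
# likelihood (for the posterior).

PENALTY_BASE <- 1e12

.bin_shapes <- function(spec) ifelse(spec$freqs == 0, spec$K / 2, spec$K)

#' Least-squares profiled amplitude
#'
#' `alpha = sum(S * S_hat) / sum(S_hat^2)`, the minimizer of the sum of
#' squared residuals between `alpha * S_hat` and `S`.
#'
#' @param S Measured spectral powers.
#' @param S_hat Model spectral values (positive, same length).
#' @return Scalar amplitude.
#' @export
alpha_ls <- function(S, S_hat) {
  if (length(S) != length(S_hat)) stop("length mismatch", call. = FALSE)
  d <- sum(S_hat^2)
  if (d == 0) stop("model spectrum is identically zero", call. = FALSE)
  sum(S * S_hat) / d
}

#' Maximum-likelihood profiled amplitude
#'
#' For a common gamma shape, `alpha = mean(S / S_hat)`, the stationary point
#' of the gamma likelihood in alpha.  With per-bin shapes (only relevant if a
#' zero-frequency bin were kept), the shape-weighted generalization
#' `sum(shape * S / S_hat) / sum(shape)` is used.
#'
#' @inheritParams alpha_ls
#' @param shape Optional per-bin gamma shapes.
#' @return Scalar amplitude.
#' @export
alpha_ml <- function(S, S_hat, shape = NULL) {
  if (length(S) != length(S_hat)) stop("length mismatch", call. = FALSE)
  if (all(S_hat == 0)) stop("model spectrum is identically zero", call. = FALSE)
  if (is.null(shape)) return(mean(S / S_hat))
  sum(shape * S / S_hat) / sum(shape)
}

# Penalty for out-of-box / model-failure parameter vectors: large, finite,
# and increasing in the normalized boundary violation so the swarm is pushed
# back toward the box.
.penalty <- function(theta_norm) {
  PENALTY_BASE * (1 + sum(pmax(abs(theta_norm) - 1, 0)))
}

#' Least-squares cost of a parameter set on a spectrum
#'
#' `C = sum((alpha_LS * S_hat - S)^2)` with the amplitude profiled by
#' [alpha_ls()].  Parameter sets outside the box, or whose model has no
#' stable equilibrium, receive a large finite penalty instead of an error so
#' that swarm optimization remains well defined.
#'
#' @param params `npm_params`, or a normalized 22-vector with
#'   `normalized = TRUE`.
#' @param spec Band-selected `spectral_estimate`.
#' @param box `param_box` used for normalization and the penalty.
#' @param normalized Interpret `params` as normalized coordinates.
#' @return Nonnegative cost.
#' @export
ls_cost <- function(params, spec, box = default_box(), normalized = FALSE) {
  if (normalized) {
    theta_norm <- as.numeric(params)
    if (any(abs(theta_norm) > 1)) return(.penalty(theta_norm))
    phys <- .theta_phys(denormalize_params(theta_norm, box))
  } else {
    theta_norm <- tryCatch(normalize_params(params, box), error = function(e) NULL)
    if (is.null(theta_norm)) return(PENALTY_BASE * 2)
    phys <- .theta_phys(params)
  }
  r <- spectrum_status(phys, spec$freqs)
  if (r$status != 0) return(.penalty(theta_norm))
  a <- alpha_ls(spec$power, r$S)
  sum((a * r$S - spec$power)^2)
}

.loglik_core <- function(S, S_hat, shape) {
  a <- alpha_ml(S, S_hat, shape)
  sum(dgamma(S, shape = shape, scale = a * S_hat / shape, log = TRUE))
}

#' Gamma log-likelihood of a spectrum given model parameters
#'
#' Natural log of the profiled-amplitude likelihood: the product over bins of
#' gamma densities with shape K and scale `alpha_ML * S_hat_n / K`.  All
#' shape- and K-dependent constants are included, so absolute values are
#' comparable across runs.  Returns `-Inf` for parameter sets without a
#' stable equilibrium (samplers treat this as certain rejection).
#'
#' @inheritParams ls_cost
#' @return Log-likelihood (nats), or `-Inf`.
#' @export
log_likelihood <- function(params, spec, box = default_box(), normalized = FALSE) {
  if (any(spec$power <= 0)) stop("nonpositive spectral power", call. = FALSE)
  if (normalized) {
    theta_norm <- as.numeric(params)
    if (any(abs(theta_norm) > 1)) return(-Inf)
    phys <- .theta_phys(denormalize_params(theta_norm, box))
  } else {
    phys <- .theta_phys(params)
  }
  r <- spectrum_status(phys, spec$freqs)
  if (r$status != 0) return(-Inf)
  .loglik_core(spec$power, r$S, .bin_shapes(spec))
}

#' Log-likelihood ratio between two parameter sets
#'
#' Equals `log_likelihood(theta_new) - log_likelihood(theta_old)`.  Under the
#' uniform prior the prior-ratio terms reduce to a support indicator, which
#' the samplers enforce separately.
#'
#' @param params_new,params_old Parameter sets (`npm_params` or normalized
#'   vectors with `normalized = TRUE`).
#' @inheritParams ls_cost
#' @return Scalar log ratio.
#' @export
log_likelihood_ratio <- function(params_new, params_old, spec,
                                 box = default_box(), normalized = FALSE) {
  log_likelihood(params_new, spec, box, normalized) -
    log_likelihood(params_old, spec, box, normalized)
}

#' Per-bin gamma quantiles of the fitted spectral distribution
#'
#' Quantiles of the gamma sampling distribution with shape K and scale
#' `alpha * S_hat_n / K`, e.g. the 16% and 84% bands drawn around fitted
#' spectra.
#'
#' @param S_hat Model spectral values.
#' @param alpha Profiled amplitude.
#' @param K Gamma shape.
#' @param q Quantile(s) in (0, 1).
#' @return Matrix with one row per bin and one column per quantile.
#' @export
spectral_quantiles <- function(S_hat, alpha, K, q) {
  if (any(q <= 0 | q >= 1)) stop("quantiles must lie in (0, 1)", call. = FALSE)
  out <- vapply(q, function(p) qgamma(p, shape = K, scale = alpha * S_hat / K),
                numeric(length(S_hat)))
  matrix(out, nrow = length(S_hat), dimnames = list(NULL, paste0("q", q)))
}

# Closures over normalized coordinates used by the fitting layers.
.objective_ls <- function(spec, box) {
  force(spec); force(box)
  function(theta_norm) ls_cost(theta_norm, spec, box, normalized = TRUE)
}

.log_posterior <- function(spec, box) {
  force(spec); force(box)
  shapes <- .bin_shapes(spec)
  S <- spec$power
  freqs <- spec$freqs
  lower <- box$lower; width <- (box$upper - box$lower) / 2
  function(theta_norm) {
    if (any(abs(theta_norm) > 1)) return(-Inf)
    phys <- lower + (theta_norm + 1) * width
    r <- spectrum_status(phys, freqs)
    if (r$status != 0) return(-Inf)
    .loglik_core(S, r$S, shapes)
  }
}
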