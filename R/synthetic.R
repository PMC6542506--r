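# Synthetic data: ground-truth parameter sets, gamma-sampled spectra, and
# noise-driven simulated time series.  These emulate the study conditions of
# a one-minute, 160 Hz eyes-closed recording analysed with 4-s Hamming
# windows at 50% overlap (K = 29 averaged segments, 0.25 Hz resolution,
# fitted over 2-20 Hz).

#' Draw an alpha-peaked, linearly stable ground-truth parameter set
#'
#' Rejection sampling of uniform draws from the box until the parameter set
#' (a) has a stable equilibrium and (b) produces a visibly alpha-peaked model
#' spectrum: the spectral argmax over the 2-20 Hz grid lies in the alpha band
#' and the peak is at least `prominence` times the power at the low-frequency
#' edge.  Deterministic per seed.
#'
#' @param box `param_box`.
#' @param seed Integer RNG seed.
#' @param K Gamma shape of the emulated Welch estimate (default 29, the
#'   segment count of a 60 s / 4 s / 50% overlap analysis).
#' @param freqs Frequency grid in Hz (default 2-20 Hz at 0.25 Hz).
#' @param alpha True amplitude applied to the model spectrum.
#' @param peak_band Required location of the spectral peak (default 8-13 Hz).
#' @param prominence Required peak-to-edge power ratio (default 2).
#' @param max_tries Rejection limit.
#' @return Object of class `ground_truth`: `params`, `theta` (normalized),
#'   `S_hat` (model spectrum on the grid), `alpha`, `K`, `freqs`, `seed`,
#'   `rejections`.
#' @export
sample_ground_truth <- function(box = default_box(), seed = 1L, K = 29,
                                freqs = seq(2, 20, by = 0.25), alpha = 1,
                                peak_band = c(8, 13), prominence = 2,
                                max_tries = 1e5) {
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    th <- runif(22, -1, 1)
    phys <- box$lower + (th + 1) / 2 * (box$upper - box$lower)
    r <- spectrum_status(as.numeric(phys), freqs)
    if (r$status != 0) next
    pk <- which.max(r$S)
    if (freqs[pk] < peak_band[1] || freqs[pk] > peak_band[2]) next
    if (r$S[pk] < prominence * r$S[1]) next
    return(structure(list(
      params = denormalize_params(th, box),
      theta = stats::setNames(th, param_names()),
      S_hat = r$S, alpha = alpha, K = K, freqs = freqs,
      seed = seed, rejections = i - 1L,
      note = "synthetic ground truth (rejection-sampled)"),
      class = "ground_truth"))
  }
  stop("no stable alpha-peaked parameter set in ", max_tries,
       " draws; relax the peak constraints or change the seed", call. = FALSE)
}

#' Draw a synthetic-subject ground truth by fitting a realistic spectrum
#'
#' Emulates the way a ground truth is obtained in a recovery study on real
#' data: take a plausible eyes-closed occipital EEG spectrum (a `1/f^b`
#' background plus a clear alpha peak, here a parametric template with
#' randomized peak frequency, width, height and background slope) and use
#' the model's maximum-likelihood estimate for it as the true parameter set.
#' Such fitted truths land in the physiological regime where the alpha peak
#' is an inhibitory-loop resonance, which is where real-data fits live; a
#' uniform draw from the box constrained only to be stable and alpha-peaked
#' ([sample_ground_truth()]) usually does not.
#'
#' The fit runs a small ensemble of particle swarms on the least-squares
#' cost followed by simplex refinement of the gamma likelihood.
#'
#' @param seed Integer RNG seed (drives the template and the fit).
#' @param box `param_box`.
#' @param freqs Frequency grid in Hz.
#' @param K Gamma shape of the emulated Welch estimate.
#' @param alpha True amplitude applied to the model spectrum.
#' @param n_pso Number of swarm runs per attempt.
#' @param control [swarm_control()] for each run.
#' @param max_attempts A fit can miss the alpha bump and land on a
#'   monotone background spectrum, which is not a usable ground truth
#'   (the truth's own spectrum must peak in the alpha band); such fits are
#'   rejected and a fresh template is drawn, up to this many times.
#' @param peak_band Required location of the truth spectrum's peak.
#' @return Object of class `ground_truth` (see [sample_ground_truth()]),
#'   with the template stored in `$template` and the number of rejected
#'   fits in `$rejections`.
#' @export
sample_subject_truth <- function(seed = 1L, box = default_box(),
                                 freqs = seq(2, 20, by = 0.25), K = 29,
                                 alpha = 1, n_pso = 8,
                                 control = swarm_control(n_particles = 50,
                                                         n_iterations = 250,
                                                         stall_iterations = 50),
                                 max_attempts = 8, peak_band = c(8, 13)) {
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    slope <- runif(1, 1.1, 1.5)
    f0 <- runif(1, 9, 11)
    width <- runif(1, 0.8, 1.5)
    rel_height <- runif(1, 4, 8)        # peak over the local 1/f background
    S_t <- freqs^(-slope) + rel_height * f0^(-slope) *
      exp(-(freqs - f0)^2 / (2 * width^2))
    spec_t <- spectral_estimate(freqs, S_t, K, source = "subject-template")
    obj <- .objective_ls(spec_t, box)
    run_seeds <- sample.int(.Machine$integer.max - 1L, n_pso)
    best <- NULL
    for (r in seq_len(n_pso)) {
      fit <- pso_minimize(obj, rep(-1, 22), rep(1, 22), control, run_seeds[r])
      if (is.null(best) || fit$cost < best$cost) best <- fit
    }
    ref <- ml_refine(spec_t, best$par, box)
    th <- as.numeric(ref$theta)
    phys <- denormalize_params(th, box)
    S_hat <- model_spectrum(phys, freqs)
    pk <- freqs[which.max(S_hat)]
    if (pk < peak_band[1] || pk > peak_band[2]) next
    return(structure(list(
      params = phys,
      theta = stats::setNames(th, param_names()),
      S_hat = S_hat, alpha = alpha, K = K,
      freqs = freqs, seed = seed, rejections = attempt - 1L,
      template = list(slope = slope, f0 = f0, width = width,
                      rel_height = rel_height, ls_cost = best$cost,
                      log_lik = ref$log_lik),
      note = "synthetic subject (ML fit to a template alpha spectrum)"),
      class = "ground_truth"))
  }
  stop("no alpha-peaked subject fit in ", max_attempts,
       " template attempts; increase n_pso or max_attempts", call. = FALSE)
}

#' Gamma-sampled synthetic spectrum from a ground truth
#'
#' Draws each frequency bin independently from the gamma sampling
#' distribution of the Welch estimate: shape K, scale
#' `alpha * S_hat_n / K`, so the bin mean is `alpha * S_hat_n` and the bin
#' variance `(alpha * S_hat_n)^2 / K`.
#'
#' @param gt `ground_truth` from [sample_ground_truth()].
#' @param seed Integer RNG seed.
#' @return `spectral_estimate` on the ground truth's frequency grid.
#' @export
synth_spectrum <- function(gt, seed = 1L) {
  set.seed(seed)
  mu <- gt$alpha * gt$S_hat
  S <- rgamma(length(mu), shape = gt$K, scale = mu / gt$K)
  spectral_estimate(gt$freqs, S, gt$K, source = "synthetic-gamma")
}

#' Write / read a ground truth as JSON
#'
#' @param gt `ground_truth`.
#' @param path File path.
#' @export
write_ground_truth <- function(gt, path) {
  obj <- list(params = as.list(unclass(gt$params)),
              alpha = gt$alpha, K = gt$K, freqs = gt$freqs,
              seed = gt$seed, rejections = gt$rejections, note = gt$note)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @param box `param_box` used to recompute normalized coordinates and the
#'   model spectrum.
#' @export
read_ground_truth <- function(path, box = default_box()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- npm_params(values = unlist(obj$params))
  freqs <- as.numeric(obj$freqs)
  structure(list(params = params,
                 theta = normalize_params(params, box),
                 S_hat = model_spectrum(params, freqs),
                 alpha = obj$alpha, K = as.integer(obj$K), freqs = freqs,
                 seed = obj$seed, rejections = obj$rejections,
                 note = obj$note),
            class = "ground_truth")
}

#' Simulate a noise-driven model time series
#'
#' Euler-Maruyama integration of the population equations (or their
#' linearization about the stable equilibrium) with Gaussian white noise
#' entering through the external excitatory drive p_ee.  The excitatory
#' potential h_e is recorded at the output sampling rate; the internal step
#' never exceeds 0.1 ms.
#'
#' The default noise amplitude is calibrated (by a short seeded pilot run) so
#' the h_e fluctuation SD is about 1 mV; the absolute amplitude is immaterial
#' to fitting because the spectral amplitude alpha absorbs scale.
#'
#' @param params `npm_params` with a stable equilibrium.
#' @param duration_s Output duration in seconds.
#' @param fs Output sampling rate in Hz (default 160).
#' @param noise_sd White-noise SD on p_ee (1/ms units); `NULL` calibrates to
#'   about 1 mV output SD.
#' @param seed Integer RNG seed.
#' @param mode `"nonlinear"` (full equations) or `"linearized"`.
#' @param init Optional initial state (length 10); defaults to the
#'   equilibrium.
#' @return `npm_timeseries` of h_e samples (mV).
#' @export
simulate_timeseries <- function(params, duration_s, fs = 160,
                                noise_sd = NULL, seed = 1L,
                                mode = c("nonlinear", "linearized"),
                                init = NULL) {
  mode <- match.arg(mode)
  ss <- linearize(params)
  xeq <- eq_state_vector(ss$equilibrium)
  if (is.null(init)) init <- xeq
  out_dt <- 1000 / fs                       # ms between output samples
  substeps <- ceiling(out_dt / 0.1)
  dt <- out_dt / substeps
  n_out <- round(duration_s * fs)
  m <- if (mode == "nonlinear") 0L else 1L
  theta <- .theta_phys(params)
  set.seed(seed)
  if (is.null(noise_sd)) {
    pilot <- cpp_simulate(theta, sigmoid_scale(), xeq, xeq, ss$A, m,
                          round(8 * fs), substeps, dt, 1.0)
    if (pilot$status != 0)
      stop("instability during noise calibration run", call. = FALSE)
    s1 <- sd(pilot$h_e)
    if (s1 == 0) stop("calibration run produced no fluctuation", call. = FALSE)
    noise_sd <- 1 / s1
  }
  r <- cpp_simulate(theta, sigmoid_scale(), as.numeric(init), xeq, ss$A, m,
                    n_out, substeps, dt, noise_sd)
  if (r$status != 0)
    stop("numerical blow-up during simulation (h_e left the physiological ",
         "range); the parameter set may be only marginally stable",
         call. = FALSE)
  ts <- timeseries(r$h_e, fs, channel = "h_e")
  ts$noise_sd <- noise_sd
  ts$mode <- mode
  ts
}
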