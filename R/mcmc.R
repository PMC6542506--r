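# Metropolis-Hastings sampling of the posterior under the uniform prior and
# gamma likelihood; chain thinning; local maximum-likelihood refinement.

#' MCMC configuration
#'
#' @param n_samples Post-burn-in chain length (10^6 at full scale).
#' @param burn_in Burn-in length during which the proposal step size is
#'   adapted (default 40000); adaptation is frozen afterwards so the
#'   post-burn-in chain satisfies detailed balance.
#' @param target_acceptance Acceptance ratio targeted by the adaptation
#'   (default 0.25).
#' @param initial_step Initial proposal step size in normalized units.
#' @param adapt_batch Batch length for the step-size adaptation: after each
#'   batch of this many burn-in iterations the log step size moves by
#'   `min(0.1, 1/sqrt(batch index))` toward the target acceptance.  This
#'   diminishing-adaptation scheme stays responsive through the whole
#'   burn-in, so the frozen step reflects the region the chain actually
#'   reached, not its starting basin.
#' @param thin_to Default length of thinned subsamples.
#' @param store_every Store every `store_every`-th post-burn-in state (bounds
#'   memory for long chains); acceptance statistics are kept at full
#'   resolution.  `NULL` picks a stride so that about 10^4 states are kept.
#' @return List of class `mcmc_control`.
#' @export
mcmc_control <- function(n_samples = 1e6, burn_in = 40000,
                         target_acceptance = 0.25, initial_step = 0.05,
                         adapt_batch = 50, thin_to = 1000,
                         store_every = NULL) {
  stopifnot(burn_in < n_samples, target_acceptance > 0, target_acceptance < 1)
  if (is.null(store_every)) store_every <- max(1L, floor(n_samples / 1e4))
  structure(list(n_samples = n_samples, burn_in = burn_in,
                 target_acceptance = target_acceptance,
                 initial_step = initial_step,
                 adapt_batch = as.integer(adapt_batch),
                 thin_to = thin_to, store_every = as.integer(store_every)),
            class = "mcmc_control")
}

#' Metropolis-Hastings sampler with burn-in step adaptation
#'
#' Isotropic Gaussian random-walk proposals with a single scalar step size.
#' During burn-in the log step size is adapted by stochastic approximation
#' (Robbins-Monro) toward the target acceptance ratio, then frozen.
#' Proposals outside `[lower, upper]` or with `log_target = -Inf` are
#' rejected.  Generic over the target; [fit_mcmc()] supplies the spectral
#' posterior.
#'
#' @param log_target Function of a position vector returning a log density
#'   (`-Inf` outside support).
#' @param init Initial position (finite `log_target`).
#' @param lower,upper Support box.
#' @param control [mcmc_control()].
#' @param seed Integer RNG seed.
#' @return Object of class `npm_chain`: `samples` (stored post-burn-in
#'   states), `log_target` values, `acceptance_rate` (post-burn-in, full
#'   resolution), `step` (final), `control`, `seed`.
#' @export
mh_sample <- function(log_target, init, lower, upper,
                      control = mcmc_control(), seed = 1L) {
  set.seed(seed)
  d <- length(init)
  x <- as.numeric(init)
  lx <- log_target(x)
  if (!is.finite(lx)) stop("init has zero posterior density", call. = FALSE)
  ls <- log(control$initial_step)
  n_total <- control$burn_in + control$n_samples
  n_store <- floor(control$n_samples / control$store_every)
  samples <- matrix(NA_real_, n_store, d)
  lvals <- numeric(n_store)
  acc_burn <- 0L; acc_post <- 0L; acc_batch <- 0L
  batch <- 0L
  n_batches <- floor(control$burn_in / control$adapt_batch)
  tail_from <- max(1L, n_batches - floor(n_batches / 5) + 1L)
  ls_tail <- numeric(0)    # late-burn-in steps, averaged for the freeze
  si <- 0L
  for (t in seq_len(n_total)) {
    prop <- x + exp(ls) * rnorm(d)
    accept <- FALSE
    if (all(prop >= lower) && all(prop <= upper)) {
      lp <- log_target(prop)
      if (is.finite(lp) && log(runif(1)) < lp - lx) {
        x <- prop; lx <- lp; accept <- TRUE
      }
    }
    if (t <= control$burn_in) {
      if (accept) { acc_burn <- acc_burn + 1L; acc_batch <- acc_batch + 1L }
      if (t %% control$adapt_batch == 0L) {
        batch <- batch + 1L
        delta <- min(0.1, 1 / sqrt(batch))
        rate <- acc_batch / control$adapt_batch
        ls <- ls + if (rate > control$target_acceptance) delta else -delta
        acc_batch <- 0L
        if (batch >= tail_from) ls_tail <- c(ls_tail, ls)
      }
      # freeze at the average late-burn-in step, not the (noisy) last value
      if (t == control$burn_in && length(ls_tail) > 0) ls <- mean(ls_tail)
    } else {
      if (accept) acc_post <- acc_post + 1L
      k <- t - control$burn_in
      if (k %% control$store_every == 0 && si < n_store) {
        si <- si + 1L
        samples[si, ] <- x
        lvals[si] <- lx
      }
    }
    if (t == control$burn_in && acc_burn == 0L)
      stop("no accepted moves during burn-in; try a smaller initial_step",
           call. = FALSE)
  }
  structure(list(samples = samples[seq_len(si), , drop = FALSE],
                 log_target = lvals[seq_len(si)],
                 acceptance_rate = acc_post / control$n_samples,
                 burn_in_acceptance = acc_burn / max(1L, control$burn_in),
                 step = exp(ls), control = control, seed = seed),
            class = "npm_chain")
}

#' Sample the posterior over model parameters for a spectrum
#'
#' Runs [mh_sample()] on the gamma-likelihood posterior in normalized
#' coordinates with the uniform prior on `[-1, 1]^22`.  The chain starts at
#' the highest-likelihood state among `n_init` stable uniform draws from the
#' box: with a gamma-noise spectral likelihood the landscape carries many
#' shallow noise-induced local maxima, and a random-walk chain started in an
#' arbitrary basin can fail to leave it within any practical run length, so
#' a cheap preliminary screen of the prior is used to place the start in a
#' good basin.  The starting point affects convergence speed only, not the
#' stationary distribution.
#'
#' @param spec Band-selected `spectral_estimate`.
#' @param box `param_box`.
#' @param control [mcmc_control()].
#' @param seed Integer RNG seed.
#' @param n_init Number of stable uniform draws screened for the initial
#'   state (1 reproduces a plain random stable start).
#' @param max_init_tries Total draw limit while collecting stable candidates.
#' @param init Optional explicit initial state in normalized coordinates
#'   (e.g. a particle-swarm fit); overrides the screening.
#' @return `npm_chain` with column names over [param_names()].
#' @export
fit_mcmc <- function(spec, box = default_box(), control = mcmc_control(),
                     seed = 1L, n_init = 100, max_init_tries = 10000,
                     init = NULL) {
  lp <- .log_posterior(spec, box)
  set.seed(seed)
  if (is.null(init)) {
    best <- -Inf; found <- 0L
    for (i in seq_len(max_init_tries)) {
      cand <- runif(22, -1, 1)
      v <- lp(cand)
      if (is.finite(v)) {
        found <- found + 1L
        if (v > best) { best <- v; init <- cand }
        if (found >= n_init) break
      }
    }
  }
  if (is.null(init))
    stop("could not find a stable initial state in ", max_init_tries,
         " draws", call. = FALSE)
  chain <- mh_sample(lp, init, rep(-1, 22), rep(1, 22), control,
                     seed = seed + 1L)
  colnames(chain$samples) <- param_names()
  chain$box <- box
  chain
}

#' Evenly strided thinning of a chain
#'
#' Subsamples the stored post-burn-in states to `n` with stride
#' `floor(available / n)`.
#'
#' @param chain `npm_chain`.
#' @param n Number of samples to retain (default 1000).
#' @return Matrix `n x d` of normalized parameter samples.
#' @export
thin_chain <- function(chain, n = 1000) {
  m <- nrow(chain$samples)
  if (n > m) stop("chain provides only ", m, " stored samples", call. = FALSE)
  stride <- floor(m / n)
  idx <- seq(m - (n - 1) * stride, m, by = stride)
  chain$samples[idx, , drop = FALSE]
}

#' Local maximum-likelihood refinement of a parameter estimate
#'
#' Derivative-free simplex (Nelder-Mead) search on the negative log
#' posterior in normalized coordinates, with the uniform-prior support
#' enforced by a penalty.  Never returns a worse point than the start.
#'
#' @param spec Band-selected `spectral_estimate`.
#' @param theta0 Normalized 22-vector with finite posterior density.
#' @param box `param_box`.
#' @param maxit Simplex iteration budget.
#' @return List: `theta` (normalized), `params` (physical), `log_lik`,
#'   `alpha` (ML amplitude).
#' @export
ml_refine <- function(spec, theta0, box = default_box(), maxit = 2000) {
  lp <- .log_posterior(spec, box)
  f <- function(th) {
    v <- lp(th)
    if (is.finite(v)) -v else PENALTY_BASE * (1 + sum(pmax(abs(th) - 1, 0)))
  }
  opt <- optim(as.numeric(theta0), f, method = "Nelder-Mead",
               control = list(maxit = maxit))
  cand <- if (opt$value <= f(as.numeric(theta0))) opt$par else as.numeric(theta0)
  phys <- denormalize_params(cand, box)
  r <- spectrum_status(.theta_phys(phys), spec$freqs)
  a <- if (r$status == 0) alpha_ml(spec$power, r$S, .bin_shapes(spec)) else NA_real_
  list(theta = stats::setNames(cand, param_names()), params = phys,
       log_lik = -f(cand), alpha = a)
}

#' @export
print.npm_chain <- function(x, ...) {
  cat(sprintf("MH chain: %d stored samples (of %g post burn-in), acceptance %.3f, step %.4f\n",
              nrow(x$samples), x$control$n_samples, x$acceptance_rate, x$step))
  invisible(x)
}
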