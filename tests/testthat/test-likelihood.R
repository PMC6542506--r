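# Independent transcription of the closed-form profiled-amplitude
# log-likelihood (kept deliberately separate from the implementation).
loglik_closed_form <- function(S, S_hat, K) {
  N <- length(S)
  N * (K * log(K) - K - lgamma(K)) -
    N * K * log(mean(S / S_hat)) +
    sum((K - 1) * log(S / S_hat) - log(S_hat))
}

test_that("profiled amplitudes solve their 1-d optimizations", {
  set.seed(10)
  for (i in 1:25) {
    S <- exp(rnorm(40)); S_hat <- exp(rnorm(40))
    a_ls <- alpha_ls(S, S_hat)
    o_ls <- optimize(function(a) sum((a * S_hat - S)^2),
                     c(0, 10 * a_ls), tol = 1e-12)$minimum
    expect_equal(a_ls, o_ls, tolerance = 1e-7)
    a_ml <- alpha_ml(S, S_hat)
    # numeric maximizer of the unprofiled gamma likelihood over alpha
    nll <- function(a) -sum(dgamma(S, shape = 29, scale = a * S_hat / 29,
                                   log = TRUE))
    o_ml <- optimize(nll, c(a_ml / 10, 10 * a_ml), tol = 1e-12)$minimum
    expect_equal(a_ml, o_ml, tolerance = 1e-6)
  }
  S3 <- exp(rnorm(10))
  expect_equal(alpha_ls(3 * S3, S3), 3)   # S = 3 * S_hat
  expect_equal(alpha_ml(3 * S3, S3), 3)
  # the two amplitudes differ on asymmetric data
  S <- c(1, 10); S_hat <- c(1, 2)
  expect_false(isTRUE(all.equal(alpha_ls(S, S_hat), alpha_ml(S, S_hat))))
  expect_error(alpha_ls(S, c(0, 0)), "zero")
})

test_that("the two likelihood routes agree to 1e-10", {
  gt <- fx_ground_truth()
  spec <- fx_spectrum()
  # implementation: per-bin gamma log-pdfs at the profiled amplitude
  l_impl <- log_likelihood(gt$params, spec)
  # oracle: closed-form profiled-amplitude expression
  S_hat <- model_spectrum(gt$params, spec$freqs)
  l_closed <- loglik_closed_form(spec$power, S_hat, spec$K)
  expect_equal(l_impl, l_closed, tolerance = 1e-10)
})

test_that("rescaling the data shifts the log-likelihood by -N log c", {
  gt <- fx_ground_truth()
  spec <- fx_spectrum()
  N <- length(spec$freqs)
  l0 <- log_likelihood(gt$params, spec)
  for (c_ in c(0.2, 5)) {
    spec_c <- spectral_estimate(spec$freqs, c_ * spec$power, spec$K)
    expect_equal(log_likelihood(gt$params, spec_c), l0 - N * log(c_),
                 tolerance = 1e-8)
    # theta comparisons are therefore scale-invariant
    th2 <- denormalize_params(0.9 * gt$theta)
    expect_equal(log_likelihood_ratio(th2, gt$params, spec_c),
                 log_likelihood_ratio(th2, gt$params, spec),
                 tolerance = 1e-8)
  }
})

test_that("log-likelihood ratio matches the explicit three-term form", {
  gt <- fx_ground_truth()
  spec <- fx_spectrum()
  th_new <- denormalize_params(0.85 * gt$theta)
  expect_equal(log_likelihood_ratio(gt$params, gt$params, spec), 0)
  llr <- log_likelihood_ratio(th_new, gt$params, spec)
  expect_equal(llr, -log_likelihood_ratio(gt$params, th_new, spec))
  # independent transcription: K N {ln mean(S/S_old) - ln mean(S/S_new)}
  #                          + K sum{ln S_old_hat - ln S_new_hat}
  S <- spec$power; K <- spec$K; N <- length(S)
  Sh_old <- model_spectrum(gt$params, spec$freqs)
  Sh_new <- model_spectrum(th_new, spec$freqs)
  llr_explicit <- K * N * (log(mean(S / Sh_old)) - log(mean(S / Sh_new))) +
    K * sum(log(Sh_old) - log(Sh_new))
  expect_equal(llr, llr_explicit, tolerance = 1e-10)
})

test_that("least-squares cost vanishes at the generating parameters", {
  gt <- fx_ground_truth()
  S_hat <- model_spectrum(gt$params, gt$freqs)
  spec_exact <- spectral_estimate(gt$freqs, 2.7 * S_hat, gt$K)
  expect_equal(ls_cost(gt$params, spec_exact), 0, tolerance = 1e-12)
  # permutation invariance of the cost
  spec <- fx_spectrum()
  set.seed(5)
  perm <- sample(length(spec$freqs))
  c1 <- ls_cost(gt$params, spec)
  c2 <- sum((alpha_ls(spec$power[perm], S_hat[perm]) * S_hat[perm] -
               spec$power[perm])^2)
  expect_equal(c1, c2, tolerance = 1e-10)
})

test_that("the instability penalty dwarfs any achievable cost", {
  spec <- fx_spectrum()
  # flat-spectrum baseline: a constant model spectrum fit by amplitude alone
  flat_cost <- sum((mean(spec$power) - spec$power)^2)
  expect_gt(1e12, 1e3 * flat_cost)
  out_theta <- rep(1.5, 22)
  expect_gte(ls_cost(out_theta, spec, normalized = TRUE),
             1e12 * (1 + 0.5 * 22))
})

test_that("gamma quantile bands bracket the mean and tighten as K grows", {
  S_hat <- exp(seq(0, 2, length.out = 20))
  q <- spectral_quantiles(S_hat, alpha = 2, K = 29, q = c(0.16, 0.84))
  expect_true(all(q[, 1] < 2 * S_hat & 2 * S_hat < q[, 2]))
  qbig <- spectral_quantiles(S_hat, alpha = 2, K = 1e6, q = c(0.16, 0.84))
  expect_true(all(abs(qbig / (2 * S_hat) - 1) < 0.01))
  # independent root-found inversion of the gamma CDF
  for (p in c(0.16, 0.84)) {
    got <- unname(spectral_quantiles(S_hat[1], 2, 29, p)[1, 1])
    oracle <- uniroot(function(x) pgamma(x, shape = 29,
                                         scale = 2 * S_hat[1] / 29) - p,
                      c(1e-8, 50), tol = 1e-12)$root
    expect_equal(got, oracle, tolerance = 1e-8)
  }
  expect_error(spectral_quantiles(S_hat, 2, 29, 1.2), "quantile")
})

test_that("a zero-frequency bin uses the halved gamma shape", {
  gt <- fx_ground_truth()
  freqs <- c(0, seq(2, 5, by = 0.25))
  ss <- linearize(gt$params)
  S_hat <- transfer_gain(ss, freqs)
  set.seed(8)
  S <- rgamma(length(freqs), shape = 29, scale = S_hat / 29)
  spec0 <- suppressWarnings(spectral_estimate(freqs, S, K = 29))
  shapes <- ifelse(freqs == 0, 29 / 2, 29)
  a <- sum(shapes * S / S_hat) / sum(shapes)
  manual <- sum(dgamma(S, shape = shapes, scale = a * S_hat / shapes,
                       log = TRUE))
  expect_equal(log_likelihood(gt$params, spec0), manual, tolerance = 1e-10)
})

test_that("log-likelihood is continuous along segments inside the stable region", {
  spec <- fx_spectrum()
  gt <- fx_ground_truth()
  set.seed(21)
  lp <- function(th) log_likelihood(th, spec, normalized = TRUE)
  for (rep in 1:3) {
    d <- rnorm(22); d <- 0.02 * d / sqrt(sum(d^2))
    tgrid <- seq(-1, 1, length.out = 41)
    vals <- vapply(tgrid, function(t) lp(gt$theta + t * d), numeric(1))
    if (any(!is.finite(vals))) next
    jumps <- abs(diff(vals))
    expect_lt(max(jumps), 10 * stats::median(jumps) + 1)
  }
})
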