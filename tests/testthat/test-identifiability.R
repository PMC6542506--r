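test_that("histogram KLD has its closed-form values", {
  # exactly uniform across 10 bins
  x <- rep(seq(-0.9, 0.9, by = 0.2), 10)
  expect_equal(kld_hist(x), 0)
  # all mass in one bin
  x1 <- runif(50, -1, -0.85)
  expect_equal(kld_hist(x1), log(10), tolerance = 1e-12)
  # large uniform sample: estimator bias below 0.05 nats
  set.seed(6)
  expect_lt(kld_hist(runif(20000, -1, 1)), 0.05)
  expect_error(kld_hist(c(runif(30), 2)), "support")
  expect_error(kld_hist(runif(10)), "20")
})

test_that("KDE KLD matches the Gaussian-vs-uniform closed form", {
  set.seed(7)
  # posterior equal to the prior: near zero
  expect_lt(kld_kde(runif(1000, -1, 1)), 0.1)
  # narrow Gaussian on [-1, 1]: ln 2 - ln sigma - 0.5 ln(2 pi e)
  sig <- 0.02
  x <- rnorm(4000, 0, sig)
  want <- log(2) - log(sig) - 0.5 * log(2 * pi * exp(1))
  expect_equal(kld_kde(x), want, tolerance = 0.15 / want)
  expect_error(kld_kde(rep(0.5, 200)), "zero-variance")
  expect_error(kld_kde(runif(50)), "100")
})

test_that("the truncated KDE integrates to one on its grid", {
  set.seed(8)
  x <- rnorm(500, 0.9, 0.3)           # substantial mass beyond the support
  g <- seq(-1, 1, length.out = 100)
  bw <- bw.nrd0(x)
  f <- vapply(g, function(gi) mean(dnorm(gi, x, bw)), numeric(1))
  f <- f / alphamass:::.trapz(g, f)
  expect_equal(alphamass:::.trapz(g, f), 1, tolerance = 1e-3)
})

test_that("the Fisher information is K-linear, symmetric and PSD", {
  gt <- fx_ground_truth()
  freqs <- seq(2, 20, by = 2)
  f1 <- fisher_information(gt$theta, freqs, K = 29)
  f2 <- fisher_information(gt$theta, freqs, K = 58)
  expect_equal(f2$fim, 2 * f1$fim, tolerance = 1e-12)
  expect_equal(f1$fim, t(f1$fim), tolerance = 1e-12)
  ev <- eigen(f1$fim, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # single frequency: a rank-1 outer product
  fr1 <- fisher_information(gt$theta, 10, K = 29)
  e1 <- fim_eigen(fr1)
  expect_equal(e1$n_zero, 21L)
})

test_that("log-spectrum gradients agree with a step-halved Richardson oracle", {
  gt <- fx_ground_truth()
  freqs <- seq(2, 20, by = 1.5)
  box <- default_box()
  f_h <- fisher_information(gt$theta, freqs, K = 29, h = 1e-3)
  # Richardson extrapolation of 5-point stencils at h and h/2 has error
  # O(h^6); use it as the reference
  f_h2 <- fisher_information(gt$theta, freqs, K = 29, h = 5e-4)
  ref <- (16 * f_h2$grad - f_h$grad) / 15
  expect_lt(max(abs(f_h$grad - ref)) / max(abs(ref)), 1e-5)
})

test_that("eigenvalue thresholding flags near-null directions", {
  e_id <- fim_eigen(diag(22))
  expect_equal(e_id$n_zero, 0L)
  expect_equal(e_id$values, rep(1, 22))
  v <- rnorm(22)
  e_r1 <- fim_eigen(tcrossprod(v))
  expect_equal(e_r1$n_zero, 21L)
  expect_equal(sum(e_r1$values > 0), 1L)
  expect_true(all(diff(e_r1$raw_values) <= 1e-12))   # descending order
})

test_that("eigenvector-axis angles follow the direction cosines", {
  v_axis <- c(1, rep(0, 21))
  a <- eigenvector_angles(cbind(v_axis))
  expect_equal(unname(a[1, 1]), 0)
  expect_equal(unname(a[1, 2:22]), rep(90, 21))
  v_eq <- rep(1 / sqrt(22), 22)
  a_eq <- eigenvector_angles(cbind(v_eq))
  expect_equal(unname(a_eq[1, ]), rep(acos(1 / sqrt(22)) * 180 / pi, 22),
               tolerance = 1e-10)
  # sign flip maps angles to their supplements
  a_flip <- eigenvector_angles(cbind(-v_eq))
  expect_equal(unname(a_flip[1, ]), 180 - unname(a_eq[1, ]))
  expect_warning(eigenvector_angles(cbind(2 * v_axis)), "normaliz")
})

test_that("random directions in high dimension are nearly orthogonal to axes", {
  a22 <- random_direction_angles(22, 4000, seed = 9L)
  expect_lt(abs(mean(a22) - 90), 1.5)
  # dim 2: angles uniform on [0, 180]
  a2 <- random_direction_angles(2, 4000, seed = 10L)
  ks <- suppressWarnings(stats::ks.test(a2, "punif", 0, 180))
  expect_gt(ks$p.value, 0.01)
  # dim 22: density proportional to sin^20
  br <- seq(0, 180, length.out = 13)
  obs <- table(cut(a22, br))
  dens <- function(th) sin(th * pi / 180)^20
  pexp <- vapply(seq_len(12), function(i)
    integrate(dens, br[i], br[i + 1])$value, numeric(1))
  pexp <- pexp / sum(pexp)
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pexp))
  expect_gt(chi$p.value, 0.01)
})

test_that("directional spectral derivatives are consistent with the FIM gradient", {
  gt <- fx_ground_truth()
  freqs <- seq(2, 20, by = 1.5)
  fim <- fisher_information(gt$theta, freqs, K = 29)
  # along a parameter axis the directional derivative is the gradient column
  d <- c(rep(0, 13), 1, rep(0, 8))       # gamma_i axis
  dd <- spectral_mode_derivative(gt$theta, d, freqs)
  expect_equal(dd, unname(fim$grad[, "gamma_i"]), tolerance = 1e-8)
  # linearity in the direction
  d2 <- rep(1 / sqrt(22), 22)
  mix <- (d + d2) / sqrt(sum((d + d2)^2))
  dd_mix <- spectral_mode_derivative(gt$theta, mix, freqs)
  dd_sep <- (dd + spectral_mode_derivative(gt$theta, d2, freqs)) /
    sqrt(sum((d + d2)^2))
  expect_equal(dd_mix, dd_sep, tolerance = 1e-6)
  # along a thresholded-zero eigenvector the spectrum barely moves
  e <- fim_eigen(fim)
  v_null <- e$vectors[, 22]
  v_lead <- e$vectors[, 1]
  rms <- function(x) sqrt(mean(x^2))
  r_null <- rms(spectral_mode_derivative(gt$theta, v_null, freqs))
  r_lead <- rms(spectral_mode_derivative(gt$theta, v_lead, freqs))
  expect_lt(r_null, 1e-4 * r_lead)
})

test_that("sample correlations are a valid correlation matrix", {
  set.seed(11)
  m <- matrix(runif(200 * 22, -1, 1), ncol = 22,
              dimnames = list(NULL, param_names()))
  r <- sample_correlations(m)
  expect_equal(diag(r), rep(1, 22), ignore_attr = TRUE)
  expect_equal(r, t(r))
  expect_lt(max(abs(r[upper.tri(r)])), 3 / sqrt(200) + 0.15)
  m2 <- m; m2[, 2] <- m2[, 1]
  expect_equal(sample_correlations(m2)[1, 2], 1)
  m3 <- m; m3[, 3] <- 0.5
  expect_warning(sample_correlations(m3), "zero-variance")
  expect_error(sample_correlations(m[1:10, ]), "50")
})
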