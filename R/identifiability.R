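# Identifiability and sloppiness diagnostics: per-parameter KLD of posterior
# vs uniform prior, Fisher information eigen-analysis, eigenvector-axis
# angles, directional spectral derivatives, sample correlations.

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Histogram KLD of samples against a uniform prior
#'
#' Kullback-Leibler divergence of the histogram density of the samples from
#' the uniform density on the support, in nats; used for small independent
#' samples (e.g. retained PSO fits).  Empty bins contribute zero.
#'
#' @param x Samples (all inside the support).
#' @param support Length-2 interval, default `c(-1, 1)`.
#' @param bins Number of equal-width bins (default 10).
#' @return Divergence in nats.
#' @export
kld_hist <- function(x, support = c(-1, 1), bins = 10) {
  if (length(x) < 20) stop("need at least 20 samples", call. = FALSE)
  if (any(x < support[1] | x > support[2]))
    stop("samples outside the support", call. = FALSE)
  br <- seq(support[1], support[2], length.out = bins + 1)
  cnt <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), bins),
                  nbins = bins)
  p <- cnt / length(x)
  nz <- p > 0
  sum(p[nz] * log(p[nz] * bins))
}

#' Kernel-density KLD of samples against a uniform prior
#'
#' Gaussian kernel density estimate (Silverman bandwidth on the untruncated
#' sample) truncated to the support, renormalized, sampled on a uniform grid
#' and integrated by the trapezoid rule.  Used for MCMC samples.
#'
#' @param x Samples (>= 100).
#' @param support Length-2 interval.
#' @param gridpoints Grid size (default 100).
#' @return Divergence in nats.
#' @export
kld_kde <- function(x, support = c(-1, 1), gridpoints = 100) {
  if (length(x) < 100) stop("need at least 100 samples", call. = FALSE)
  if (sd(x) == 0) stop("degenerate (zero-variance) samples", call. = FALSE)
  bw <- bw.nrd0(x)
  g <- seq(support[1], support[2], length.out = gridpoints)
  f <- vapply(g, function(gi) mean(dnorm(gi, mean = x, sd = bw)), numeric(1))
  Z <- .trapz(g, f)
  f <- f / Z
  p0 <- 1 / diff(support)
  integrand <- ifelse(f > 0, f * log(f / p0), 0)
  .trapz(g, integrand)
}

#' Per-parameter KLD report for a sample matrix
#'
#' @param samples Matrix of normalized samples (columns = parameters).
#' @param estimator `"kde100"` (default, for MCMC samples) or `"hist10"`
#'   (for small PSO ensembles).
#' @param support Common support interval.
#' @return Data frame with `parameter` and `kld` (nats), plus the estimator
#'   tag and sample count as attributes.
#' @export
kld_report <- function(samples, estimator = c("kde100", "hist10"),
                       support = c(-1, 1)) {
  estimator <- match.arg(estimator)
  fn <- if (estimator == "kde100") kld_kde else kld_hist
  kld <- apply(samples, 2, fn, support = support)
  out <- data.frame(parameter = colnames(samples), kld = as.numeric(kld))
  attr(out, "estimator") <- estimator
  attr(out, "n") <- nrow(samples)
  out
}

# log model spectrum at a normalized point; errors propagate as NULL
.ln_spectrum <- function(theta_norm, freqs, box) {
  phys <- box$lower + (theta_norm + 1) / 2 * (box$upper - box$lower)
  r <- spectrum_status(as.numeric(phys), freqs)
  if (r$status != 0) return(NULL)
  log(r$S)
}

# 5-point central-difference gradient of ln S_hat w.r.t. normalized
# parameters; returns an N x 22 matrix or NULL if any stencil point fails.
.ln_spectrum_grad <- function(theta_norm, freqs, box, h) {
  n <- length(freqs)
  G <- matrix(NA_real_, n, 22)
  for (mu in seq_len(22)) {
    fs <- lapply(c(-2, -1, 1, 2), function(k) {
      th <- theta_norm
      th[mu] <- th[mu] + k * h
      .ln_spectrum(th, freqs, box)
    })
    if (any(vapply(fs, is.null, logical(1)))) return(NULL)
    G[, mu] <- (fs[[1]] - 8 * fs[[2]] + 8 * fs[[3]] - fs[[4]]) / (12 * h)
  }
  G
}

#' Fisher information matrix at a parameter point
#'
#' `I[mu, nu] = K * sum_n d ln S_hat_n / d theta_mu * d ln S_hat_n / d
#' theta_nu`, with derivatives taken with respect to normalized parameters by
#' 5-point central finite differences at step `h`.  Because the amplitude
#' alpha is profiled analytically and log-spectrum derivatives are
#' scale-invariant, alpha contributes no information and does not appear.
#' If any stencil evaluation lands on an unstable parameter set, the step is
#' shrunk once by a factor 10 before giving up.
#'
#' @param theta Normalized 22-vector (stable interior point).
#' @param freqs Frequency grid in Hz.
#' @param K Gamma shape (Welch segment count).
#' @param box `param_box`.
#' @param h Finite-difference step in normalized units (default 1e-3).
#' @return Object of class `fim_result`: `fim` (22x22, symmetric), `grad`
#'   (N x 22 matrix of log-spectrum derivatives), `h`, `K`, `freqs`, `theta`.
#' @export
fisher_information <- function(theta, freqs, K, box = default_box(), h = 1e-3) {
  G <- .ln_spectrum_grad(as.numeric(theta), freqs, box, h)
  if (is.null(G)) {
    h <- h / 10
    G <- .ln_spectrum_grad(as.numeric(theta), freqs, box, h)
    if (is.null(G))
      stop("finite-difference stencil hit an unstable parameter set even ",
           "after shrinking h", call. = FALSE)
  }
  fim <- K * crossprod(G)
  fim <- (fim + t(fim)) / 2
  dimnames(fim) <- list(param_names(), param_names())
  colnames(G) <- param_names()
  structure(list(fim = fim, grad = G, h = h, K = K, freqs = freqs,
                 theta = as.numeric(theta)), class = "fim_result")
}

#' Thresholded eigen-decomposition of a Fisher information matrix
#'
#' Eigenvalues in descending order; values that are negative or smaller than
#' `threshold` times the largest eigenvalue are set to zero and counted.
#'
#' @param fim `fim_result` or a symmetric matrix.
#' @param threshold Relative zero threshold (default 1e-10).
#' @return List: `values` (thresholded), `raw_values`, `vectors` (columns),
#'   `n_zero`.
#' @export
fim_eigen <- function(fim, threshold = 1e-10) {
  M <- if (inherits(fim, "fim_result")) fim$fim else fim
  e <- eigen(M, symmetric = TRUE)
  raw <- e$values
  lmax <- max(raw)
  zero <- raw < 0 | raw < threshold * lmax
  vals <- ifelse(zero, 0, raw)
  list(values = vals, raw_values = raw, vectors = e$vectors,
       n_zero = sum(zero))
}

#' Angles between eigenvectors and parameter axes
#'
#' For each unit eigenvector, the inverse cosines of its components: 0 or
#' 180 degrees mean perfect alignment with a parameter axis, 90 degrees
#' orthogonality.
#'
#' @param vectors Matrix with unit-norm eigenvectors in columns.
#' @return Matrix (eigenvector x parameter) of angles in degrees.
#' @export
eigenvector_angles <- function(vectors) {
  vectors <- as.matrix(vectors)
  nrm <- sqrt(colSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-8)) {
    warning("non-unit eigenvector(s); normalizing", call. = FALSE)
    vectors <- sweep(vectors, 2, nrm, "/")
  }
  ang <- acos(pmin(pmax(t(vectors), -1), 1)) * 180 / pi
  dimnames(ang) <- list(paste0("v", seq_len(nrow(ang))), rownames(vectors))
  ang
}

#' Null distribution of angles to a random direction
#'
#' Angles between uniformly random unit vectors in `dim` dimensions and a
#' fixed parameter axis; the density is proportional to `sin^(dim-2)` of the
#' angle.  Serves as the null comparison for eigenvector-axis angles.
#'
#' @param dim Dimension (default 22).
#' @param n Number of random directions.
#' @param seed Integer RNG seed.
#' @return Vector of angles in degrees.
#' @export
random_direction_angles <- function(dim = 22, n, seed = 1L) {
  set.seed(seed)
  Z <- matrix(rnorm(n * dim), nrow = dim)
  acos(Z[1, ] / sqrt(colSums(Z^2))) * 180 / pi
}

#' Directional derivative of the log model spectrum
#'
#' 5-point central-difference derivative of `ln S_hat` along a unit direction
#' in normalized parameter space; used to interpret the leading Fisher
#' eigenvectors as spectral modes (peak position, height, width).
#'
#' @param theta Normalized 22-vector.
#' @param direction Unit 22-vector.
#' @param freqs Frequency grid in Hz.
#' @param box `param_box`.
#' @param h Step in normalized units.
#' @return Per-frequency derivative vector.
#' @export
spectral_mode_derivative <- function(theta, direction, freqs,
                                     box = default_box(), h = 1e-3) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-8) {
    warning("non-unit direction; normalizing", call. = FALSE)
    direction <- direction / nrm
  }
  ev <- function(k) .ln_spectrum(as.numeric(theta) + k * h * direction,
                                 freqs, box)
  fs <- lapply(c(-2, -1, 1, 2), ev)
  if (any(vapply(fs, is.null, logical(1)))) {
    h <- h / 10
    fs <- lapply(c(-2, -1, 1, 2), ev)
    if (any(vapply(fs, is.null, logical(1))))
      stop("directional stencil hit an unstable parameter set", call. = FALSE)
  }
  (fs[[1]] - 8 * fs[[2]] + 8 * fs[[3]] - fs[[4]]) / (12 * h)
}

#' Pearson correlations of parameter samples
#'
#' @param samples Matrix of samples (>= 50 rows, columns = parameters).
#' @return Correlation matrix; zero-variance columns yield NA entries with a
#'   warning.
#' @export
sample_correlations <- function(samples) {
  if (nrow(samples) < 50) stop("need at least 50 samples", call. = FALSE)
  sds <- apply(samples, 2, sd)
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(samples)[sds == 0], collapse = ", "),
            "; correlations undefined there", call. = FALSE)
  suppressWarnings(cor(samples))
}
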