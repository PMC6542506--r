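# Welch spectral estimation, band selection, spectrum/time-series containers.

#' Construct a time-series object
#'
#' @param samples Numeric vector of potential samples (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param channel Channel label.
#' @return Object of class `npm_timeseries`.
#' @export
timeseries <- function(samples, fs, channel = "sim") {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs, channel = channel),
            class = "npm_timeseries")
}

#' Construct a spectral estimate
#'
#' The data object fitted by the likelihood: a frequency grid, spectral
#' powers, and the gamma shape K (the number of Welch segments averaged,
#' which sets the per-bin sampling distribution).
#'
#' @param freqs Strictly increasing frequencies in Hz.
#' @param power Positive spectral powers, same length as `freqs`.
#' @param K Integer gamma shape (averaged segment count), >= 1.
#' @param window,window_s,overlap,source Metadata.
#' @return Object of class `spectral_estimate`.
#' @export
spectral_estimate <- function(freqs, power, K, window = NA, window_s = NA,
                              overlap = NA, source = NA) {
  if (length(freqs) != length(power))
    stop("freqs and power must have the same length", call. = FALSE)
  if (is.unsorted(freqs, strictly = TRUE))
    stop("freqs must be strictly increasing", call. = FALSE)
  if (any(power < 0)) stop("negative spectral power", call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  df <- diff(freqs)
  if (length(df) > 1 && (max(df) - min(df)) > 1e-8 * max(df))
    warning("non-uniform frequency grid; model is evaluated per-bin",
            call. = FALSE)
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 K = as.integer(K), window = window, window_s = window_s,
                 overlap = overlap, source = source),
            class = "spectral_estimate")
}

#' Welch power spectral estimate
#'
#' Averaged one-sided periodogram over overlapping Hamming-windowed segments.
#' Each segment has its mean removed (no linear detrend) before windowing.
#' The density normalization is `|X|^2 / (fs * sum(w^2))` with non-DC,
#' non-Nyquist bins doubled; the absolute scale is irrelevant to fitting
#' because the amplitude alpha is profiled out.  The number of segments,
#' `K = floor((T - window_s) / (window_s * (1 - overlap))) + 1`, is stored as
#' the gamma shape of the per-bin sampling distribution.
#'
#' @param ts `npm_timeseries` (or numeric vector, with `fs` supplied).
#' @param fs Sampling rate in Hz if `ts` is a bare vector.
#' @param window_s Segment length in seconds (default 4).
#' @param overlap Fractional overlap in [0, 1) (default 0.5).
#' @return A [spectral_estimate()] with frequency resolution `1/window_s` Hz.
#' @export
welch_spectrum <- function(ts, fs = NULL, window_s = 4, overlap = 0.5) {
  if (inherits(ts, "npm_timeseries")) {
    x <- ts$samples; fs <- ts$fs
  } else {
    if (is.null(fs)) stop("fs required for a bare sample vector", call. = FALSE)
    x <- as.numeric(ts)
  }
  L <- round(window_s * fs)
  n <- length(x)
  if (n < L)
    stop("time series too short: ", n, " samples < one ", window_s,
         "-s window (", L, " samples)", call. = FALSE)
  step <- round(L * (1 - overlap))
  K <- floor((n - L) / step) + 1
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hamming
  norm <- fs * sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (k in seq_len(K)) {
    seg <- x[(1 + (k - 1) * step):((k - 1) * step + L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    P <- (Mod(X)^2) / norm
    # one-sided: double all bins except DC and (for even L) Nyquist
    dbl <- rep(2, nf); dbl[1] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    acc <- acc + P * dbl
  }
  freqs <- (seq_len(nf) - 1) * fs / L
  spectral_estimate(freqs, acc / K, K, window = "hamming",
                    window_s = window_s, overlap = overlap, source = "welch")
}

#' Restrict a spectral estimate to a frequency band
#'
#' Inclusive endpoints; the zero-frequency bin is always excluded (so the
#' K/2 shape rule for the DC bin is never needed in fitting).  Bins with zero
#' power are rejected with a warning.
#'
#' @param spec `spectral_estimate`.
#' @param fmin,fmax Band limits in Hz (defaults 2 and 20).
#' @return A `spectral_estimate` restricted to the band.
#' @export
band_select <- function(spec, fmin = 2, fmax = 20) {
  keep <- spec$freqs >= fmin & spec$freqs <= fmax & spec$freqs > 0
  if (!any(keep)) stop("band [", fmin, ", ", fmax, "] Hz does not intersect ",
                       "the frequency grid", call. = FALSE)
  if (any(spec$power[keep] == 0)) {
    warning("rejecting ", sum(spec$power[keep] == 0),
            " zero-power bin(s) in the band", call. = FALSE)
    keep <- keep & spec$power > 0
  }
  spectral_estimate(spec$freqs[keep], spec$power[keep], spec$K,
                    window = spec$window, window_s = spec$window_s,
                    overlap = spec$overlap, source = spec$source)
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("Spectral estimate: %d bins, %.3g-%.3g Hz, K = %d (%s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$K,
              ifelse(is.na(x$source), "unknown source", x$source)))
  invisible(x)
}
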