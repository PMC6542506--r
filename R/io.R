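# Plain-text I/O for spectra and time series.
#
# Spectrum CSV dialect: '#'-prefixed header lines carrying K and the Welch
# settings, then columns frequency_hz, power.  K is required on read because
# the gamma likelihood needs it.  Values are written with 17 significant
# digits so write -> read round-trips at full double precision.

.write_header <- function(con, fields) {
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.null(v) && !is.na(v)) cat(sprintf("# %s: %s\n", nm, v), file = con)
  }
}

.read_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (l in hdr) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

#' Write / read a spectral estimate as CSV
#'
#' @param spec `spectral_estimate`.
#' @param path File path.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(K = spec$K, window = spec$window,
                          window_s = spec$window_s, overlap = spec$overlap,
                          source = spec$source))
  cat("frequency_hz,power\n", file = con)
  cat(sprintf("%.17g,%.17g\n", spec$freqs, spec$power), file = con, sep = "")
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  hdr <- .read_header(path)
  if (is.null(hdr$K))
    stop("spectrum file lacks the required 'K' header (gamma shape)",
         call. = FALSE)
  df <- read.csv(path, comment.char = "#")
  if (!all(c("frequency_hz", "power") %in% names(df)))
    stop("expected columns frequency_hz, power", call. = FALSE)
  if (any(df$power < 0))
    stop("negative spectral power in ", path, call. = FALSE)
  num_or_na <- function(v) if (is.null(v)) NA else suppressWarnings(as.numeric(v))
  spectral_estimate(df$frequency_hz, df$power, as.integer(hdr$K),
                    window = if (is.null(hdr$window)) NA else hdr$window,
                    window_s = num_or_na(hdr$window_s),
                    overlap = num_or_na(hdr$overlap),
                    source = if (is.null(hdr$source)) NA else hdr$source)
}

#' Write / read a time series as CSV
#'
#' @param ts `npm_timeseries`.
#' @param path File path.
#' @export
write_timeseries <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(fs_hz = ts$fs, channel = ts$channel))
  cat("sample\n", file = con)
  cat(sprintf("%.17g\n", ts$samples), file = con, sep = "")
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  hdr <- .read_header(path)
  if (is.null(hdr$fs_hz))
    stop("time-series file lacks the required 'fs_hz' header", call. = FALSE)
  df <- read.csv(path, comment.char = "#")
  timeseries(df$sample, as.numeric(hdr$fs_hz),
             channel = if (is.null(hdr$channel)) NA else hdr$channel)
}
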