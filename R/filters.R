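#' Band definition
#'
#' Describes one analysis band of the multi-frequency decomposition.
#' `order` is the design order of the underlying Butterworth low-pass
#' prototype *before* forward-backward application, so the effective
#' magnitude response of [zero_phase_bandpass()] is the square of an
#' order-`order` band-pass.
#'
#' @param name Band name, e.g. `"SCG"`.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high`.
#' @param order Butterworth design order (default 2).
#' @return An object of class `"band_definition"`.
#' @export
band_definition <- function(name, low, high, order = 2) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(is.finite(low) && is.finite(high) && low > 0 && high > low))
    stop("invalid band edges: need 0 < low < high")
  if (order < 1) stop("filter order must be >= 1")
  structure(list(name = name, low = low, high = high, order = order),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz, order %d>\n", x$name, x$low, x$high,
              as.integer(x$order)))
  invisible(x)
}

#' Canonical analysis bands
#'
#' The four bands used throughout the package: filtered ECG (1-40 Hz),
#' ULF-SCG (1-5 Hz, cardiac volume change), SCG (5-30 Hz, valve and
#' contraction fiducials) and PCG (20-200 Hz, heart sounds).
#'
#' @return Named list of [band_definition()] objects.
#' @export
canonical_bands <- function() {
  list(
    "ECG"     = band_definition("ECG", 1, 40),
    "ULF-SCG" = band_definition("ULF-SCG", 1, 5),
    "SCG"     = band_definition("SCG", 5, 30),
    "PCG"     = band_definition("PCG", 20, 200)
  )
}

# polynomial coefficients (descending powers) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0i) - c(0i, p * ri)
  p
}

#' Digital Butterworth band-pass design
#'
#' Designs an order-`order` Butterworth band-pass by the standard route:
#' analog low-pass prototype, low-pass-to-band-pass transform with
#' pre-warped edge frequencies, then the bilinear transform.
#'
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz; requires `high < fs/2`.
#' @param order Design order of the low-pass prototype (default 2); the
#'   resulting band-pass has `2 * order` poles.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low, high, fs, order = 2) {
  if (high >= fs / 2) stop("band edge ", high, " Hz is not below Nyquist (fs = ", fs, " Hz)")
  if (low <= 0 || low >= high) stop("invalid band edges: need 0 < low < high < fs/2")
  k <- seq_len(order)
  # low-pass prototype poles on the unit circle, left half plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each prototype pole splits into a pair
  pb <- p * bw / 2
  pbp <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  # bilinear transform; analog zeros (order of them) sit at s = 0
  pd <- (fs2 + pbp) / (fs2 - pbp)
  zd <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  kd <- Re(bw^order * fs2^order / prod(fs2 - pbp))
  a <- Re(poly_from_roots(pd))
  b <- kd * Re(poly_from_roots(zd))
  list(b = b, a = a)
}

# single-pass IIR filter y: a(z) Y = b(z) X, via C-level stats::filter
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[(nb - 1) + seq_along(x)]
  if (length(a) > 1) {
    as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  } else {
    v
  }
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the designed band-pass forward and backward (filtfilt), giving
#' zero net phase shift and the squared magnitude response of the design.
#' Edges are handled by even-reflection padding of `pad` samples at both
#' ends (default three times the filter length).
#'
#' @param x Numeric trace.
#' @param band A [band_definition()].
#' @param sampling_rate Sampling rate in Hz.
#' @param pad Reflection pad length in samples; `NULL` uses
#'   `3 * (2 * order + 1)`.
#' @return Filtered trace, same length as `x`.
#' @export
zero_phase_bandpass <- function(x, band, sampling_rate, pad = NULL) {
  stopifnot(inherits(band, "band_definition"))
  ba <- butter_bandpass(band$low, band$high, sampling_rate, band$order)
  flen <- max(length(ba$a), length(ba$b))
  if (is.null(pad)) pad <- 3 * flen
  if (length(x) <= pad) stop("input shorter than filter warm-up (", pad, " samples)")
  n <- length(x)
  # even reflection about the endpoints (endpoint not repeated)
  head_pad <- x[(pad + 1):2]
  tail_pad <- x[(n - 1):(n - pad)]
  xe <- c(head_pad, x, tail_pad)
  y <- iir_filter(ba$b, ba$a, xe)
  y <- rev(iir_filter(ba$b, ba$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Decompose a recording into the canonical bands
#'
#' Splits the composite vibration channel into ULF-SCG, SCG and PCG, and
#' band-limits the ECG channel to 1-40 Hz, all with [zero_phase_bandpass()].
#'
#' @param vibration Composite vibration trace.
#' @param ecg Synchronized ECG trace, same length.
#' @param sampling_rate Sampling rate in Hz.
#' @param bands List of [band_definition()]s; default [canonical_bands()].
#' @return Named list of filtered traces (`ECG`, `ULF-SCG`, `SCG`, `PCG`)
#'   with the band metadata attached as attribute `"bands"`.
#' @export
decompose_bands <- function(vibration, ecg, sampling_rate,
                            bands = canonical_bands()) {
  if (length(vibration) != length(ecg))
    stop("vibration and ecg channels must have equal length")
  out <- lapply(bands, function(bd) {
    src <- if (bd$name == "ECG") ecg else vibration
    zero_phase_bandpass(src, bd, sampling_rate)
  })
  names(out) <- names(bands)
  attr(out, "bands") <- bands
  out
}

#' Spectral centroid of a trace
#'
#' Power-weighted mean frequency over the 0..Nyquist half-spectrum; used as
#' the frequency-ordering oracle for intrinsic mode functions.
#'
#' @param x Numeric trace.
#' @param sampling_rate Sampling rate in Hz.
#' @return Centroid frequency in Hz (NA for an all-zero trace).
#' @export
spectral_centroid <- function(x, sampling_rate) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  half <- seq_len(floor(n / 2) + 1)
  f <- (half - 1) * sampling_rate / n
  p <- sp[half]
  if (sum(p) == 0) return(NA_real_)
  sum(f * p) / sum(p)
}

#' Fraction of spectral energy inside a band
#'
#' @param x Numeric trace.
#' @param low,high Band edges in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @return Fraction in `[0, 1]`.
#' @export
band_energy_fraction <- function(x, low, high, sampling_rate) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  half <- seq_len(floor(n / 2) + 1)
  f <- (half - 1) * sampling_rate / n
  p <- sp[half]
  tot <- sum(p)
  if (tot == 0) return(NA_real_)
  sum(p[f >= low & f <= high]) / tot
}
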