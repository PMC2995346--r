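#' Spatial Gabor filter specification
#'
#' Even and odd spatial filters are Gabor functions
#' `E(x) = cos(2*pi*f*x) * exp(-(x/sigma)^2)` and
#' `O(x) = sin(2*pi*f*x) * exp(-(x/sigma)^2)`,
#' sampled on `[-extent/2, extent/2)` at spacing `dx`.
#'
#' @param f Carrier spatial frequency, cycles/degree (default 1.1).
#' @param sigma Gaussian envelope scale, degrees (default 0.5).
#' @param extent Spatial support, degrees (default 4, centred on 0).
#' @param dx Sample spacing, degrees; must match the stimulus grid.
#' @return An object of class `spatial_filter_spec` including the sample
#'   coordinates `x`.
#' @export
spatial_filter_spec <- function(f = 1.1, sigma = 0.5, extent = 4, dx = 0.05) {
  stopifnot(f > 0, sigma > 0, extent > 0, dx > 0)
  n <- as.integer(round(extent / dx))
  structure(
    list(f = f, sigma = sigma, extent = extent, dx = dx,
         x = seq(-extent / 2, by = dx, length.out = n)),
    class = "spatial_filter_spec"
  )
}

#' Even spatial filter profile
#' @param spec A [spatial_filter_spec()].
#' @return Numeric vector `E(x)` on the spec's sample points.
#' @export
spatial_even <- function(spec) {
  stopifnot(inherits(spec, "spatial_filter_spec"))
  cos(2 * pi * spec$f * spec$x) * exp(-(spec$x / spec$sigma)^2)
}

#' Odd spatial filter profile
#' @param spec A [spatial_filter_spec()].
#' @return Numeric vector `O(x)` on the spec's sample points.
#' @export
spatial_odd <- function(spec) {
  stopifnot(inherits(spec, "spatial_filter_spec"))
  sin(2 * pi * spec$f * spec$x) * exp(-(spec$x / spec$sigma)^2)
}

#' Biphasic temporal filter specification
#'
#' The temporal impulse response is
#' `R(t) = (kt)^n * exp(-kt) * [1/n! - beta*(kt)^2/(n+2)!]`,
#' a gamma-function difference with one positive lobe followed by one
#' negative lobe. The scale factor `k` (1/s) controls the filter's speed
#' and hence its centre temporal frequency; `n = 9` gives the slow filter
#' and `n = 6` the fast one; `beta` weights the negative lobe.
#'
#' @param k Scale factor, 1/seconds (> 0); the fitted quantity.
#' @param n Integer exponent; 9 (slow) or 6 (fast) by convention.
#' @param beta Negative-lobe weighting in `[0, 1)` (default 0.9).
#' @param extent Temporal support, seconds (default 0.5).
#' @param dt Sample spacing, seconds.
#' @return An object of class `temporal_filter_spec` including sample
#'   times `t` on `[0, extent)`.
#' @export
temporal_filter_spec <- function(k, n = 9, beta = 0.9, extent = 0.5,
                                 dt = 0.005) {
  stopifnot(k > 0, n >= 1, n == round(n), beta >= 0, beta < 1,
            extent > 0, dt > 0)
  m <- as.integer(round(extent / dt))
  structure(
    list(k = k, n = as.integer(n), beta = beta, extent = extent, dt = dt,
         t = seq(0, by = dt, length.out = m)),
    class = "temporal_filter_spec"
  )
}

# R(t) evaluated overflow-safely at arbitrary times (log-space factorials
# and powers; (kt)^n underflows gracefully for kt near 0).
.temporal_impulse <- function(t, k, n, beta) {
  out <- numeric(length(t))
  pos <- t > 0
  kt <- k * t[pos]
  lead <- exp(n * log(kt) - kt - lfactorial(n))
  tail <- exp((n + 2) * log(kt) - kt - lfactorial(n + 2))
  out[pos] <- lead - beta * tail
  out
}

#' Temporal impulse response
#'
#' @param spec A [temporal_filter_spec()].
#' @return Numeric vector `R(t)` on the spec's sample times; `R(0) = 0`,
#'   and the response is biphasic (exactly one sign change) for the
#'   default parameters.
#' @export
temporal_response <- function(spec) {
  stopifnot(inherits(spec, "temporal_filter_spec"))
  .temporal_impulse(spec$t, spec$k, spec$n, spec$beta)
}

#' Closed-form amplitude spectrum of the temporal filter
#'
#' The Fourier transform of the impulse response is
#' `F(w) = k^n / (k + iw)^(n+1) * [1 - beta * k^2 / (k + iw)^2]`
#' (angular frequency `w = 2*pi*f`). Exposed for oracle comparison with
#' the FFT-based estimate; `|F(0)| = (1 - beta)/k` (small nonzero DC gain).
#'
#' @param f_hz Frequencies in Hz at which to evaluate the amplitude.
#' @param spec A [temporal_filter_spec()].
#' @return Numeric vector `|F(2*pi*f_hz)|`.
#' @export
temporal_amplitude <- function(f_hz, spec) {
  stopifnot(inherits(spec, "temporal_filter_spec"))
  w <- 2 * pi * f_hz
  z <- complex(real = spec$k, imaginary = w)
  Mod(spec$k^spec$n / z^(spec$n + 1) * (1 - spec$beta * spec$k^2 / z^2))
}

#' Centre frequency of the temporal filter
#'
#' Frequency of the peak of the amplitude spectrum of the impulse
#' response, estimated by a zero-padded FFT. The response is first
#' re-sampled on an extent long enough to contain its tail (the stored
#' extent is doubled as needed; a warning is issued when the stored extent
#' truncates the response). Because the impulse response depends on time
#' only through `kt`, the centre frequency is proportional to `k`.
#'
#' @param spec A [temporal_filter_spec()].
#' @param resolution Frequency resolution of the padded transform, Hz
#'   (default 0.005).
#' @return Peak frequency in Hz.
#' @export
centre_frequency <- function(spec, resolution = 0.005) {
  stopifnot(inherits(spec, "temporal_filter_spec"))
  r0 <- temporal_response(spec)
  if (abs(r0[length(r0)]) > 1e-6 * max(abs(r0))) {
    warning("temporal filter extent truncates the response tail; ",
            "using a longer extent for spectrum estimation")
  }
  extent <- spec$extent
  repeat {
    tt <- seq(0, by = spec$dt, length.out = as.integer(round(extent / spec$dt)))
    r <- .temporal_impulse(tt, spec$k, spec$n, spec$beta)
    if (abs(r[length(r)]) <= 1e-6 * max(abs(r)) || extent >= 16) break
    extent <- extent * 2
  }
  n_pad <- stats::nextn(max(length(r), ceiling(1 / (resolution * spec$dt))))
  amp <- Mod(stats::fft(c(r, rep(0, n_pad - length(r)))))
  half <- seq_len(n_pad %/% 2)
  freqs <- (half - 1) / (n_pad * spec$dt)
  freqs[which.max(amp[half])]
}

#' Round a centre frequency to reporting granularity
#'
#' Centre frequencies are conventionally reported to the nearest 0.5 Hz.
#'
#' @param f_hz Frequency in Hz.
#' @param step Rounding step, Hz (default 0.5).
#' @return Rounded frequency.
#' @export
round_centre_frequency <- function(f_hz, step = 0.5) {
  round(f_hz / step) * step
}
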