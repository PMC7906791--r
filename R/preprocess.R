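#' Welch spectral estimation settings
#'
#' Defaults follow the convention used throughout the package: a
#' 1024-point DFT, Hann window of length 128, 50% segment overlap.
#'
#' @param n_dft Number of DFT points (zero-padded when longer than the
#'   window).
#' @param window_length Hann window length in samples
#'   (<= `n_dft`).
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(n_dft = 1024, window_length = 128,
                            overlap = 0.5) {
  stopifnot(window_length >= 2, window_length <= n_dft,
            overlap >= 0, overlap < 1)
  structure(list(n_dft = n_dft, window_length = window_length,
                 overlap = overlap),
            class = "spectral_config")
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Welch power spectral density estimate
#'
#' One-sided PSD from Hann-windowed, overlapping segments, averaged and
#' scaled as a density (units^2 / Hz). Frequency resolution is
#' `1 / (n_dft * dt)`.
#'
#' @param ts A [time_series] (or numeric vector plus `dt`).
#' @param cfg A [spectral_config].
#' @param dt Sampling interval, only when `ts` is a bare vector.
#' @return An object of class `spectrum_estimate` with elements
#'   `freqs` (Hz) and `psd`.
#' @export
#' @examples
#' ts <- time_series(sin(2 * pi * 0.05 * 0:899), dt = 1)
#' sp <- welch_psd(ts)
#' sp$freqs[which.max(sp$psd)]  # ~0.05 Hz
welch_psd <- function(ts, cfg = spectral_config(), dt = NULL) {
  ts <- as_time_series(ts, dt)
  x <- ts$values
  L <- cfg$window_length
  if (length(x) < L) {
    stop(sprintf("input too short for Welch estimation: %d < window %d",
                 length(x), L))
  }
  fs <- 1 / ts$dt
  w <- hann_window(L)
  step <- max(1L, as.integer(round(L * (1 - cfg$overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  nfft <- cfg$n_dft
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    X <- stats::fft(c(seg, rep(0, nfft - L)))
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * fs * sum(w^2))
  half <- nfft %/% 2 + 1L
  one <- pxx[seq_len(half)]
  if (half > 2L) {
    inner <- 2:(half - 1L)
    one[inner] <- 2 * one[inner]   # fold negative frequencies
    if (nfft %% 2 == 1L) one[half] <- 2 * one[half]
  }
  structure(list(freqs = (seq_len(half) - 1L) * fs / nfft, psd = one,
                 dt = ts$dt, config = cfg),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d bins, 0-%g Hz, df=%g Hz\n",
              length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' Write a spectrum as two-column delimited text
#' @param spec A `spectrum_estimate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.table(data.frame(freq_hz = spec$freqs, psd = spec$psd),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' High-frequency power normalisation
#'
#' Removes the mean and rescales the trace so that its mean Welch PSD
#' above `cutoff` equals one. Spectra of vessel traces flatten above
#' about 0.2 Hz, so this brings the high-frequency noise floor of all
#' signals to a common unit baseline while preserving relative
#' low-frequency oscillation strength. The divisor is the square root
#' of the mean high-frequency PSD (power scales quadratically with
#' amplitude, so this is the scaling that achieves a unit baseline);
#' `literal_division = TRUE` divides the values by the mean PSD itself
#' instead.
#'
#' @param ts A [time_series].
#' @param cutoff High-frequency cutoff in Hz.
#' @param cfg [spectral_config] used for the PSD estimate.
#' @param literal_division Divide by the mean PSD rather than its
#'   square root.
#' @return The normalised [time_series]; `meta$normalized` is set.
#' @export
frequency_normalize <- function(ts, cutoff = 0.2,
                                cfg = spectral_config(),
                                literal_division = FALSE) {
  ts <- as_time_series(ts)
  x <- ts$values - mean(ts$values)
  sp <- welch_psd(time_series(x, ts$dt), cfg)
  sel <- sp$freqs > cutoff
  if (!any(sel)) {
    stop(sprintf("no frequencies above %g Hz at dt=%g s", cutoff, ts$dt))
  }
  m <- mean(sp$psd[sel])
  if (m <= 0) stop("zero high-frequency power: degenerate input")
  div <- if (literal_division) m else sqrt(m)
  out <- ts
  out$values <- x / div
  out$meta$normalized <- TRUE
  out$meta$normalization_divisor <- div
  out
}

companion_matrix <- function(a) {
  n <- length(a) - 1L
  M <- matrix(0, n, n)
  M[1, ] <- -a[-1] / a[1]
  if (n > 1) M[cbind(2:n, 1:(n - 1))] <- 1
  M
}

# Steady-state initial filter state (direct-form II transposed) so that
# the filter response to a step of the first sample has no transient.
filter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  IminusA <- diag(n - 1L) - t(companion_matrix(a))
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(IminusA, B))
}

# Direct-form II transposed IIR filter with initial state zi.
df2t_filter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  z <- if (is.null(zi)) rep(0, n - 1L) else zi
  y <- numeric(length(x))
  nz <- n - 1L
  for (t in seq_along(x)) {
    xt <- x[t]
    yt <- b[1] * xt + z[1]
    if (nz > 1L) {
      z[1:(nz - 1L)] <- b[2:nz] * xt + z[2:nz] - a[2:nz] * yt
    }
    z[nz] <- b[n] * xt - a[n] * yt
    y[t] <- yt
  }
  y
}

# Zero-phase filtering: odd-reflection padding plus forward-backward
# passes with steady-state initial conditions.
filtfilt_refl <- function(b, a, x) {
  nfact <- 3L * (max(length(a), length(b)) - 1L)
  if (length(x) <= nfact) {
    stop(sprintf("input too short for zero-phase filtering (need > %d samples)",
                 nfact))
  }
  n <- length(x)
  pre <- 2 * x[1] - x[(nfact + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - nfact)]
  xp <- c(pre, x, post)
  zi <- filter_zi(b, a)
  y <- df2t_filter(b, a, xp, zi * xp[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Butterworth design followed by forward-backward (zero-phase)
#' application, so a within-band sinusoid passes with no group delay.
#' The forward-backward pass squares the magnitude response, giving an
#' effective order of `2 * order`.
#'
#' @param ts A [time_series].
#' @param band A [band_spec]; both edges must lie below Nyquist.
#' @param order Butterworth order of each pass (default 4).
#' @return The filtered [time_series]; `meta$band` is set.
#' @export
#' @examples
#' ts <- time_series(sin(2 * pi * 0.05 * 0:899) + rnorm(900), dt = 1)
#' filt <- bandpass(ts, band_spec(0.01, 0.1))
bandpass <- function(ts, band, order = 4) {
  ts <- as_time_series(ts)
  stopifnot(inherits(band, "band_spec"))
  check_band_nyquist(band, ts$dt)
  wn <- c(band$low, band$high) * 2 * ts$dt   # normalized to Nyquist
  flt <- signal::butter(order, wn, type = "pass")
  out <- ts
  out$values <- filtfilt_refl(flt$b, flt$a, ts$values)
  out$meta$band <- c(band$low, band$high)
  out$meta$filter_order <- order
  out
}

# Magnitude response of the zero-phase band-pass at frequency f (Hz).
bandpass_gain <- function(band, f, dt = 1, order = 4) {
  wn <- c(band$low, band$high) * 2 * dt
  flt <- signal::butter(order, wn, type = "pass")
  z <- exp(-1i * 2 * pi * f * dt)
  H <- sum(flt$b * z^(0:(length(flt$b) - 1))) /
    sum(flt$a * z^(0:(length(flt$a) - 1)))
  Mod(H)^2   # forward-backward pass squares the magnitude
}

# Windowed-sinc interpolation with anti-aliasing: evaluates the
# band-limited reconstruction of x (cut off at the smaller Nyquist) at
# arbitrary times. Edge samples use the truncated kernel, renormalised.
sinc_resample <- function(x, dt, t_new, target_dt) {
  fc <- 0.5 * min(1 / dt, 1 / target_dt)       # anti-aliasing cutoff, Hz
  half_width <- 16 * max(1, target_dt / dt)    # kernel half-width, samples
  n <- length(x)
  vapply(t_new, function(tt) {
    c0 <- tt / dt
    k <- max(1L, floor(c0 - half_width) + 1L):min(n, ceiling(c0 + half_width) + 1L)
    tau <- (k - 1) - c0                        # offsets in samples
    arg <- 2 * fc * dt * tau
    kern <- ifelse(abs(arg) < 1e-12, 1, sin(pi * arg) / (pi * arg))
    w <- 0.5 * (1 + cos(pi * tau / half_width))  # Hann taper
    kern <- kern * w
    # normalising by the kernel sum gives exact unity DC gain,
    # including at the (truncated) edges
    sum(x[k] * kern) / sum(kern)
  }, numeric(1))
}

#' Resample a time series to a new sampling interval
#'
#' Windowed-sinc (anti-aliased) resampling; linear interpolation is
#' available as an alternative. Duration is preserved to within one
#' sample.
#'
#' @param ts A [time_series].
#' @param target_dt Desired sampling interval (s).
#' @param method `"sinc"` (default) or `"linear"`.
#' @return The resampled [time_series].
#' @export
resample_to_dt <- function(ts, target_dt,
                           method = c("sinc", "linear")) {
  ts <- as_time_series(ts)
  method <- match.arg(method)
  if (target_dt <= 0) stop("target_dt must be > 0")
  if (isTRUE(all.equal(target_dt, ts$dt))) return(ts)
  out <- ts
  if (method == "sinc") {
    dur <- (length(ts$values) - 1) * ts$dt
    t_new <- seq(0, dur, by = target_dt)
    out$values <- sinc_resample(ts$values, ts$dt, t_new, target_dt)
  } else {
    t_old <- (seq_along(ts$values) - 1) * ts$dt
    t_new <- seq(0, t_old[length(t_old)], by = target_dt)
    out$values <- stats::approx(t_old, ts$values, xout = t_new)$y
  }
  out$dt <- target_dt
  out$meta$resampled_from_dt <- ts$dt
  out
}

#' Build a prediction input/target pair
#'
#' The forecaster's input is the frequency-normalised raw trace; its
#' target is the band-passed version of the same normalised trace
#' advanced by `shift` seconds, i.e. `target[t] = filtered[t + shift/dt]`.
#' Both are truncated to the common valid length.
#'
#' @param ts A [time_series].
#' @param band Target [band_spec].
#' @param shift Prediction horizon in seconds (default 10); must be an
#'   integer multiple of `dt` and less than the trace duration.
#' @param cutoff,cfg,order Passed to [frequency_normalize()] and
#'   [bandpass()].
#' @param normalize Apply [frequency_normalize()]? Disable for inputs
#'   that are already normalised, or for noiseless synthetic signals
#'   whose high-frequency power is (near) zero and would make the
#'   normalisation degenerate.
#' @return An object of class `target_pair` with elements `input`,
#'   `target` (equal-length [time_series]), `shift` and `band`.
#' @export
#' @examples
#' tr <- generate_vessel_trial(vessel_trial_spec(n_vessels = 1, seed = 3))
#' tp <- make_target_pair(tr$series[[1]], band_spec(0.01, 0.1))
make_target_pair <- function(ts, band, shift = 10, cutoff = 0.2,
                             cfg = spectral_config(), order = 4,
                             normalize = TRUE) {
  ts <- as_time_series(ts)
  k <- shift / ts$dt
  if (abs(k - round(k)) > 1e-9) {
    stop("shift must be an integer multiple of dt")
  }
  k <- as.integer(round(k))
  n <- length(ts$values)
  if (shift >= (n - 1) * ts$dt) stop("shift must be below the trace duration")
  norm <- if (normalize) {
    frequency_normalize(ts, cutoff = cutoff, cfg = cfg)
  } else {
    ts
  }
  filt <- bandpass(norm, band, order = order)
  input <- norm; target <- filt
  if (k > 0) {
    input$values <- norm$values[seq_len(n - k)]
    target$values <- filt$values[(k + 1L):n]
  }
  target$label <- paste0(ts$label, "_target")
  structure(list(input = input, target = target, shift = shift,
                 band = band, dt = ts$dt, label = ts$label),
            class = "target_pair")
}

#' @export
print.target_pair <- function(x, ...) {
  cat(sprintf("<target_pair> '%s': %d samples, %g s ahead, band %g-%g Hz\n",
              x$label, length(x$input$values), x$shift,
              x$band$low, x$band$high))
  invisible(x)
}

#' Full width at half maximum of a spectral peak
#'
#' Locates the PSD maximum above 0 Hz and returns the width between
#' the two half-maximum crossings bracketing it, using linear
#' interpolation between frequency bins.
#'
#' @param spec A `spectrum_estimate` from [welch_psd()].
#' @return FWHM in Hz.
#' @export
psd_fwhm <- function(spec) {
  sel <- spec$freqs > 0
  f <- spec$freqs[sel]; p <- spec$psd[sel]
  i0 <- which.max(p)
  half <- p[i0] / 2
  left <- NA_real_
  if (i0 > 1L) {
    for (j in (i0 - 1L):1L) {
      if (p[j] < half) {
        left <- f[j] + (half - p[j]) / (p[j + 1L] - p[j]) * (f[j + 1L] - f[j])
        break
      }
    }
  }
  right <- NA_real_
  if (i0 < length(p)) {
    for (j in (i0 + 1L):length(p)) {
      if (p[j] < half) {
        right <- f[j - 1L] +
          (p[j - 1L] - half) / (p[j - 1L] - p[j]) * (f[j] - f[j - 1L])
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right)) {
    stop("no half-maximum crossing bracketing the peak (monotone spectrum?)")
  }
  right - left
}
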