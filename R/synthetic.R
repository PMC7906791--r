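#' @title Synthetic data generators
#' @description Seeded generators emulating the statistical structure of
#'   slow vascular fMRI fluctuations: per-vessel trials sharing one
#'   band-limited slow component, multi-ROI sessions with separately
#'   tunable global and default-mode-network (DMN) coupling, narrow-band
#'   spectral probe signals, and dark-dot vessel images. Every generator
#'   is a pure function of its spec including the seed.
#' @name synthetic
NULL

# Evaluate expr under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %%
               2147483629)
}

#' Frequency band specification
#'
#' @param low,high Band edges in Hz; `0 < low < high`. Validity against
#'   the Nyquist frequency is checked where a sampling interval is known.
#' @return An object of class `band_spec`.
#' @export
#' @examples
#' band_spec(0.01, 0.1)   # human-like slow-oscillation band
#' band_spec(0.01, 0.05)  # rat-like band
band_spec <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low) {
    stop("band_spec requires 0 < low < high (Hz)")
  }
  structure(list(low = low, high = high), class = "band_spec")
}

check_band_nyquist <- function(band, dt) {
  nyq <- 1 / (2 * dt)
  if (band$high >= nyq) {
    stop(sprintf(
      "band high edge %g Hz is not below the Nyquist frequency %g Hz for dt=%g s",
      band$high, nyq, dt))
  }
  invisible(TRUE)
}

# Band-limited Gaussian process by frequency-domain shaping: the FFT of
# white Gaussian noise is multiplied by a band indicator (or an arbitrary
# nonnegative envelope over the positive frequencies) and inverted.
# Output is scaled to unit variance.
shaped_noise <- function(n, dt, envelope) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- dft_freqs(n, dt)            # signed frequencies per FFT bin
  g <- envelope(abs(f))
  g[1] <- 0                        # no DC
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("degenerate spectral envelope: output has zero variance")
  y / s
}

# Signed DFT bin frequencies for length n, sampling interval dt.
dft_freqs <- function(n, dt) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * dt)
}

bandlimited_process <- function(n, dt, band) {
  check_band_nyquist(band, dt)
  shaped_noise(n, dt, function(f) as.numeric(f >= band$low & f <= band$high))
}

# 1/f^alpha amplitude-shaped noise (unit variance).
colored_noise <- function(n, dt, alpha) {
  shaped_noise(n, dt, function(f) ifelse(f > 0, f^(-alpha / 2), 0))
}

#' Specification of a synthetic vessel trial
#'
#' Defaults emulate the 15-minute, 1-s-TR human regime: 900 samples,
#' a shared slow component inside the 0.01-0.1 Hz band mixed into each
#' vessel trace with weight drawn from `shared_weight_range`, plus 1/f
#' colored noise and white noise. With the default noise levels
#' (colored sd 0.7, white sd 0.7) the total noise variance is close to
#' the unit-variance shared component, i.e. SNR of about 1.
#'
#' The shared component is a band-limited Gaussian process whose
#' spectral envelope is *peaked* inside the band (Gaussian bump at
#' `peak_hz` of width `peak_width` on top of a flat in-band
#' `pedestal`), matching the peaked single-vessel power spectra of
#' real recordings rather than a flat band; set `peak_hz = NA` for a
#' flat band indicator.
#'
#' Real vessel signals also carry cross-frequency structure: the
#' amplitude of high-frequency activity rides on the slow oscillation
#' (phase-amplitude coupling). `pac_strength` reproduces this by
#' modulating the vessel-noise amplitude with the momentary value of
#' the shared component, `amp(t) = max(1 + pac * s(t), 0) /
#' sqrt(1 + pac^2)` (the divisor approximately preserves the noise
#' variance). This coupling is precisely what IAAFT surrogates
#' destroy; with `pac_strength = 0` the traces are linear-Gaussian and
#' real and surrogate traces are statistically equivalent.
#'
#' @param n_vessels Number of vessel traces.
#' @param n_timepoints Samples per trace (>= 500, i.e. at least twice
#'   the default 250-sample washout).
#' @param dt Sampling interval (s).
#' @param band [band_spec] bounding the shared slow component.
#' @param peak_hz,peak_width Centre (Hz) and standard deviation (Hz)
#'   of the spectral peak of the shared component; `peak_hz = NA`
#'   gives a flat band.
#' @param pedestal Relative amplitude of the flat in-band floor under
#'   the peak (0 = pure peak, 1 = flat band).
#' @param shared_weight_range Length-2 nonnegative interval from which
#'   per-vessel weights of the shared component are drawn uniformly.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha vessel
#'   noise; `NA` disables colored noise.
#' @param colored_noise_sd,white_noise_sd Noise standard deviations in
#'   units of the (unit-variance) shared component.
#' @param pac_strength Phase-amplitude coupling strength (0 disables).
#' @param seed Integer seed; identical specs give identical output.
#' @return An object of class `vessel_trial_spec`.
#' @export
vessel_trial_spec <- function(n_vessels = 30, n_timepoints = 900, dt = 1,
                              band = band_spec(0.01, 0.1),
                              peak_hz = 0.035, peak_width = 0.013,
                              pedestal = 0,
                              shared_weight_range = c(0.8, 1.2),
                              noise_exponent = 1,
                              colored_noise_sd = 0.7,
                              white_noise_sd = 0.7,
                              pac_strength = 4,
                              seed = 1) {
  stopifnot(n_vessels >= 1, dt > 0, pac_strength >= 0, pedestal >= 0)
  if (n_timepoints < 500) {
    stop("n_timepoints must be >= 500 (twice the default washout)")
  }
  if (length(shared_weight_range) != 2L || any(shared_weight_range < 0) ||
      diff(shared_weight_range) < 0) {
    stop("shared_weight_range must be a nondecreasing nonnegative interval")
  }
  if (!is.na(peak_hz) &&
      (peak_hz <= band$low || peak_hz >= band$high || peak_width <= 0)) {
    stop("peak_hz must lie inside the band with positive peak_width")
  }
  check_band_nyquist(band, dt)
  structure(list(n_vessels = n_vessels, n_timepoints = n_timepoints,
                 dt = dt, band = band, peak_hz = peak_hz,
                 peak_width = peak_width, pedestal = pedestal,
                 shared_weight_range = shared_weight_range,
                 noise_exponent = noise_exponent,
                 colored_noise_sd = colored_noise_sd,
                 white_noise_sd = white_noise_sd,
                 pac_strength = pac_strength, seed = seed),
            class = "vessel_trial_spec")
}

# Spectral amplitude envelope of the shared slow component.
shared_envelope <- function(spec) {
  band <- spec$band
  if (is.na(spec$peak_hz)) {
    function(f) as.numeric(f >= band$low & f <= band$high)
  } else {
    function(f) {
      inband <- f >= band$low & f <= band$high
      (exp(-(f - spec$peak_hz)^2 / (2 * spec$peak_width^2)) +
         spec$pedestal * inband) * inband
    }
  }
}

#' Generate a synthetic single-vessel trial
#'
#' Each vessel trace is `w_i * s(t) + colored noise + white noise`,
#' where `s(t)` is one band-limited Gaussian process shared across all
#' vessels of the trial and `w_i` is drawn from the spec's weight
#' range. `s(t)` is returned as ground truth.
#'
#' @param spec A [vessel_trial_spec].
#' @return A [trial_set] whose `ground_truth$shared` holds `s(t)`.
#' @export
#' @examples
#' tr <- generate_vessel_trial(vessel_trial_spec(n_vessels = 3, seed = 7))
#' tr
generate_vessel_trial <- function(spec) {
  stopifnot(inherits(spec, "vessel_trial_spec"))
  with_seed(spec$seed, {
    n <- spec$n_timepoints
    s <- shaped_noise(n, spec$dt, shared_envelope(spec))
    amp <- if (spec$pac_strength > 0) {
      pmax(1 + spec$pac_strength * s, 0) / sqrt(1 + spec$pac_strength^2)
    } else {
      rep(1, n)
    }
    w <- stats::runif(spec$n_vessels, spec$shared_weight_range[1],
                      spec$shared_weight_range[2])
    series <- lapply(seq_len(spec$n_vessels), function(i) {
      noise <- 0
      if (!is.na(spec$noise_exponent) && spec$colored_noise_sd > 0) {
        noise <- noise + spec$colored_noise_sd *
          colored_noise(n, spec$dt, spec$noise_exponent)
      }
      if (spec$white_noise_sd > 0) {
        noise <- noise + stats::rnorm(n, sd = spec$white_noise_sd)
      }
      x <- w[i] * s + amp * noise
      time_series(x, dt = spec$dt, label = sprintf("v%02d", i),
                  meta = list(shared_weight = w[i]))
    })
    trial_set(series,
              ground_truth = list(shared = s, weights = w),
              meta = list(spec = unclass(spec)[setdiff(names(spec), "band")],
                          band = c(spec$band$low, spec$band$high)))
  })
}

#' Specification of a synthetic multi-ROI session
#'
#' ROI traces are `global_coupling * g(t) + dmn_coupling * d(t)` (the
#' latter only inside the DMN subset) plus white noise, with `g`, `d`
#' independent band-limited unit-variance processes. Varying the two
#' couplings across sessions emulates the regime where global
#' fluctuation strength and DMN-internal coherence move in opposite
#' directions.
#'
#' @param n_rois Number of ROIs.
#' @param dmn_roi_indices Nonempty index set within `1:n_rois`.
#' @param global_coupling,dmn_coupling Nonnegative coupling weights.
#' @param noise_sd White-noise standard deviation per ROI.
#' @param n_timepoints,dt,band,peak_hz,peak_width,pedestal,seed As in
#'   [vessel_trial_spec()]; the peak parameters shape the spectra of
#'   both `g` and `d`.
#' @return An object of class `network_session_spec`.
#' @export
network_session_spec <- function(n_rois = 40, dmn_roi_indices = 1:8,
                                 global_coupling = 1, dmn_coupling = 1,
                                 noise_sd = 0.7, n_timepoints = 900,
                                 dt = 1, band = band_spec(0.01, 0.1),
                                 peak_hz = 0.035, peak_width = 0.013,
                                 pedestal = 0, seed = 1) {
  stopifnot(n_rois >= 2, dt > 0, n_timepoints >= 2)
  if (length(dmn_roi_indices) == 0L) stop("DMN ROI set must be nonempty")
  if (any(dmn_roi_indices < 1 | dmn_roi_indices > n_rois)) {
    stop("dmn_roi_indices out of range")
  }
  if (global_coupling < 0 || dmn_coupling < 0) {
    stop("couplings must be nonnegative")
  }
  check_band_nyquist(band, dt)
  if (!is.na(peak_hz) &&
      (peak_hz <= band$low || peak_hz >= band$high || peak_width <= 0)) {
    stop("peak_hz must lie inside the band with positive peak_width")
  }
  structure(list(n_rois = n_rois, dmn_roi_indices = sort(dmn_roi_indices),
                 global_coupling = global_coupling,
                 dmn_coupling = dmn_coupling, noise_sd = noise_sd,
                 n_timepoints = n_timepoints, dt = dt, band = band,
                 peak_hz = peak_hz, peak_width = peak_width,
                 pedestal = pedestal, seed = seed),
            class = "network_session_spec")
}

#' Generate a synthetic multi-ROI session
#'
#' @param spec A [network_session_spec].
#' @return A [session_data] object; `component_traces$global` and
#'   `component_traces$dmn` hold the ground-truth g(t) and d(t).
#' @export
generate_network_session <- function(spec) {
  stopifnot(inherits(spec, "network_session_spec"))
  with_seed(spec$seed, {
    n <- spec$n_timepoints
    env <- shared_envelope(spec)
    g <- shaped_noise(n, spec$dt, env)
    d <- shaped_noise(n, spec$dt, env)
    is_dmn <- seq_len(spec$n_rois) %in% spec$dmn_roi_indices
    traces <- vapply(seq_len(spec$n_rois), function(i) {
      x <- spec$global_coupling * g +
        (if (is_dmn[i]) spec$dmn_coupling * d else 0)
      if (spec$noise_sd > 0) x <- x + stats::rnorm(n, sd = spec$noise_sd)
      x
    }, numeric(n))
    labels <- sprintf("roi%03d", seq_len(spec$n_rois))
    colnames(traces) <- labels
    session_data(roi_traces = traces, roi_labels = labels,
                 dmn_mask = is_dmn, dt = spec$dt,
                 component_traces = list(global = g, dmn = d),
                 meta = list(global_coupling = spec$global_coupling,
                             dmn_coupling = spec$dmn_coupling,
                             seed = spec$seed))
  })
}

#' Generate a narrow-band spectral probe signal
#'
#' Gaussian noise shaped in the frequency domain by a Gaussian envelope
#' centred at `f0` with standard deviation `width`, normalised to unit
#' variance. Used to probe which peak frequency / spectral width a
#' trained forecaster prefers.
#'
#' @param f0 Peak frequency (Hz); `f0 + 3*width` must lie below Nyquist.
#' @param width Envelope standard deviation (Hz, > 0).
#' @param n_timepoints Number of samples.
#' @param dt Sampling interval (s).
#' @param seed Integer seed.
#' @return A [time_series] with unit variance.
#' @export
generate_probe_signal <- function(f0, width, n_timepoints = 900, dt = 1,
                                  seed = 1) {
  if (width <= 0) stop("width must be > 0")
  nyq <- 1 / (2 * dt)
  if (f0 + 3 * width >= nyq) {
    stop(sprintf("f0 + 3*width = %g Hz must be below Nyquist %g Hz",
                 f0 + 3 * width, nyq))
  }
  with_seed(seed, {
    y <- shaped_noise(n_timepoints, dt,
                      function(f) exp(-(f - f0)^2 / (2 * width^2)))
    time_series(y, dt = dt, label = sprintf("probe_f%.3f_w%.3f", f0, width),
                meta = list(f0 = f0, width = width, seed = seed))
  })
}

#' Generate a synthetic dark-dot vessel image
#'
#' Bright background with `n_dots` dark discs, mimicking venules in an
#' arteriole-venule map. Dot centres are placed by rejection sampling
#' with a minimum pairwise distance of `3 * dot_radius`.
#'
#' @param shape Length-2 integer vector, image size in pixels.
#' @param n_dots Number of discs (0 allowed).
#' @param dot_radius Disc radius in pixels.
#' @param contrast Darkening of disc pixels relative to the unit
#'   background (0 < contrast <= 1).
#' @param noise_sd Additive white-noise standard deviation.
#' @param seed Integer seed.
#' @return A list with `image` (numeric matrix), `mask` (logical matrix
#'   marking disc pixels) and `centers` (n_dots x 2 matrix).
#' @export
generate_vessel_image <- function(shape = c(128, 128), n_dots = 20,
                                  dot_radius = 3, contrast = 0.5,
                                  noise_sd = 0.02, seed = 1) {
  stopifnot(length(shape) == 2L, all(shape >= 1), n_dots >= 0,
            dot_radius >= 1, contrast > 0, contrast <= 1)
  margin <- dot_radius + 1
  lim <- shape - 2 * margin
  if (n_dots > 0 && (any(lim < 1) ||
      n_dots * (3 * dot_radius)^2 > 2 * prod(lim))) {
    stop("impossible packing: dots cannot fit inside the image")
  }
  with_seed(seed, {
    img <- matrix(1, shape[1], shape[2])
    mask <- matrix(FALSE, shape[1], shape[2])
    centers <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    while (nrow(centers) < n_dots) {
      if (attempts > 1000L * max(n_dots, 1L)) {
        stop("impossible packing: rejection sampling failed")
      }
      attempts <- attempts + 1L
      cand <- c(stats::runif(1, margin + 1, shape[1] - margin),
                stats::runif(1, margin + 1, shape[2] - margin))
      if (nrow(centers) > 0) {
        dmin <- min(sqrt((centers[, 1] - cand[1])^2 +
                         (centers[, 2] - cand[2])^2))
        if (dmin < 3 * dot_radius) next
      }
      centers <- rbind(centers, cand)
    }
    if (n_dots > 0) {
      rows <- row(img); cols <- col(img)
      for (i in seq_len(n_dots)) {
        disc <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
          dot_radius^2
        img[disc] <- img[disc] - contrast
        mask <- mask | disc
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(prod(shape), sd = noise_sd),
                          shape[1], shape[2])
    }
    rownames(centers) <- NULL
    list(image = img, mask = mask, centers = centers)
  })
}
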