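#' IAAFT surrogate of a time series
#'
#' Iterative amplitude adjusted Fourier transform. The surrogate keeps
#' the source's exact amplitude distribution (the output values are a
#' permutation of the input values) and a near-identical power
#' spectrum, while the Fourier phases are randomised - destroying the
#' dynamical (phase) structure that a forecaster could exploit.
#'
#' Starting from a seeded random permutation of the source, two steps
#' alternate until the relative spectral RMS error drops below `tol` or
#' the iteration budget is spent: (i) the spectrum-matching step
#' imposes the source's Fourier magnitudes while keeping the current
#' phases, and (ii) the amplitude-matching step rank-remaps the values
#' onto the source's sorted amplitudes. The amplitude step is applied
#' last, so distribution preservation is exact and the spectrum
#' approximate.
#'
#' The iteration reaches a fixed point (typically within ~100 steps)
#' whose residual spectral error depends on the starting permutation;
#' the budget of `max_iter` total iterations is therefore spread over
#' `n_restarts` seeded restarts and the best surrogate is returned.
#' Each restart stops early at its fixed point (two consecutive
#' identical errors).
#'
#' @param ts A [time_series] (length >= 16) or numeric vector with `dt`.
#' @param seed Integer seed for the initial permutations.
#' @param max_iter Total iteration budget across restarts.
#' @param tol Relative spectral RMS error below which iteration stops.
#' @param n_restarts Number of seeded restarts sharing the budget.
#' @param dt Sampling interval when `ts` is a bare vector.
#' @return An object of class `surrogate_result`: `surrogate`
#'   ([time_series]), `n_iterations` (total used), `spectral_error`
#'   (relative RMS mismatch of Fourier magnitudes) and `source_label`.
#' @export
#' @examples
#' tr <- generate_vessel_trial(vessel_trial_spec(n_vessels = 1, seed = 2))
#' sr <- iaaft(tr$series[[1]], seed = 9)
#' sr$spectral_error
iaaft <- function(ts, seed = 1, max_iter = 1000, tol = 1e-8,
                  n_restarts = 10, dt = NULL) {
  ts <- as_time_series(ts, dt)
  x <- ts$values
  n <- length(x)
  if (n < 16L) stop("iaaft needs at least 16 samples")
  if (stats::sd(x) == 0) stop("constant input: ranks undefined")
  sorted_amp <- sort(x)
  target_mag <- Mod(stats::fft(x))
  rel_err <- function(v) {
    m <- Mod(stats::fft(v))
    sqrt(mean((m - target_mag)^2)) / sqrt(mean(target_mag^2))
  }
  per_restart <- max(1L, as.integer(max_iter) %/% as.integer(n_restarts))
  best <- NULL
  total_it <- 0L
  for (r in seq_len(n_restarts)) {
    if (total_it >= max_iter) break
    cur <- with_seed(derive_seed(seed, r), sample(x, n))
    err <- rel_err(cur)
    prev_err <- Inf
    it <- 0L
    while (err > tol && it < per_restart && total_it < max_iter &&
           err != prev_err) {
      it <- it + 1L; total_it <- total_it + 1L
      prev_err <- err
      ph <- stats::fft(cur)
      mag <- Mod(ph)
      scale <- ifelse(mag > 0, target_mag / mag, 0)
      spec_matched <- Re(stats::fft(ph * scale, inverse = TRUE)) / n
      # rank remap: stable ties via ties.method = "first"
      cur <- sorted_amp[rank(spec_matched, ties.method = "first")]
      err <- rel_err(cur)
    }
    if (is.null(best) || err < best$err) best <- list(cur = cur, err = err)
    if (best$err <= tol) break
  }
  structure(list(surrogate = time_series(best$cur, ts$dt,
                                         label = paste0(ts$label, "_surr"),
                                         meta = list(surrogate = TRUE,
                                                     seed = seed)),
                 n_iterations = total_it, spectral_error = best$err,
                 source_label = ts$label),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> of '%s': %d iterations, spectral error %.3g\n",
              x$source_label, x$n_iterations, x$spectral_error))
  invisible(x)
}

#' Matched surrogate controls for a whole trial
#'
#' One IAAFT surrogate per vessel/ROI series, with per-series seeds
#' derived deterministically from `(seed, series index)`.
#'
#' @param trial A [trial_set].
#' @param seed Integer master seed.
#' @param ... Passed to [iaaft()] (`max_iter`, `tol`).
#' @return A [trial_set] of surrogates, labels mapping 1:1 onto the
#'   sources; per-series diagnostics in `meta$diagnostics`.
#' @export
surrogate_set <- function(trial, seed = 1, ...) {
  stopifnot(inherits(trial, "trial_set"))
  res <- vector("list", length(trial$series))
  diags <- vector("list", length(trial$series))
  for (i in seq_along(trial$series)) {
    r <- tryCatch(iaaft(trial$series[[i]], seed = derive_seed(seed, i), ...),
                  error = function(e) {
                    stop(sprintf("iaaft failed for series %d ('%s'): %s",
                                 i, trial$series[[i]]$label,
                                 conditionMessage(e)), call. = FALSE)
                  })
    res[[i]] <- r$surrogate
    diags[[i]] <- list(label = r$source_label,
                       n_iterations = r$n_iterations,
                       spectral_error = r$spectral_error)
  }
  trial_set(res, meta = list(surrogate_of = vapply(
    trial$series, function(s) s$label, character(1)),
    seed = seed, diagnostics = diags))
}
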