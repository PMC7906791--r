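#' Pearson correlation coefficient
#'
#' The package's prediction score: the product-moment correlation
#' between predicted and target signals.
#'
#' @param a,b Equal-length numeric vectors (>= 3 samples, nonzero
#'   variance).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3L) stop("need at least 3 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  stats::cor(a, b)
}

#' Cross-correlation lag between prediction and target
#'
#' Both series are z-scored and the lag of the maximum (unnormalised)
#' cross-correlation is returned in seconds. Sign convention: a
#' positive lag means the prediction is delayed with respect to the
#' target; negative means it runs too early. Ties are broken towards
#' the smallest absolute lag.
#'
#' @param pred,target Equal-length numeric vectors.
#' @param dt Sampling interval (s).
#' @param max_lag Maximum lag magnitude in samples (default: full
#'   overlap).
#' @return Lag in seconds.
#' @export
#' @examples
#' x <- sin(2 * pi * 0.05 * 0:199)
#' xcorr_lag(c(rep(0, 5), x[1:195]), x, dt = 1)  # delayed by 5 -> +5 s
xcorr_lag <- function(pred, target, dt = 1, max_lag = NULL) {
  n <- length(pred)
  if (n != length(target)) stop("length mismatch")
  if (stats::sd(pred) == 0 || stats::sd(target) == 0) {
    stop("flat input: z-scoring undefined")
  }
  p <- as.numeric(scale(pred)); tg <- as.numeric(scale(target))
  if (is.null(max_lag)) max_lag <- n - 1L
  max_lag <- min(max_lag, n - 1L)
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(l) {
    # c(l) = sum_t p[t] * tg[t - l]
    if (l >= 0) sum(p[(1 + l):n] * tg[1:(n - l)])
    else sum(p[1:(n + l)] * tg[(1 - l):n])
  }, numeric(1))
  best <- lags[order(-cc, abs(lags))[1]]
  best * dt
}

#' Sliding-window prediction score signal
#'
#' Pearson correlation between prediction and target inside a centred
#' window of `window` seconds around each timepoint (31 samples for a
#' 30-s window at 1-s sampling: 15 left, the centre, 15 right). The
#' first and last half-window values use truncated windows; a window
#' truncated below 3 samples yields `NA`.
#'
#' @param pred,target Equal-length numeric vectors.
#' @param dt Sampling interval (s).
#' @param window Window length in seconds (default 30).
#' @return A [time_series] of per-timepoint scores, same length as the
#'   input.
#' @export
sliding_window_cc <- function(pred, target, dt = 1, window = 30) {
  n <- length(pred)
  if (n != length(target)) stop("length mismatch")
  half <- floor(round(window / dt) / 2)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j1 <- max(1L, i - half); j2 <- min(n, i + half)
    if (j2 - j1 + 1L >= 3L) {
      p <- pred[j1:j2]; tg <- target[j1:j2]
      if (stats::sd(p) > 0 && stats::sd(tg) > 0) {
        out[i] <- stats::cor(p, tg)
      }
    }
  }
  time_series(out, dt = dt, label = "window_cc",
              meta = list(window_s = window))
}

#' Paired test on Fisher-z-transformed correlations
#'
#' Applies the Fisher z-transform (atanh) to both vectors of
#' correlations and runs a paired t-test on the differences. Used to
#' compare real-trace prediction scores against their matched
#' surrogate controls.
#'
#' @param real_ccs,surrogate_ccs Equal-length vectors of correlations
#'   strictly inside (-1, 1).
#' @return List with `statistic` (t), `p`, `df` and `mean_diff_z`.
#' @export
paired_fisher_test <- function(real_ccs, surrogate_ccs) {
  if (length(real_ccs) != length(surrogate_ccs)) stop("length mismatch")
  if (length(real_ccs) < 3L) stop("need at least 3 pairs")
  if (any(abs(c(real_ccs, surrogate_ccs)) >= 1)) {
    stop("|cc| = 1 present: Fisher z is infinite")
  }
  zr <- atanh(real_ccs); zs <- atanh(surrogate_ccs)
  d <- zr - zs
  if (stats::sd(d) == 0) {
    # identical vectors (or constant shift of exactly zero spread):
    # no evidence either way
    if (all(d == 0)) {
      return(list(statistic = 0, p = 1, df = length(d) - 1,
                  mean_diff_z = 0))
    }
  }
  ht <- stats::t.test(zr, zs, paired = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff_z = mean(zr - zs))
}

#' Per-node two-sample test on Fisher-z-transformed correlation maps
#'
#' For every node/ROI column, both groups of correlation values are
#' atanh-transformed and compared with a standard (equal-variance)
#' two-sample t-test; `welch = TRUE` switches to the Welch form.
#' Degenerate nodes (no variance in either group) get `p = 1` and are
#' flagged.
#'
#' @param group_a_maps,group_b_maps Matrices with one row per map
#'   (session) and one column per node; >= 2 rows each.
#' @param welch Use the Welch (unequal-variance) t-test?
#' @return List with vectors `t`, `p` and logical `flagged`.
#' @export
two_sample_fisher_test <- function(group_a_maps, group_b_maps,
                                   welch = FALSE) {
  a <- as.matrix(group_a_maps); b <- as.matrix(group_b_maps)
  if (ncol(a) != ncol(b)) stop("groups must have the same nodes")
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 maps per group")
  nn <- ncol(a)
  tv <- numeric(nn); pv <- numeric(nn); flag <- logical(nn)
  for (j in seq_len(nn)) {
    za <- atanh(pmin(pmax(a[, j], -1 + 1e-12), 1 - 1e-12))
    zb <- atanh(pmin(pmax(b[, j], -1 + 1e-12), 1 - 1e-12))
    if (stats::sd(za) == 0 && stats::sd(zb) == 0) {
      tv[j] <- 0; pv[j] <- 1; flag[j] <- TRUE
    } else {
      ht <- stats::t.test(za, zb, var.equal = !welch)
      tv[j] <- unname(ht$statistic); pv[j] <- ht$p.value
    }
  }
  if (any(flag)) warning(sprintf("%d degenerate node(s) set to p = 1",
                                 sum(flag)))
  list(t = tv, p = pv, flagged = flag)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment of p-values with a rejection mask at level `q`.
#'
#' @param pvals Vector of p-values in `[0, 1]` (may be empty).
#' @param q FDR level.
#' @return List with `adjusted` p-values and logical `reject` mask.
#' @export
fdr_adjust <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) {
    return(list(adjusted = numeric(0), reject = logical(0)))
  }
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}
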