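#' Multi-ROI session container
#'
#' Holds the ROI traces of one resting-state session, the DMN subset,
#' optional voxel traces and optional named component traces (e.g. a
#' DMN-ICA-like time course supplied by the user or, for synthetic
#' sessions, the generator's ground truth).
#'
#' @param roi_traces Time x ROI numeric matrix.
#' @param roi_labels Character vector, one per ROI column.
#' @param dmn_mask Logical vector marking the DMN ROIs.
#' @param dt Sampling interval (s).
#' @param voxel_traces Optional time x voxel matrix.
#' @param component_traces Optional named list of component time
#'   courses aligned with the ROI traces.
#' @param meta Named list of provenance info.
#' @return An object of class `session_data`.
#' @export
session_data <- function(roi_traces, roi_labels = colnames(roi_traces),
                         dmn_mask = NULL, dt = 1, voxel_traces = NULL,
                         component_traces = NULL, meta = list()) {
  roi_traces <- as.matrix(roi_traces)
  if (is.null(roi_labels)) {
    roi_labels <- sprintf("roi%03d", seq_len(ncol(roi_traces)))
  }
  stopifnot(length(roi_labels) == ncol(roi_traces))
  if (is.null(dmn_mask)) dmn_mask <- rep(FALSE, ncol(roi_traces))
  stopifnot(length(dmn_mask) == ncol(roi_traces))
  if (!is.null(voxel_traces) &&
      nrow(as.matrix(voxel_traces)) != nrow(roi_traces)) {
    stop("voxel_traces must share the time dimension")
  }
  if (!is.null(component_traces)) {
    lens <- vapply(component_traces, length, integer(1))
    if (any(lens != nrow(roi_traces))) {
      stop("component traces must share the time dimension")
    }
  }
  colnames(roi_traces) <- roi_labels
  structure(list(roi_traces = roi_traces, roi_labels = roi_labels,
                 dmn_mask = dmn_mask, dt = dt,
                 voxel_traces = voxel_traces,
                 component_traces = component_traces, meta = meta),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> %d ROIs (%d DMN) x %d timepoints @ dt=%g s\n",
              ncol(x$roi_traces), sum(x$dmn_mask), nrow(x$roi_traces),
              x$dt))
  invisible(x)
}

# Unweighted mean trace over all ROIs (the session's "global signal").
global_signal <- function(session) rowMeans(session$roi_traces)

#' Score sessions with a trained forecaster
#'
#' For each session the requested ROI trace (or the global mean trace)
#' is extracted, preprocessed with the model's own recipe
#' (frequency-normalised, band-passed, 10-s-shifted target) and
#' predicted; the per-session CC and lag are tabulated. A missing ROI
#' fails that session only.
#'
#' @param model A `gru_model`.
#' @param sessions List of [session_data] (sampling interval must match
#'   the model's; resample first otherwise).
#' @param roi ROI label, or `"global"` for the mean-across-ROIs trace.
#' @return A `data.frame` with one row per session: `session`, `roi`,
#'   `cc`, `lag_s`, `global_variance`, `intrinsic_dmn_corr` (NA when
#'   the session carries no DMN component trace), `error`.
#' @export
score_sessions <- function(model, sessions, roi = "global") {
  rows <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    res <- tryCatch({
      if (!isTRUE(all.equal(s$dt, model$recipe$dt))) {
        stop(sprintf("session dt=%g differs from model dt=%g",
                     s$dt, model$recipe$dt))
      }
      tr <- if (identical(roi, "global")) {
        global_signal(s)
      } else {
        if (!roi %in% s$roi_labels) stop(sprintf("ROI '%s' missing", roi))
        s$roi_traces[, roi]
      }
      rec <- predict_gru(model, time_series(tr, s$dt, label = roi))
      idc <- if (!is.null(s$component_traces$dmn) && any(s$dmn_mask)) {
        intrinsic_dmn_correlation(s$component_traces$dmn,
                                  s$roi_traces[, s$dmn_mask, drop = FALSE])
      } else NA_real_
      data.frame(session = i, roi = roi, cc = rec$cc, lag_s = rec$lag,
                 global_variance = stats::var(global_signal(s)),
                 intrinsic_dmn_corr = idc, error = NA_character_)
    }, error = function(e) {
      data.frame(session = i, roi = roi, cc = NA_real_, lag_s = NA_real_,
                 global_variance = NA_real_, intrinsic_dmn_corr = NA_real_,
                 error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  do.call(rbind, rows)
}

#' Top and bottom percentile groups
#'
#' Indices of the `ceiling(pct * n)` largest and smallest scores. Ties
#' are broken by stable original order: the bottom group takes the
#' earliest tied indices, the top group the latest.
#'
#' @param scores Numeric vector.
#' @param pct Fraction in (0, 0.5).
#' @return List with integer vectors `top` and `bottom`.
#' @export
percentile_groups <- function(scores, pct = 0.05) {
  n <- length(scores)
  if (pct <= 0 || pct >= 0.5) stop("pct must lie in (0, 0.5)")
  k <- ceiling(pct * n)
  if (k < 1 || n * pct < 1) {
    stop("too few scores for the requested percentile")
  }
  ord_asc <- order(scores, seq_len(n))
  list(top = sort(ord_asc[(n - k + 1L):n]),
       bottom = sort(ord_asc[seq_len(k)]))
}

#' Seed-based correlation map
#'
#' Pearson correlation of a seed trace with every column of a trace
#' matrix. Zero-variance columns yield `NA` with a warning.
#'
#' @param seed_trace Numeric vector (or [time_series]).
#' @param traces_matrix Time x node matrix, aligned with the seed.
#' @return Numeric vector, one correlation per column.
#' @export
seed_correlation_map <- function(seed_trace, traces_matrix) {
  s <- value_of(seed_trace)
  m <- as.matrix(traces_matrix)
  if (length(s) != nrow(m)) stop("seed and traces must be aligned")
  sds <- apply(m, 2, stats::sd)
  out <- rep(NA_real_, ncol(m))
  ok <- sds > 0
  if (any(!ok)) warning(sprintf("%d zero-variance column(s) set to NA",
                                sum(!ok)))
  out[ok] <- as.numeric(stats::cor(s, m[, ok, drop = FALSE]))
  out
}

#' Group difference of seed-correlation maps
#'
#' Mean(top) - mean(bottom) per node, with a per-node significance
#' mask from [two_sample_fisher_test()] followed by
#' Benjamini-Hochberg FDR control. Antisymmetric under group swap.
#'
#' @param maps_top,maps_bottom Lists of correlation vectors (or
#'   matrices with one row per map); >= 2 maps per group.
#' @param q FDR level for the mask.
#' @return List with `difference` (numeric vector), `p`, `adjusted_p`
#'   and logical `significant`.
#' @export
difference_map <- function(maps_top, maps_bottom, q = 0.05) {
  as_mat <- function(m) if (is.list(m)) do.call(rbind, m) else as.matrix(m)
  a <- as_mat(maps_top); b <- as_mat(maps_bottom)
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 maps per group")
  tst <- two_sample_fisher_test(a, b)
  adj <- fdr_adjust(tst$p, q)
  list(difference = colMeans(a) - colMeans(b), p = tst$p,
       adjusted_p = adj$adjusted, significant = adj$reject)
}

#' Intrinsic DMN correlation index
#'
#' Mean over DMN voxels/ROIs of the Pearson correlation between each
#' voxel trace and the DMN component time course (the mean of the
#' correlations, not the correlation with the mean).
#'
#' @param dmn_component_trace Numeric vector (or [time_series]).
#' @param dmn_voxel_traces Time x voxel matrix (>= 1 column).
#' @return Scalar correlation index.
#' @export
intrinsic_dmn_correlation <- function(dmn_component_trace,
                                      dmn_voxel_traces) {
  comp <- value_of(dmn_component_trace)
  m <- as.matrix(dmn_voxel_traces)
  if (ncol(m) == 0L) stop("empty DMN voxel set")
  if (length(comp) != nrow(m)) stop("traces must be aligned")
  mean(as.numeric(stats::cor(comp, m)))
}

#' Score-binned relationship curve
#'
#' Sessions are sorted by score and partitioned into consecutive bins
#' of `floor(n * bin_pct)` sessions (remainder joining the last bin);
#' per-bin mean score and mean value form the curve.
#'
#' @param scores,values Equal-length numeric vectors.
#' @param bin_pct Bin width as a fraction of n (default 0.02, i.e. 2%
#'   bins).
#' @return A `data.frame` with `bin`, `mean_score`, `mean_value`, `n`.
#' @export
binned_relationship <- function(scores, values, bin_pct = 0.02) {
  n <- length(scores)
  if (length(values) != n) stop("length mismatch")
  per <- floor(n * bin_pct)
  if (per < 1) stop("too few observations for the requested bin width")
  n_bins <- n %/% per
  ord <- order(scores, seq_len(n))
  bin_id <- pmin(ceiling(seq_len(n) / per), n_bins)
  data.frame(
    bin = seq_len(n_bins),
    mean_score = as.numeric(tapply(scores[ord], bin_id, mean)),
    mean_value = as.numeric(tapply(values[ord], bin_id, mean)),
    n = as.integer(table(bin_id)))
}

#' Variance-based session grouping
#'
#' Per-session variance of the global (mean across ROIs) trace,
#' percentile grouping on those variances, and - when prediction
#' scores are supplied - the overlap between variance-based and
#' score-based groups plus the score spread within each variance
#' group.
#'
#' @param sessions List of [session_data], or a numeric vector of
#'   per-session global variances.
#' @param pct Percentile fraction, as in [percentile_groups()].
#' @param scores Optional per-session prediction scores to compare
#'   against.
#' @return List with `variance`, `groups` (top/bottom indices) and,
#'   when scores are given, `overlap` counts and `score_range` per
#'   group.
#' @export
variance_groups <- function(sessions, pct = 0.05, scores = NULL) {
  v <- if (is.numeric(sessions)) {
    sessions
  } else {
    vapply(sessions, function(s) stats::var(global_signal(s)), numeric(1))
  }
  if (any(v == 0)) {
    warning(sprintf("%d zero-variance session(s) excluded from log curves",
                    sum(v == 0)))
  }
  grp <- percentile_groups(v, pct)
  out <- list(variance = v, log_variance = ifelse(v > 0, log(v), NA),
              groups = grp)
  if (!is.null(scores)) {
    sg <- percentile_groups(scores, pct)
    out$overlap <- list(
      top = length(intersect(grp$top, sg$top)),
      bottom = length(intersect(grp$bottom, sg$bottom)))
    out$score_range <- list(
      top = range(scores[grp$top]), bottom = range(scores[grp$bottom]))
    out$variance_range_of_score_groups <- list(
      top = range(v[sg$top]), bottom = range(v[sg$bottom]))
  }
  out
}

#' Laplacian spectral reordering of a correlation matrix
#'
#' Builds a nonnegative affinity `A = (corr + 1) / 2` (zero diagonal),
#' forms the graph Laplacian `L = D - A` and orders rows by the Fiedler
#' vector (eigenvector of the second-smallest eigenvalue), so ROIs with
#' similar correlation patterns become adjacent. The Fiedler vector's
#' sign is fixed by requiring its first element to be nonnegative;
#' ties in the ordering are broken by original index. A disconnected
#' affinity graph is reordered per connected component, with a warning.
#'
#' @param corr_matrix Square symmetric correlation matrix.
#' @return Integer permutation of the row indices.
#' @export
spectral_reorder <- function(corr_matrix) {
  C <- as.matrix(corr_matrix)
  n <- nrow(C)
  if (n != ncol(C) || max(abs(C - t(C))) > 1e-8) {
    stop("corr_matrix must be square and symmetric")
  }
  A <- (C + 1) / 2
  diag(A) <- 0
  comp <- connected_components(A > 0)
  if (max(comp) > 1L) {
    warning("disconnected affinity graph: ordering per component")
  }
  perm <- integer(0)
  for (ci in seq_len(max(comp))) {
    idx <- which(comp == ci)
    if (length(idx) <= 2L) { perm <- c(perm, idx); next }
    Ai <- A[idx, idx]
    L <- diag(rowSums(Ai)) - Ai
    eg <- eigen(L, symmetric = TRUE)
    f <- eg$vectors[, ncol(eg$vectors) - 1L]   # second-smallest eigenvalue
    if (f[1] < 0) f <- -f
    perm <- c(perm, idx[order(f, seq_along(f))])
  }
  perm
}

# Connected components of a logical adjacency matrix (BFS).
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Spectral preference map of a trained forecaster
#'
#' Predicts seeded narrow-band probe signals over a grid of peak
#' frequencies and spectral widths and averages the prediction CC per
#' cell, revealing which oscillatory regime the model is tuned to.
#'
#' @param model A `gru_model`.
#' @param f0_grid,width_grid Numeric grids (Hz); every `f0 + 3*width`
#'   must lie below Nyquist at the model's sampling interval.
#' @param n_seeds Probe realisations averaged per cell.
#' @param n_timepoints Probe length in samples.
#' @param seed Master seed.
#' @return Matrix of mean CCs, `length(f0_grid)` x
#'   `length(width_grid)`, with dimnames giving the grids.
#' @export
probe_preference_map <- function(model, f0_grid, width_grid,
                                 n_seeds = 3, n_timepoints = 900,
                                 seed = 1) {
  if (length(f0_grid) == 0L || length(width_grid) == 0L) {
    stop("empty probe grid")
  }
  dt <- model$recipe$dt
  out <- matrix(NA_real_, length(f0_grid), length(width_grid),
                dimnames = list(sprintf("%g", f0_grid),
                                sprintf("%g", width_grid)))
  band <- model$recipe$band
  for (i in seq_along(f0_grid)) {
    for (j in seq_along(width_grid)) {
      ccs <- vapply(seq_len(n_seeds), function(s) {
        probe <- generate_probe_signal(f0_grid[i], width_grid[j],
                                       n_timepoints = n_timepoints,
                                       dt = dt,
                                       seed = derive_seed(seed, i * 1000 +
                                                            j * 100 + s))
        # probes are generated at unit variance and carry no
        # high-frequency noise floor, so the usual high-frequency
        # renormalisation is degenerate for them and is skipped
        spp <- welch_psd(probe)
        sel <- spp$freqs >= band$low & spp$freqs <= band$high
        if (sum(spp$psd[sel]) / sum(spp$psd) < 1e-4) {
          # essentially no band content: nothing to predict, and the
          # band-passed "target" would be pure filter edge ringing
          return(0)
        }
        pair <- make_target_pair(probe, band = band,
                                 shift = model$recipe$shift,
                                 normalize = FALSE)
        predict_gru(model, pair)$cc
      }, numeric(1))
      out[i, j] <- mean(ccs)
    }
  }
  out
}
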