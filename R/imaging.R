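#' @title Vessel localisation on 2-D anatomical images
#' @description Venules appear as dark dots on anatomical
#'   (arteriole-venule map or mean-EPI) images. Localisation is a
#'   local-statistics pipeline: a local minimum filter emphasises dark
#'   structures, a normalised rectangular averaging filter smooths the
#'   result, and thresholding at a dark quantile yields a binary vessel
#'   mask. Mask components then drive time-course extraction from the
#'   functional data.
#' @name imaging
NULL

# Local minimum filter over a (2k+1) x (2k+1) neighbourhood, edge
# pixels using the truncated neighbourhood.
local_min_filter <- function(img, size = 3) {
  k <- (size - 1L) %/% 2L
  out <- img
  for (di in -k:k) {
    for (dj in -k:k) {
      if (di == 0 && dj == 0) next
      sh <- shift_matrix(img, di, dj)
      out <- pmin(out, sh, na.rm = TRUE)
    }
  }
  out
}

# Shift a matrix by (di, dj), padding with NA.
shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) - di; ci <- seq_len(nc) - dj
  ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}

# size x size moving-average filter (normalised by the count of pixels
# actually inside the image), via cumulative sums.
box_mean_filter <- function(img, size = 10) {
  nr <- nrow(img); nc <- ncol(img)
  lo <- -((size - 1L) %/% 2L); hi <- size %/% 2L
  # integral image
  S <- matrix(0, nr + 1L, nc + 1L)
  cs <- apply(img, 2, cumsum)
  S[-1, -1] <- t(apply(cs, 1, cumsum))
  i1 <- as.vector(pmax(row(img) + lo, 1L))
  i2 <- as.vector(pmin(row(img) + hi, nr))
  j1 <- as.vector(pmax(col(img) + lo, 1L))
  j2 <- as.vector(pmin(col(img) + hi, nc))
  tot <- S[cbind(i2 + 1L, j2 + 1L)] - S[cbind(i1, j2 + 1L)] -
    S[cbind(i2 + 1L, j1)] + S[cbind(i1, j1)]
  cnt <- (i2 - i1 + 1L) * (j2 - j1 + 1L)
  matrix(tot / cnt, nr, nc)
}

#' Localise dark vessel dots on a 2-D image
#'
#' Pipeline: local minimum filter over a `neighborhood` x
#' `neighborhood` window (default 3, i.e. the centre plus or minus one
#' pixel), then a `rank_size` x `rank_size` rectangular averaging
#' filter normalised by the filter size, then thresholding at the
#' darkest `threshold` quantile of the filtered image.
#'
#' @param image 2-D numeric matrix (finite values).
#' @param neighborhood Minimum-filter window size in pixels.
#' @param rank_size Averaging-filter window size in pixels.
#' @param threshold Dark quantile defining the mask (default 0.02).
#' @return An object of class `vessel_mask`: logical matrix `mask`
#'   (same shape as the image) plus the parameters used.
#' @export
#' @examples
#' synth <- generate_vessel_image(n_dots = 10, seed = 4)
#' vm <- localize_vessels(synth$image)
#' sum(vm$mask & synth$mask) > 0
localize_vessels <- function(image, neighborhood = 3, rank_size = 10,
                             threshold = 0.02) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image must be finite")
  if (stats::sd(image) == 0) {
    warning("constant image: returning an empty mask")
    return(structure(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                          parameters = list(neighborhood = neighborhood,
                                            rank_size = rank_size,
                                            threshold = threshold)),
                     class = "vessel_mask"))
  }
  mn <- local_min_filter(image, neighborhood)
  sm <- box_mean_filter(mn, rank_size)
  cut <- stats::quantile(sm, threshold)
  structure(list(mask = sm <= cut,
                 parameters = list(neighborhood = neighborhood,
                                   rank_size = rank_size,
                                   threshold = threshold)),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d, %d pixels in %d component(s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              max(label_mask(x$mask))))
  invisible(x)
}

#' Combine a vessel mask with a thresholded component map
#'
#' Logical AND of the vessel mask with `|component map| >=
#' z_threshold`, restricting vessels to those inside a slow-oscillation
#' spatial component.
#'
#' @param vessel_mask A `vessel_mask` or logical matrix.
#' @param component_map Numeric matrix (e.g. an ICA spatial map in z
#'   units), same shape.
#' @param z_threshold Absolute threshold applied to the map.
#' @return A `vessel_mask` (always a subset of the input mask).
#' @export
combine_masks <- function(vessel_mask, component_map, z_threshold) {
  m <- if (inherits(vessel_mask, "vessel_mask")) vessel_mask$mask
       else vessel_mask
  cm <- as.matrix(component_map)
  if (!all(dim(m) == dim(cm))) stop("shape mismatch")
  structure(list(mask = m & (abs(cm) >= z_threshold),
                 parameters = list(z_threshold = z_threshold)),
            class = "vessel_mask")
}

# 8-connectivity labelling of a logical mask.
label_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      i <- ((v - 1L) %% nr) + 1L
      j <- ((v - 1L) %/% nr) + 1L
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs$di[o]; jj <- j + offs$dj[o]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          w <- (jj - 1L) * nr + ii
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

#' Extract per-vessel time courses from masked functional data
#'
#' One [time_series] per connected mask component: the mean over that
#' component's pixels at each timepoint, labelled by the component
#' centroid.
#'
#' @param data 3-D array (x, y, time) of functional data.
#' @param mask A `vessel_mask` or logical matrix matching the spatial
#'   dimensions.
#' @param dt Sampling interval (s).
#' @return A [trial_set] (empty mask gives a warning and `NULL`).
#' @export
extract_timecourses <- function(data, mask, dt = 1) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  d <- dim(data)
  if (length(d) != 3L || !all(d[1:2] == dim(m))) {
    stop("data must be (x, y, time) with spatial dims matching the mask")
  }
  lab <- label_mask(m)
  ncomp <- max(lab)
  if (ncomp == 0L) {
    warning("empty mask: no time courses extracted")
    return(NULL)
  }
  flat <- matrix(data, d[1] * d[2], d[3])
  series <- lapply(seq_len(ncomp), function(k) {
    px <- which(lab == k)
    vals <- if (length(px) == 1L) flat[px, ] else colMeans(flat[px, ])
    ci <- mean(((px - 1L) %% d[1]) + 1L)
    cj <- mean(((px - 1L) %/% d[1]) + 1L)
    time_series(vals, dt = dt,
                label = sprintf("vessel_%.0f_%.0f", ci, cj),
                meta = list(n_pixels = length(px),
                            centroid = c(ci, cj)))
  })
  trial_set(series, meta = list(n_components = ncomp))
}
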