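#' Sampled time series
#'
#' The basic signal container used throughout the package: a numeric
#' vector of regularly sampled values together with its sampling
#' interval in seconds. All frequencies in the package are in Hz, all
#' times in seconds.
#'
#' @param values Numeric vector of finite samples (length >= 2).
#' @param dt Sampling interval in seconds (> 0).
#' @param label Optional text label (e.g. vessel or ROI name).
#' @param meta Named list of provenance flags (e.g. `normalized`,
#'   `band`). Free-form; the preprocessing functions update it.
#' @return An object of class `time_series`.
#' @export
#' @examples
#' ts <- time_series(sin(2 * pi * 0.05 * 0:899), dt = 1, label = "v1")
#' ts
time_series <- function(values, dt, label = "", meta = list()) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("time_series needs at least 2 samples")
  if (any(is.nan(values) | is.infinite(values))) {
    stop("time_series values must be finite (NA allowed for missing)")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a single positive number (seconds)")
  }
  structure(list(values = values, dt = dt, label = as.character(label),
                 meta = meta),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> '%s': %d samples @ dt=%g s (%.1f s)\n",
              x$label, length(x$values), x$dt,
              (length(x$values) - 1) * x$dt))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time = (seq_along(x$values) - 1) * x$dt, value = x$values)
}

#' Test for time_series objects
#' @param x Object to test.
#' @return Logical scalar.
#' @export
is_time_series <- function(x) inherits(x, "time_series")

# Accept either a time_series or a bare numeric vector plus dt.
as_time_series <- function(x, dt = NULL, label = "") {
  if (is_time_series(x)) return(x)
  if (is.null(dt)) stop("a bare numeric vector needs an explicit dt")
  time_series(x, dt = dt, label = label)
}

#' Collection of vessel/ROI time series forming one trial or session
#'
#' @param series List of [time_series] objects sharing the same `dt`
#'   and length.
#' @param ground_truth Optional named list of ground-truth components
#'   (e.g. the shared slow component of a synthetic trial), each a
#'   numeric vector or `time_series`.
#' @param meta Named list of provenance information.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(series, ground_truth = NULL, meta = list()) {
  if (length(series) == 0L) stop("trial_set needs at least one series")
  stopifnot(all(vapply(series, is_time_series, logical(1))))
  dts <- vapply(series, function(s) s$dt, numeric(1))
  ns <- vapply(series, length, integer(1))
  if (length(unique(dts)) != 1L || length(unique(ns)) != 1L) {
    stop("all series in a trial_set must share dt and length")
  }
  labs <- vapply(series, function(s) s$label, character(1))
  if (any(labs == "")) {
    labs[labs == ""] <- sprintf("v%02d", which(labs == ""))
    series <- Map(function(s, l) { s$label <- l; s }, series, labs)
  }
  names(series) <- labs
  structure(list(series = series, ground_truth = ground_truth,
                 meta = meta),
            class = "trial_set")
}

#' @export
length.trial_set <- function(x) length(x$series)

#' @export
print.trial_set <- function(x, ...) {
  s1 <- x$series[[1]]
  cat(sprintf("<trial_set> %d series, %d samples @ dt=%g s%s\n",
              length(x$series), length(s1$values), s1$dt,
              if (!is.null(x$ground_truth)) " (+ ground truth)" else ""))
  invisible(x)
}

#' Write a trial set as delimited text
#'
#' One column per series with a header row of labels; the first column
#' is time in seconds. Ground-truth components, when present, go to a
#' sidecar JSON file `<path>.json`.
#'
#' @param trial A [trial_set].
#' @param path Output file path (tab-separated text).
#' @param sidecar Write the ground-truth/meta sidecar JSON?
#' @return `path`, invisibly.
#' @export
write_trial_set <- function(trial, path, sidecar = TRUE) {
  stopifnot(inherits(trial, "trial_set"))
  s1 <- trial$series[[1]]
  m <- do.call(cbind, lapply(trial$series, function(s) s$values))
  df <- data.frame(time = (seq_len(nrow(m)) - 1) * s1$dt, m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (sidecar && (!is.null(trial$ground_truth) || length(trial$meta))) {
    gt <- lapply(trial$ground_truth, function(g)
      if (is_time_series(g)) g$values else as.numeric(g))
    jsonlite::write_json(list(ground_truth = gt, meta = trial$meta),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a trial set written by [write_trial_set()]
#'
#' @param path File path. The sampling interval is inferred from the
#'   time column.
#' @return A [trial_set]. Ground truth is restored from the sidecar
#'   JSON when present.
#' @export
read_trial_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("expected a time column plus >=1 series")
  dt <- stats::median(diff(df[[1]]))
  series <- lapply(names(df)[-1], function(nm)
    time_series(df[[nm]], dt = dt, label = nm))
  gt <- NULL; meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(j$ground_truth))
      gt <- lapply(j$ground_truth, as.numeric)
    if (!is.null(j$meta)) meta <- as.list(j$meta)
  }
  trial_set(series, ground_truth = gt, meta = meta)
}
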