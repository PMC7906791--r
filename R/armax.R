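#' ARMAX model order
#'
#' Orders of the autoregressive-moving-average model with exogenous
#' input `A(q) y(t) = B(q) u(t - n_k) + C(q) e(t)`, written out as
#' `y(t) + a_1 y(t-1) + ... + a_na y(t-na) = b_1 u(t-nk) + ... +
#' b_nb u(t-nk-nb+1) + c_1 e(t-1) + ... + c_nc e(t-nc) + e(t)`.
#' The delay `n_k` defaults to 10 samples, matching the 10-s prediction
#' horizon at 1-s sampling.
#'
#' @param n_a Number of past outputs (>= 1).
#' @param n_b Number of past inputs (>= 1).
#' @param n_c Number of past noise terms (0 allowed: ARX).
#' @param n_k Input delay in samples (>= 0).
#' @return An object of class `armax_order`.
#' @export
armax_order <- function(n_a, n_b, n_c = 0, n_k = 10) {
  stopifnot(n_a >= 1, n_b >= 1, n_c >= 0, n_k >= 0)
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 n_c = as.integer(n_c), n_k = as.integer(n_k)),
            class = "armax_order")
}

# matrix of lagged values: column j holds x[t - lags[j]] (NA-padded).
lag_matrix <- function(x, lags) {
  n <- length(x)
  vapply(lags, function(l) c(rep(NA_real_, l), x[seq_len(n - l)]),
         numeric(n))
}

# One-step prediction errors e(t) for parameter vector theta, one trial.
# Returns the residual vector (initial transients dropped).
armax_residuals_one <- function(theta, order, y, u) {
  na <- order$n_a; nb <- order$n_b; nc <- order$n_c; nk <- order$n_k
  a <- theta[seq_len(na)]
  b <- theta[na + seq_len(nb)]
  cc <- if (nc > 0) theta[na + nb + seq_len(nc)] else numeric(0)
  vy <- as.numeric(stats::filter(y, c(1, a), method = "convolution",
                                 sides = 1))
  vu <- as.numeric(stats::filter(u, c(rep(0, nk), b),
                                 method = "convolution", sides = 1))
  v <- vy - vu
  t0 <- max(na, nk + nb - 1L) + 1L
  v <- v[t0:length(v)]
  if (anyNA(v)) stop("series too short for the requested order")
  if (nc > 0) {
    as.numeric(stats::filter(v, -cc, method = "recursive"))
  } else {
    v
  }
}

armax_sse <- function(theta, order, trials) {
  tot <- 0; n <- 0L
  for (tr in trials) {
    e <- armax_residuals_one(theta, order, tr$y, tr$u)
    if (!all(is.finite(e))) return(1e12)
    tot <- tot + sum(e^2); n <- n + length(e)
  }
  tot / n
}

poly_stable <- function(coefs) {
  # roots of 1 + c_1 z + ... + c_n z^n must lie outside the unit circle
  if (length(coefs) == 0L || all(coefs == 0)) return(TRUE)
  all(Mod(polyroot(c(1, coefs))) > 1)
}

as_armax_trials <- function(y, u) {
  if (is.list(y) && !is_time_series(y) && is.null(y$values)) {
    stopifnot(is.list(u), length(y) == length(u))
    return(Map(function(yy, uu) list(y = value_of(yy), u = value_of(uu)),
               y, u))
  }
  list(list(y = value_of(y), u = value_of(u)))
}

value_of <- function(x) if (is_time_series(x)) x$values else as.numeric(x)

#' Fit an ARMAX model by prediction-error minimisation
#'
#' Two-stage estimation: a Hannan-Rissanen start (long-AR residuals
#' feed a linear regression for `a`, `b`, `c`), refined by numerical
#' minimisation of the mean squared one-step prediction error (the
#' residuals are computed exactly by the model's own recursion, so the
#' fitted residuals are the model's `e(t)` estimates). Multiple trials
#' may be pooled; the recursion restarts at each trial boundary.
#'
#' @param y Target series (numeric, [time_series], or a list of them).
#' @param u Exogenous input series, aligned with `y`.
#' @param order An [armax_order].
#' @param refine Run the iterative refinement after the
#'   Hannan-Rissanen start?
#' @param control Passed to [stats::optim()] (method BFGS).
#' @return An object of class `armax_model` with coefficient vectors
#'   `a`, `b`, `c`, the `order`, `noise_variance`, and `stable` /
#'   `invertible` flags (an unstable estimate is flagged, not hidden).
#' @export
#' @examples
#' set.seed(1)
#' u <- rnorm(500)
#' y <- as.numeric(stats::filter(0.5 * c(rep(0, 2), u)[1:500],
#'                               c(0.6), method = "recursive"))
#' fit <- fit_armax(y, u, armax_order(1, 1, 0, n_k = 2))
#' fit$a; fit$b
fit_armax <- function(y, u, order, refine = TRUE,
                      control = list(maxit = 200, reltol = 1e-10)) {
  stopifnot(inherits(order, "armax_order"))
  trials <- as_armax_trials(y, u)
  na <- order$n_a; nb <- order$n_b; nc <- order$n_c; nk <- order$n_k
  min_len <- min(vapply(trials, function(tr) length(tr$y), integer(1)))
  if (min_len < 4L * (na + nb + nc + nk + 1L)) {
    stop("series too short relative to the model order")
  }

  # --- Hannan-Rissanen initialisation -------------------------------
  p_long <- min(max(10L, 2L * (na + nc)), min_len %/% 5L)
  build_rows <- function(tr, ehat = NULL) {
    ylags <- lag_matrix(tr$y, seq_len(max(na, 1L)))[, seq_len(na), drop = FALSE]
    ulags <- lag_matrix(tr$u, nk + seq_len(nb) - 1L)
    cols <- cbind(-ylags, ulags)
    if (nc > 0) {
      cols <- cbind(cols, lag_matrix(ehat, seq_len(nc)))
    }
    list(X = cols, yv = tr$y)
  }
  Xs <- list(); ys <- list()
  for (tr in trials) {
    ehat <- NULL
    if (nc > 0) {
      # long ARX to approximate the innovations
      Xl <- cbind(lag_matrix(tr$y, seq_len(p_long)),
                  lag_matrix(tr$u, nk + seq_len(nb) - 1L))
      ok <- stats::complete.cases(Xl)
      fit0 <- stats::lm.fit(Xl[ok, , drop = FALSE], tr$y[ok])
      ehat <- rep(NA_real_, length(tr$y))
      ehat[ok] <- fit0$residuals
      ehat[is.na(ehat)] <- 0
    }
    br <- build_rows(tr, ehat)
    ok <- stats::complete.cases(br$X)
    Xs[[length(Xs) + 1L]] <- br$X[ok, , drop = FALSE]
    ys[[length(ys) + 1L]] <- br$yv[ok]
  }
  X <- do.call(rbind, Xs); yv <- unlist(ys)
  beta <- stats::lm.fit(X, yv)$coefficients
  beta[is.na(beta)] <- 0
  theta <- as.numeric(beta)

  if (refine && nc > 0) {
    # extended-least-squares iterations: refresh the innovation
    # estimates from the current model and re-regress
    for (iter in seq_len(20L)) {
      Xs <- list(); ys <- list()
      for (tr in trials) {
        e_cur <- rep(0, length(tr$y))
        res <- tryCatch(armax_residuals_one(theta, order, tr$y, tr$u),
                        error = function(e) NULL)
        if (is.null(res) || !all(is.finite(res))) break
        e_cur[(length(tr$y) - length(res) + 1L):length(tr$y)] <- res
        br <- build_rows(tr, e_cur)
        ok <- stats::complete.cases(br$X)
        Xs[[length(Xs) + 1L]] <- br$X[ok, , drop = FALSE]
        ys[[length(ys) + 1L]] <- br$yv[ok]
      }
      if (length(Xs) < length(trials)) break
      beta <- stats::lm.fit(do.call(rbind, Xs), unlist(ys))$coefficients
      beta[is.na(beta)] <- 0
      theta_new <- as.numeric(beta)
      if (armax_sse(theta_new, order, trials) >
          armax_sse(theta, order, trials)) break
      delta <- max(abs(theta_new - theta))
      theta <- theta_new
      if (delta < 1e-8) break
    }
  }
  if (refine) {
    opt <- stats::optim(theta, armax_sse, order = order, trials = trials,
                        method = "BFGS", control = control)
    if (opt$value <= armax_sse(theta, order, trials)) theta <- opt$par
  }
  a <- theta[seq_len(na)]
  b <- theta[na + seq_len(nb)]
  cc <- if (nc > 0) theta[na + nb + seq_len(nc)] else numeric(0)
  resid <- unlist(lapply(trials, function(tr)
    armax_residuals_one(theta, order, tr$y, tr$u)))
  structure(list(a = a, b = b, c = cc, order = order,
                 noise_variance = mean(resid^2),
                 stable = poly_stable(a), invertible = poly_stable(cc)),
            class = "armax_model")
}

#' @export
print.armax_model <- function(x, ...) {
  cat(sprintf(
    "<armax_model> na=%d nb=%d nc=%d nk=%d; noise var %.4g%s\n",
    x$order$n_a, x$order$n_b, x$order$n_c, x$order$n_k,
    x$noise_variance,
    if (!x$stable || !x$invertible) " [UNSTABLE/NON-INVERTIBLE]" else ""))
  invisible(x)
}

#' One-step prediction errors of a fitted ARMAX model
#' @param model An `armax_model`.
#' @param y,u Series as in [fit_armax()].
#' @return Residual vector(s) (list when multiple trials).
#' @export
armax_residuals <- function(model, y, u) {
  trials <- as_armax_trials(y, u)
  theta <- c(model$a, model$b, model$c)
  res <- lapply(trials, function(tr)
    armax_residuals_one(theta, model$order, tr$y, tr$u))
  if (length(res) == 1L) res[[1]] else res
}

#' Multi-step ARMAX forecast
#'
#' Minimum-MSE forecast: future innovations are set to their zero
#' expectation and the recursion is iterated `horizon` steps past the
#' end of the history. In the package's sign convention an AR(1) with
#' `y(t) = phi y(t-1) + e(t)` (i.e. `a_1 = -phi`) forecasts
#' `phi^h * y_last`.
#'
#' @param model An `armax_model`.
#' @param y_hist Output history (numeric or [time_series]).
#' @param u Input series, at least as long as the history; entries
#'   beyond the history are used when the delay requires them.
#' @param horizon Steps ahead (>= 1).
#' @return Numeric vector of `horizon` forecasts.
#' @export
forecast_armax <- function(model, y_hist, u, horizon = 10) {
  if (horizon < 1) stop("horizon must be >= 1")
  y <- value_of(y_hist); u <- value_of(u)
  na <- model$order$n_a; nb <- model$order$n_b
  nc <- model$order$n_c; nk <- model$order$n_k
  Tn <- length(y)
  if (Tn < max(na, nk + nb - 1L, nc) + 2L) {
    stop("history shorter than the maximum lag")
  }
  e <- rep(0, Tn + horizon)
  res <- armax_residuals_one(c(model$a, model$b, model$c), model$order,
                             y, u[seq_len(Tn)])
  e[(Tn - length(res) + 1L):Tn] <- res
  yy <- c(y, rep(NA_real_, horizon))
  uu <- c(u, rep(0, max(0L, Tn + horizon - length(u))))
  for (h in seq_len(horizon)) {
    t <- Tn + h
    ar <- -sum(model$a * yy[t - seq_len(na)])
    xb <- sum(model$b * uu[t - nk - seq_len(nb) + 1L])
    ma <- if (nc > 0) sum(model$c * e[t - seq_len(nc)]) else 0
    yy[t] <- ar + xb + ma   # future e(t) = 0
  }
  yy[(Tn + 1L):(Tn + horizon)]
}

#' Rolling k-step-ahead ARMAX predictions
#'
#' For each timepoint `t`, the forecast of `y(t)` made `k` steps
#' earlier (innovations after `t - k` zeroed). This is the prediction
#' series compared against the forecaster's 10-s-ahead output.
#'
#' @param model An `armax_model`.
#' @param y,u Full series (numeric or [time_series]).
#' @param k Forecast horizon in samples (default 10).
#' @return Numeric vector aligned with `y`; leading entries that lack
#'   history are `NA`.
#' @export
armax_predict_series <- function(model, y, u, k = 10) {
  y <- value_of(y); u <- value_of(u)
  na <- model$order$n_a; nb <- model$order$n_b
  nc <- model$order$n_c; nk <- model$order$n_k
  Tn <- length(y)
  theta <- c(model$a, model$b, model$c)
  t0 <- max(na, nk + nb - 1L) + 1L
  res <- armax_residuals_one(theta, model$order, y, u)
  e <- c(rep(0, t0 - 1L), res)
  out <- rep(NA_real_, Tn)
  start <- t0 + max(na, nc) + k
  for (tt in start:Tn) {
    base <- tt - k             # last time with known y and e
    yy <- y[seq_len(base)]
    for (h in seq_len(k)) {
      t <- base + h
      ar <- -sum(model$a * yy[t - seq_len(na)])
      xb <- sum(model$b * u[t - nk - seq_len(nb) + 1L])
      ma <- if (nc > 0) {
        lags <- t - seq_len(nc)
        sum(model$c * ifelse(lags <= base, e[pmax(lags, 1L)], 0))
      } else 0
      yy <- c(yy, ar + xb + ma)
    }
    out[tt] <- yy[tt]
  }
  out
}

#' Exhaustive ARMAX order grid search
#'
#' Evaluates every `(n_a, n_b, n_c)` combination by cross-validated
#' k-step forecast CC with fixed delay `n_k`, and returns the argmax
#' plus the full score table. The desk-scale default grid is
#' 1-10 x 1-10 x 0-5; the full-scale search (orders to 50 by 1 and to
#' 150 by 5) is available by passing the corresponding vectors.
#'
#' @param trials List of `list(y =, u =)` pairs (or `target_pair`s with
#'   zero shift, whose input/target supply `u`/`y`).
#' @param grid Named list with integer vectors `n_a`, `n_b`, `n_c`.
#' @param n_k Input delay (samples).
#' @param k Forecast horizon for scoring (samples).
#' @param washout Samples excluded from scoring at the start.
#' @return List with `best` ([armax_order]) and `table` (one row per
#'   cell with the mean cross-validated CC).
#' @export
grid_search_orders <- function(trials,
                               grid = list(n_a = 1:10, n_b = 1:10,
                                           n_c = 0:5),
                               n_k = 10, k = 10, washout = 250) {
  stopifnot(length(trials) >= 2L)
  trials <- lapply(trials, function(tr) {
    if (inherits(tr, "target_pair")) {
      list(y = tr$target$values, u = tr$input$values)
    } else tr
  })
  cells <- expand.grid(n_a = grid$n_a, n_b = grid$n_b, n_c = grid$n_c)
  if (nrow(cells) == 0L) stop("empty grid")
  scores <- rep(NA_real_, nrow(cells))
  errors <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ord <- armax_order(cells$n_a[i], cells$n_b[i], cells$n_c[i], n_k)
    ccs <- tryCatch({
      vapply(seq_along(trials), function(fold) {
        tr_train <- trials[-fold]
        model <- fit_armax(lapply(tr_train, `[[`, "y"),
                           lapply(tr_train, `[[`, "u"), ord)
        held <- trials[[fold]]
        pred <- armax_predict_series(model, held$y, held$u, k = k)
        sel <- seq_along(pred) > washout & !is.na(pred)
        pearson_cc(pred[sel], held$y[sel])
      }, numeric(1))
    }, error = function(e) { errors[i] <<- conditionMessage(e); NULL })
    if (!is.null(ccs)) scores[i] <- mean(ccs)
  }
  if (all(is.na(scores))) {
    stop(paste("all grid cells failed:",
               paste(unique(errors[errors != ""]), collapse = "; ")))
  }
  cells$cc <- scores
  best <- cells[which.max(scores), ]
  list(best = armax_order(best$n_a, best$n_b, best$n_c, n_k),
       table = cells)
}
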