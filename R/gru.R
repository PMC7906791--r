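#' @useDynLib slowpred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GRU training configuration
#'
#' Architecture and optimisation settings for the gated-recurrent-unit
#' forecaster. The `loss` may be mean squared error (`"mse"`), the
#' negative Pearson correlation between prediction and target (`"cc"`,
#' natural here because CC is also the evaluation metric), or their sum
#' (`"mse_cc"`). The first `washout` outputs only drive the recurrent
#' state and are excluded from both the loss and scoring.
#'
#' @param n_layers Number of stacked GRU layers (1-5).
#' @param hidden_size Hidden state dimension per layer.
#' @param loss One of `"cc"`, `"mse"`, `"mse_cc"`.
#' @param learning_rate Adam learning rate.
#' @param l2 L2 weight-decay strength.
#' @param gradient_clipping `FALSE`, or a positive number bounding the
#'   global gradient norm.
#' @param dropout Dropout fraction applied between stacked layers
#'   (ignored for a single layer).
#' @param residual Feed the input directly into the linear readout
#'   alongside the hidden state?
#' @param batch_size Sequences per weight update.
#' @param n_epochs Passes over the training set.
#' @param washout Initial samples used only to drive the state
#'   (default 250).
#' @param seed Integer seed controlling initialisation and batch order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_layers = 1, hidden_size = 88,
                         loss = c("cc", "mse", "mse_cc"),
                         learning_rate = 1e-3, l2 = 0,
                         gradient_clipping = FALSE, dropout = 0,
                         residual = FALSE, batch_size = 10,
                         n_epochs = 50, washout = 250, seed = 1) {
  loss <- match.arg(loss)
  stopifnot(n_layers >= 1, hidden_size >= 1, batch_size >= 1,
            n_epochs >= 1, washout >= 0, dropout >= 0, dropout < 1,
            learning_rate > 0, l2 >= 0)
  if (!identical(gradient_clipping, FALSE)) {
    stopifnot(is.numeric(gradient_clipping), gradient_clipping > 0)
  }
  structure(list(n_layers = as.integer(n_layers),
                 hidden_size = as.integer(hidden_size), loss = loss,
                 learning_rate = learning_rate, l2 = l2,
                 gradient_clipping = gradient_clipping,
                 dropout = dropout, residual = residual,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 washout = as.integer(washout), seed = as.integer(seed)),
            class = "train_config")
}

#' Optimised hyperparameter presets
#'
#' The two named presets are the hyperparameter sets obtained by
#' Bayesian optimisation for the rat (anesthetised, 0.01-0.05 Hz band)
#' and human (awake, 0.01-0.1 Hz band) single-vessel recordings:
#' rat = 2 layers, hidden 290, CC loss, lr 0.001, L2 3e-4, dropout
#' 0.128, residual readout, batch 22, 87 epochs; human = 1 layer,
#' hidden 88, CC loss, lr 0.00121, L2 0.0221, batch 10, 69 epochs.
#' Both use a 250-sample washout and no gradient clipping.
#'
#' @param name `"human"` or `"rat"`.
#' @param seed Seed stored in the returned config.
#' @return A [train_config].
#' @export
gru_preset <- function(name = c("human", "rat"), seed = 1) {
  name <- match.arg(name)
  if (name == "human") {
    train_config(n_layers = 1, hidden_size = 88, loss = "cc",
                 learning_rate = 0.00121, l2 = 0.0221,
                 gradient_clipping = FALSE, dropout = 0,
                 residual = FALSE, batch_size = 10, n_epochs = 69,
                 washout = 250, seed = seed)
  } else {
    train_config(n_layers = 2, hidden_size = 290, loss = "cc",
                 learning_rate = 0.001, l2 = 3e-4,
                 gradient_clipping = FALSE, dropout = 0.128,
                 residual = TRUE, batch_size = 22, n_epochs = 87,
                 washout = 250, seed = seed)
  }
}

#' Initialise GRU parameters
#'
#' Weights and biases drawn uniformly from plus/minus
#' `1/sqrt(hidden_size)`, the conventional recurrent initialisation.
#'
#' @param hidden_size,n_layers,residual Architecture settings.
#' @param input_size Input dimension (1 for single-vessel traces).
#' @param seed Integer seed.
#' @return A parameter list: `layers` (each with the six weight
#'   matrices `W_ir`, `W_iz`, `W_in`, `W_hr`, `W_hz`, `W_hn` and six
#'   bias vectors), readout weights `w_out` and, when `residual`,
#'   `w_res`.
#' @export
init_gru_params <- function(hidden_size, n_layers = 1, residual = FALSE,
                            input_size = 1, seed = 1) {
  k <- 1 / sqrt(hidden_size)
  with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(l) {
      d <- if (l == 1) input_size else hidden_size
      rm_ <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
      rv_ <- function(n) stats::runif(n, -k, k)
      list(W_ir = rm_(hidden_size, d), W_iz = rm_(hidden_size, d),
           W_in = rm_(hidden_size, d), W_hr = rm_(hidden_size, hidden_size),
           W_hz = rm_(hidden_size, hidden_size),
           W_hn = rm_(hidden_size, hidden_size),
           b_ir = rv_(hidden_size), b_iz = rv_(hidden_size),
           b_in = rv_(hidden_size), b_hr = rv_(hidden_size),
           b_hz = rv_(hidden_size), b_hn = rv_(hidden_size))
    })
    list(layers = layers,
         w_out = stats::runif(hidden_size, -k, k),
         w_res = if (residual) stats::runif(input_size, -k, k) else numeric(1),
         residual = residual, input_size = as.integer(input_size),
         hidden_size = as.integer(hidden_size),
         n_layers = as.integer(n_layers))
  })
}

#' Single GRU recurrence step
#'
#' Evaluates the reset gate `r`, update gate `z`, candidate state `n`
#' and new hidden state `h` for one time step:
#' `r = sigmoid(W_ir x + b_ir + W_hr h + b_hr)`,
#' `z = sigmoid(W_iz x + b_iz + W_hz h + b_hz)`,
#' `n = tanh(W_in x + b_in + r * (W_hn h + b_hn))`,
#' `h = (1 - z) * n + z * h_prev`.
#' For stacked layers the output of each layer is the input of the
#' next.
#'
#' @param params Parameter list from [init_gru_params()].
#' @param x_t Input value(s) at time t.
#' @param h_prev Previous hidden state: a vector (single layer) or a
#'   list of vectors (one per layer).
#' @return A list with `r`, `z`, `n`, `h`; for stacked layers each is a
#'   list over layers.
#' @export
gru_step <- function(params, x_t, h_prev) {
  L <- length(params$layers)
  hs <- if (is.list(h_prev)) h_prev else list(h_prev)
  if (length(hs) != L) stop("h_prev must supply one state per layer")
  x <- matrix(as.numeric(x_t), ncol = 1)
  out <- list(r = vector("list", L), z = vector("list", L),
              n = vector("list", L), h = vector("list", L))
  for (l in seq_len(L)) {
    p <- params$layers[[l]]
    h <- matrix(hs[[l]], ncol = 1)
    if (nrow(x) != ncol(p$W_ir) || nrow(h) != ncol(p$W_hr)) {
      stop("shape mismatch between params and inputs")
    }
    r <- stats::plogis(p$W_ir %*% x + p$b_ir + p$W_hr %*% h + p$b_hr)
    z <- stats::plogis(p$W_iz %*% x + p$b_iz + p$W_hz %*% h + p$b_hz)
    n <- tanh(p$W_in %*% x + p$b_in + r * (p$W_hn %*% h + p$b_hn))
    hnew <- (1 - z) * n + z * h
    out$r[[l]] <- as.numeric(r); out$z[[l]] <- as.numeric(z)
    out$n[[l]] <- as.numeric(n); out$h[[l]] <- as.numeric(hnew)
    x <- hnew
  }
  if (L == 1L) lapply(out, `[[`, 1L) else out
}

#' Linear readout from the hidden state
#'
#' `y(t) = w_out . h(t)`, plus `w_res . x(t)` when the residual path is
#' enabled (the input fed directly to the readout).
#'
#' @param params Parameter list.
#' @param h_t Top-layer hidden state vector.
#' @param x_t Input value(s), needed only for the residual path.
#' @return Predicted value (scalar).
#' @export
readout <- function(params, h_t, x_t = NULL) {
  y <- sum(params$w_out * h_t)
  if (isTRUE(params$residual)) {
    if (is.null(x_t)) stop("residual readout needs x_t")
    y <- y + sum(params$w_res * x_t)
  }
  y
}

#' Correlation-based training objective
#'
#' Returns `-CC(pred, target)` for the `"cc"` loss; `"mse"` returns the
#' mean squared error; `"mse_cc"` returns their equally weighted sum
#' `MSE - CC`.
#'
#' @param pred,target Equal-length numeric vectors (>= 3 samples,
#'   nonzero variance).
#' @param type Loss type.
#' @return Scalar loss.
#' @export
cc_objective <- function(pred, target, type = c("cc", "mse", "mse_cc")) {
  type <- match.arg(type)
  if (length(pred) != length(target)) stop("length mismatch")
  if (length(pred) < 3L) stop("need at least 3 samples")
  if (type != "mse" &&
      (stats::sd(pred) == 0 || stats::sd(target) == 0)) {
    stop("zero-variance input: correlation undefined")
  }
  switch(type,
         cc = -stats::cor(pred, target),
         mse = mean((pred - target)^2),
         mse_cc = mean((pred - target)^2) - stats::cor(pred, target))
}

# ---- internal: parameter flattening for the optimiser ----------------

params_to_vec <- function(p) {
  v <- unlist(lapply(p$layers, function(ly) unlist(ly, use.names = FALSE)),
              use.names = FALSE)
  c(v, p$w_out, p$w_res)
}

vec_to_params <- function(v, template) {
  p <- template
  pos <- 1L
  for (l in seq_along(p$layers)) {
    for (nm in names(p$layers[[l]])) {
      sz <- length(p$layers[[l]][[nm]])
      val <- v[pos:(pos + sz - 1L)]
      if (is.matrix(p$layers[[l]][[nm]])) {
        dim(val) <- dim(p$layers[[l]][[nm]])
      }
      p$layers[[l]][[nm]] <- val
      pos <- pos + sz
    }
  }
  sz <- length(p$w_out)
  p$w_out <- v[pos:(pos + sz - 1L)]; pos <- pos + sz
  sz <- length(p$w_res)
  p$w_res <- v[pos:(pos + sz - 1L)]
  p
}

grads_to_vec <- function(g) {
  v <- unlist(lapply(g$layers, function(ly) unlist(ly, use.names = FALSE)),
              use.names = FALSE)
  c(v, g$w_out, g$w_res)
}

# Loss value and gradient wrt predictions over post-washout samples.
# Y, Tg: T x B matrices. Returns mean per-sequence loss and dY (T x B).
loss_and_grad <- function(Y, Tg, washout, loss) {
  T_ <- nrow(Y); B <- ncol(Y)
  if (washout >= T_ - 2L) stop("washout leaves too few scored samples")
  idx <- (washout + 1L):T_
  nw <- length(idx)
  dY <- matrix(0, T_, B)
  total <- 0
  for (j in seq_len(B)) {
    y <- Y[idx, j]; tg <- Tg[idx, j]
    if (loss %in% c("mse", "mse_cc")) {
      e <- y - tg
      total <- total + mean(e^2)
      dY[idx, j] <- dY[idx, j] + 2 * e / nw
    }
    if (loss %in% c("cc", "mse_cc")) {
      yc <- y - mean(y); tc <- tg - mean(tg)
      sy <- sqrt(sum(yc^2)); st <- sqrt(sum(tc^2))
      if (sy == 0 || st == 0) return(list(loss = NA_real_, dY = dY))
      cc <- sum(yc * tc) / (sy * st)
      total <- total - cc
      dY[idx, j] <- dY[idx, j] - (tc / (sy * st) - cc * yc / sy^2)
    }
  }
  list(loss = total / B, dY = dY / B)
}

# Assemble T x B input/target matrices from target pairs (equal length).
pairs_to_matrices <- function(pairs) {
  ns <- vapply(pairs, function(p) length(p$input$values), integer(1))
  stopifnot(length(unique(ns)) == 1L)
  list(X = vapply(pairs, function(p) p$input$values, numeric(ns[1])),
       Tg = vapply(pairs, function(p) p$target$values, numeric(ns[1])))
}

dropout_masks <- function(cfg) {
  nm <- max(cfg$n_layers - 1L, 1L)
  m <- matrix(1, cfg$hidden_size, nm)
  if (cfg$dropout > 0 && cfg$n_layers > 1L) {
    keep <- matrix(stats::rbinom(cfg$hidden_size * (cfg$n_layers - 1L),
                                 1, 1 - cfg$dropout),
                   cfg$hidden_size, cfg$n_layers - 1L)
    m[, seq_len(cfg$n_layers - 1L)] <- keep / (1 - cfg$dropout)
  }
  m
}

#' Train the GRU forecaster
#'
#' Minimises the configured loss over post-washout samples by Adam,
#' batching whole sequences, with L2 weight decay and optional global
#' gradient-norm clipping. Deterministic given the config seed and
#' `init_seed` (single-threaded).
#'
#' @param pairs List of [make_target_pair()] objects (the training
#'   trials). Sequences of different lengths are grouped into
#'   equal-length sub-batches.
#' @param config A [train_config].
#' @param init_seed Seed for parameter initialisation (defaults to the
#'   config seed).
#' @return An object of class `gru_model`: `params`, `config`,
#'   `recipe` (band/shift used to build targets) and `log` (per-epoch
#'   mean training loss).
#' @export
#' @examples
#' \donttest{
#' trial <- generate_vessel_trial(vessel_trial_spec(n_vessels = 4, seed = 1))
#' pairs <- lapply(trial$series, make_target_pair, band = band_spec(0.01, 0.1))
#' cfg <- train_config(hidden_size = 16, n_epochs = 3, batch_size = 2,
#'                     learning_rate = 0.01)
#' model <- train_gru(pairs, cfg)
#' }
train_gru <- function(pairs, config, init_seed = config$seed) {
  stopifnot(length(pairs) >= 1L,
            all(vapply(pairs, inherits, logical(1), "target_pair")))
  lens <- vapply(pairs, function(p) length(p$input$values), integer(1))
  if (any(lens <= config$washout + 2L)) {
    stop("all traces must be longer than the washout")
  }
  params <- init_gru_params(config$hidden_size, config$n_layers,
                            config$residual, input_size = 1,
                            seed = init_seed)
  theta <- params_to_vec(params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  log_loss <- numeric(config$n_epochs)

  with_seed(derive_seed(config$seed, 1L), {
    for (epoch in seq_len(config$n_epochs)) {
      ord <- sample(seq_along(pairs))
      # group shuffled trials into equal-length batches
      batches <- list()
      for (len in unique(lens[ord])) {
        cand <- ord[lens[ord] == len]
        splits <- split(cand, ceiling(seq_along(cand) / config$batch_size))
        batches <- c(batches, unname(splits))
      }
      epoch_loss <- 0
      for (bidx in batches) {
        mats <- pairs_to_matrices(pairs[bidx])
        params <- vec_to_params(theta, params)
        masks <- dropout_masks(config)
        fwd <- gru_forward_cpp(params$layers, mats$X, params$w_out,
                               params$w_res, params$residual, masks,
                               keep_cache = TRUE)
        lg <- loss_and_grad(fwd$Y, mats$Tg, config$washout, config$loss)
        if (!is.finite(lg$loss)) {
          stop(sprintf(
            "training diverged at epoch %d (non-finite loss); lr=%g",
            epoch, config$learning_rate))
        }
        epoch_loss <- epoch_loss + lg$loss
        bwd <- gru_backward_cpp(params$layers, fwd$cache, mats$X, lg$dY,
                                params$w_out, params$w_res,
                                params$residual, masks)
        g <- grads_to_vec(bwd) + config$l2 * theta
        if (!identical(config$gradient_clipping, FALSE)) {
          gn <- sqrt(sum(g^2))
          if (gn > config$gradient_clipping) {
            g <- g * config$gradient_clipping / gn
          }
        }
        step <- step + 1L
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mhat <- m / (1 - b1^step)
        vhat <- v / (1 - b2^step)
        theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      log_loss[epoch] <- epoch_loss / length(batches)
    }
  })
  params <- vec_to_params(theta, params)
  p1 <- pairs[[1]]
  structure(list(params = params, config = config,
                 recipe = list(band = p1$band, shift = p1$shift,
                               dt = p1$dt),
                 log = data.frame(epoch = seq_len(config$n_epochs),
                                  loss = log_loss)),
            class = "gru_model")
}

#' @export
print.gru_model <- function(x, ...) {
  cat(sprintf(
    "<gru_model> %d layer(s), hidden %d, loss '%s'; trained %d epochs (final loss %.4f)\n",
    x$config$n_layers, x$config$hidden_size, x$config$loss,
    x$config$n_epochs, utils::tail(x$log$loss, 1)))
  invisible(x)
}

# Run the recurrence over one pair; returns Y vector and top h matrix.
gru_run <- function(model, pair) {
  X <- matrix(pair$input$values, ncol = 1)
  masks <- matrix(1, model$config$hidden_size,
                  max(model$config$n_layers - 1L, 1L))
  fwd <- gru_forward_cpp(model$params$layers, X, model$params$w_out,
                         model$params$w_res, model$params$residual,
                         masks, keep_cache = FALSE)
  h <- fwd$h_top           # H x 1 x T cube
  list(y = as.numeric(fwd$Y),
       h = t(matrix(h, dim(h)[1], dim(h)[3])))   # T x H
}

as_model_pair <- function(model, x) {
  if (inherits(x, "target_pair")) return(x)
  make_target_pair(as_time_series(x), band = model$recipe$band,
                   shift = model$recipe$shift)
}

#' Predict a trace and score the prediction
#'
#' Runs the trained recurrence over the full input trace, discards the
#' first `washout` outputs from scoring, and records the Pearson CC,
#' the cross-correlation lag and the 30-s sliding-window score signal
#' between the post-washout prediction and target.
#'
#' @param model A `gru_model`.
#' @param x A `target_pair`, or a raw [time_series] (then the model's
#'   own band/shift recipe builds the target).
#' @param washout Samples to discard from scoring (defaults to the
#'   model's training washout).
#' @return An object of class `prediction_record` with `prediction`,
#'   `target` (equal-length post-washout [time_series]), `cc`, `lag`
#'   (seconds), `window_scores` and `label`.
#' @export
predict_gru <- function(model, x, washout = model$config$washout) {
  pair <- as_model_pair(model, x)
  T_ <- length(pair$input$values)
  if (T_ <= washout + 2L) stop("trace shorter than washout")
  run <- gru_run(model, pair)
  idx <- (washout + 1L):T_
  pred <- run$y[idx]
  tg <- pair$target$values[idx]
  cc <- stats::cor(pred, tg)
  lag <- xcorr_lag(pred, tg, dt = pair$dt)
  ws <- sliding_window_cc(pred, tg, dt = pair$dt)
  structure(list(prediction = time_series(pred, pair$dt,
                                          label = paste0(pair$label, "_pred")),
                 target = time_series(tg, pair$dt,
                                      label = paste0(pair$label, "_target")),
                 cc = cc, lag = lag, window_scores = ws,
                 label = pair$label, washout = washout),
            class = "prediction_record")
}

#' @export
print.prediction_record <- function(x, ...) {
  cat(sprintf("<prediction_record> '%s': CC = %.3f, lag = %g s (%d scored samples)\n",
              x$label, x$cc, x$lag, length(x$prediction$values)))
  invisible(x)
}

#' Cross-validated prediction scores
#'
#' Leave-one-subject-out (`strategy = "subject"`) or
#' leave-one-trial-out within the pooled set (`strategy = "trial"`):
#' the model is trained on all folds but one and every held-out trace
#' is scored exactly once.
#'
#' @param subjects A list of subjects, each a list of `target_pair`s.
#' @param config A [train_config].
#' @param strategy Fold strategy.
#' @return A data frame with columns `fold`, `subject`, `label`, `cc`,
#'   `lag_s`.
#' @export
crossvalidate_gru <- function(subjects, config,
                              strategy = c("subject", "trial")) {
  strategy <- match.arg(strategy)
  stopifnot(length(subjects) >= 2L)
  if (strategy == "trial") {
    subjects <- lapply(unlist(subjects, recursive = FALSE), list)
  }
  if (any(vapply(subjects, length, integer(1)) == 0L)) {
    stop("every fold needs at least one trace")
  }
  rows <- list()
  for (k in seq_along(subjects)) {
    train_pairs <- unlist(subjects[-k], recursive = FALSE)
    model <- train_gru(train_pairs, config)
    for (p in subjects[[k]]) {
      rec <- predict_gru(model, p)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = k, subject = k, label = rec$label, cc = rec$cc,
        lag_s = rec$lag)
    }
  }
  do.call(rbind, rows)
}

#' Default hyperparameter search space
#'
#' The ranges explored by the original optimisation: layers 1-5,
#' hidden size 10-500, all three losses, learning rate 1e-5 to 1
#' (log-uniform), L2 0-10, clipping on/off, dropout 0-0.2, residual
#' on/off, batch size 3-32, epochs 1-100.
#'
#' @return A named list understood by [hyperparameter_search()]: each
#'   element is a fixed value, a `c(lo, hi)` numeric range, or a list
#'   of discrete choices.
#' @export
default_search_space <- function() {
  list(n_layers = 1:5, hidden_size = c(10L, 500L),
       loss = list("mse", "cc", "mse_cc"),
       learning_rate = c(1e-5, 1), l2 = c(0, 10),
       gradient_clipping = list(FALSE, 1), dropout = c(0, 0.2),
       residual = list(FALSE, TRUE), batch_size = c(3L, 32L),
       n_epochs = c(1L, 100L))
}

# Draw raw hyperparameter values from the space (no validation; a
# drawn combination may fail train_config's checks and is then scored
# -Inf by the search).
sample_config_values <- function(space, washout, seed) {
  draw <- function(nm, s) {
    if (is.list(s)) return(s[[sample.int(length(s), 1)]])
    if (length(s) == 1L) return(s)
    if (nm == "learning_rate") {
      return(exp(stats::runif(1, log(s[1]), log(s[2]))))
    }
    if (is.integer(s)) {
      if (length(s) > 2L) return(sample(s, 1))
      return(sample(seq(s[1], s[2]), 1))
    }
    stats::runif(1, s[1], s[2])
  }
  vals <- lapply(names(space), function(nm) draw(nm, space[[nm]]))
  names(vals) <- names(space)
  vals$washout <- washout
  vals$seed <- seed
  vals
}

#' Random hyperparameter search
#'
#' Seeded random search over a space of training configurations,
#' scored by mean cross-validated CC. (Sequential model-based search in
#' the style of tree-of-Parzen-estimators is the reference procedure;
#' random search over the same space is the strategy implemented
#' here, with every evaluated configuration logged.)
#'
#' @param subjects As in [crossvalidate_gru()].
#' @param space Search space, see [default_search_space()]. A space of
#'   fixed single values is returned after one evaluation.
#' @param n_evals Number of configurations to evaluate.
#' @param seed Integer seed.
#' @param washout Washout samples (fixed, not searched).
#' @return The best [train_config]; all evaluations in
#'   `attr(, "log")` (a data frame with one row per config).
#' @export
hyperparameter_search <- function(subjects, space = default_search_space(),
                                  n_evals = 200, seed = 1, washout = 250) {
  if (n_evals < 1) stop("n_evals must be >= 1")
  fixed <- all(vapply(space, function(s)
    (is.list(s) && length(s) == 1L) || (!is.list(s) && length(s) == 1L),
    logical(1)))
  if (fixed) n_evals <- 1L
  logs <- vector("list", n_evals)
  configs <- vector("list", n_evals)
  for (i in seq_len(n_evals)) {
    vals <- with_seed(derive_seed(seed, i),
                      sample_config_values(space, washout,
                                           seed = derive_seed(seed, i)))
    # a draw that fails to validate, train or score gets -Inf and can
    # never be returned
    score <- tryCatch({
      cfg <- do.call(train_config, vals)
      configs[[i]] <- cfg
      tab <- crossvalidate_gru(subjects, cfg)
      mean(tab$cc)
    }, error = function(e) -Inf)
    logs[[i]] <- data.frame(eval = i, n_layers = vals$n_layers,
                            hidden_size = vals$hidden_size,
                            loss = unlist(vals$loss),
                            learning_rate = vals$learning_rate,
                            l2 = vals$l2, dropout = vals$dropout,
                            residual = unlist(vals$residual),
                            batch_size = vals$batch_size,
                            n_epochs = vals$n_epochs,
                            mean_cc = score)
  }
  log_df <- do.call(rbind, logs)
  if (all(!is.finite(log_df$mean_cc))) {
    stop("no configuration could be evaluated")
  }
  best <- configs[[which.max(log_df$mean_cc)]]
  attr(best, "log") <- log_df
  best
}

#' Principal components of the hidden-state trajectory
#'
#' Collects the top-layer hidden states over the post-washout steps of
#' one trace (a T x H matrix), mean-centres and returns principal
#' component scores ordered by explained variance. The first components
#' of a trained forecaster typically track the input and the generated
#' prediction.
#'
#' @param model A `gru_model`.
#' @param x A `target_pair` or raw [time_series].
#' @param washout Samples to discard (defaults to training washout).
#' @return List with `scores` (T x n components), `explained_variance`
#'   and `proportion`.
#' @export
hidden_state_pca <- function(model, x, washout = model$config$washout) {
  pair <- as_model_pair(model, x)
  run <- gru_run(model, pair)
  H <- run$h[(washout + 1L):nrow(run$h), , drop = FALSE]
  if (ncol(H) < 3L) {
    warning("hidden size < 3: returning fewer components")
  }
  pc <- stats::prcomp(H, center = TRUE, scale. = FALSE)
  list(scores = pc$x, explained_variance = pc$sdev^2,
       proportion = pc$sdev^2 / sum(pc$sdev^2))
}

#' Serialise a GRU model to a JSON bundle
#'
#' Weight arrays, configuration and preprocessing recipe in one JSON
#' document (text, so bundles survive plain-text archiving).
#'
#' @param model A `gru_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gru_model <- function(model, path) {
  obj <- list(params = model$params,
              config = unclass(model$config),
              recipe = list(band = c(model$recipe$band$low,
                                     model$recipe$band$high),
                            shift = model$recipe$shift,
                            dt = model$recipe$dt),
              log = model$log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GRU model bundle written by [write_gru_model()]
#' @param path Bundle path.
#' @return A `gru_model`.
#' @export
read_gru_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  hidden <- as.integer(j$params$hidden_size)
  layers <- lapply(j$params$layers, function(ly) {
    out <- list()
    for (nm in c("W_ir", "W_iz", "W_in", "W_hr", "W_hz", "W_hn")) {
      rows <- ly[[nm]]
      out[[nm]] <- do.call(rbind, lapply(rows, num))
    }
    for (nm in c("b_ir", "b_iz", "b_in", "b_hr", "b_hz", "b_hn")) {
      out[[nm]] <- num(ly[[nm]])
    }
    out
  })
  params <- list(layers = layers, w_out = num(j$params$w_out),
                 w_res = num(j$params$w_res),
                 residual = isTRUE(j$params$residual),
                 input_size = as.integer(j$params$input_size),
                 hidden_size = hidden,
                 n_layers = as.integer(j$params$n_layers))
  cfgl <- lapply(j$config, function(x) if (is.list(x)) unlist(x) else x)
  config <- do.call(train_config, cfgl)
  band <- num(j$recipe$band)
  lg <- data.frame(epoch = num(lapply(j$log, `[[`, "epoch")),
                   loss = num(lapply(j$log, `[[`, "loss")))
  structure(list(params = params, config = config,
                 recipe = list(band = band_spec(band[1], band[2]),
                               shift = num(j$recipe$shift),
                               dt = num(j$recipe$dt)),
                 log = lg),
            class = "gru_model")
}
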