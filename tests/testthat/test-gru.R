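test_that("gru_step matches the scalar oracle on 100 random instances", {
  set.seed(1)
  for (i in 1:100) {
    H <- sample(2:6, 1)
    params <- init_gru_params(H, seed = i)
    x <- rnorm(1); h0 <- rnorm(H)
    got <- gru_step(params, x, h0)
    want <- scalar_gru_oracle(params$layers[[1]], x, h0)
    for (nm in c("r", "z", "n", "h")) {
      expect_lt(max(abs(got[[nm]] - want[[nm]])), 1e-10)
    }
    expect_true(all(got$r > 0 & got$r < 1))
    expect_true(all(got$z > 0 & got$z < 1))
  }
})

test_that("all-zero parameters halve the state each step: h(t) = h0 / 2^t", {
  params <- init_gru_params(4, seed = 1)
  for (nm in names(params$layers[[1]])) params$layers[[1]][[nm]][] <- 0
  h <- c(1, -2, 0.5, 8)
  for (t in 1:20) {
    st <- gru_step(params, rnorm(1), h)
    expect_identical(st$r, rep(0.5, 4))
    expect_identical(st$z, rep(0.5, 4))
    expect_identical(st$n, rep(0, 4))
    h <- st$h
    expect_identical(h, c(1, -2, 0.5, 8) / 2^t)
  }
})

test_that("a saturated update gate freezes the state (pure memory limit)", {
  params <- init_gru_params(3, seed = 2)
  params$layers[[1]]$b_iz[] <- 50   # z ~ 1
  h <- c(0.3, -0.7, 1.2)
  for (t in 1:30) h <- gru_step(params, rnorm(1), h)$h
  expect_equal(h, c(0.3, -0.7, 1.2), tolerance = 1e-12)
})

test_that("readout is the stated linear map with optional residual path", {
  params <- init_gru_params(4, residual = TRUE, seed = 3)
  h <- rnorm(4)
  params$w_out[] <- 0; params$w_res[] <- 0
  expect_identical(readout(params, h, 1), 0)
  params$w_out <- c(0, 0, 1, 0)
  expect_identical(readout(params, h, 1), h[3])
  params$w_out[] <- 0; params$w_res <- 1
  expect_identical(readout(params, h, 0.73), 0.73)
})

test_that("cc_objective has the documented fixed points", {
  x <- rnorm(50)
  expect_equal(cc_objective(x, x, "cc"), -1, tolerance = 1e-12)
  expect_equal(cc_objective(x, -x, "cc"), 1, tolerance = 1e-12)
  expect_equal(cc_objective(x, x + 5, "cc"), -1, tolerance = 1e-12)
  expect_equal(cc_objective(x, x, "mse_cc"), -1, tolerance = 1e-12)
  expect_equal(cc_objective(x, x + 1, "mse"), 1, tolerance = 1e-12)
  expect_error(cc_objective(rep(1, 10), rnorm(10), "cc"), "zero-variance")
})

test_that("the batched recurrence agrees with stepwise R evaluation", {
  params <- init_gru_params(5, n_layers = 2, residual = TRUE, seed = 4)
  xseq <- rnorm(15)
  h <- list(rep(0, 5), rep(0, 5))
  y_ref <- numeric(15)
  for (t in 1:15) {
    st <- gru_step(params, xseq[t], h)
    h <- st$h
    y_ref[t] <- readout(params, st$h[[2]], xseq[t])
  }
  fwd <- slowpred:::gru_forward_cpp(params$layers, matrix(xseq, ncol = 1),
                                    params$w_out, params$w_res, TRUE,
                                    matrix(1, 5, 1), FALSE)
  expect_lt(max(abs(y_ref - as.numeric(fwd$Y))), 1e-12)
})

test_that("backpropagation matches finite differences", {
  set.seed(5)
  H <- 5; T_ <- 25; B <- 2
  params <- init_gru_params(H, n_layers = 2, residual = TRUE, seed = 6)
  X <- matrix(rnorm(T_ * B), T_, B)
  Tg <- matrix(rnorm(T_ * B), T_, B)
  masks <- matrix(1, H, 1)
  theta <- slowpred:::params_to_vec(params)
  lossfun <- function(th) {
    pp <- slowpred:::vec_to_params(th, params)
    fwd <- slowpred:::gru_forward_cpp(pp$layers, X, pp$w_out, pp$w_res,
                                      TRUE, masks, FALSE)
    slowpred:::loss_and_grad(fwd$Y, Tg, 4L, "mse_cc")$loss
  }
  fwd <- slowpred:::gru_forward_cpp(params$layers, X, params$w_out,
                                    params$w_res, TRUE, masks, TRUE)
  lg <- slowpred:::loss_and_grad(fwd$Y, Tg, 4L, "mse_cc")
  bwd <- slowpred:::gru_backward_cpp(params$layers, fwd$cache, X, lg$dY,
                                     params$w_out, params$w_res, TRUE,
                                     masks)
  g <- slowpred:::grads_to_vec(bwd)
  idx <- sample(length(theta), 20)
  eps <- 1e-6
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    gn <- (lossfun(tp) - lossfun(tm)) / (2 * eps)
    expect_lt(abs(g[i] - gn), 1e-6)
  }
})

small_sine_pairs <- function(n_pairs, n = 400, target_scale = 1,
                             target_shift = 0) {
  lapply(seq_len(n_pairs), function(i) {
    set.seed(i)
    ph <- runif(1, 0, 2 * pi)
    ts <- time_series(sin(2 * pi * 0.03 * (0:(n - 1)) + ph), 1,
                      label = paste0("p", i))
    tp <- make_target_pair(ts, band_spec(0.01, 0.1), shift = 10,
                           normalize = FALSE)
    tp$target$values <- target_scale * tp$target$values + target_shift
    tp
  })
}

test_that("training is deterministic given the seeds", {
  pairs <- small_sine_pairs(4)
  cfg <- train_config(hidden_size = 12, n_epochs = 3, batch_size = 2,
                      learning_rate = 0.01, washout = 50, seed = 7)
  m1 <- train_gru(pairs, cfg)
  m2 <- train_gru(pairs, cfg)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$params$w_out, m2$params$w_out)
})

test_that("the CC loss is invariant to affine rescaling of the targets", {
  cfg <- train_config(hidden_size = 12, n_epochs = 3, batch_size = 2,
                      learning_rate = 0.01, loss = "cc", washout = 50,
                      seed = 7)
  m1 <- train_gru(small_sine_pairs(4), cfg)
  m2 <- train_gru(small_sine_pairs(4, target_scale = 3.7,
                                   target_shift = -1.2), cfg)
  expect_equal(m1$log$loss, m2$log$loss, tolerance = 1e-9)
})

test_that("washout bookkeeping holds and pre-washout input only acts through state", {
  model <- fixture_small_model()
  trial <- generate_vessel_trial(vessel_trial_spec(n_vessels = 1,
                                                   seed = 77))
  pair <- make_target_pair(trial$series[[1]], band_spec(0.01, 0.1))
  rec <- predict_gru(model, pair)
  T_ <- length(pair$input$values)
  expect_identical(length(rec$prediction$values),
                   T_ - model$config$washout)
  expect_identical(length(rec$target$values), length(rec$prediction$values))
  # perturb pre-washout samples: scored lengths unchanged
  pair2 <- pair
  pair2$input$values[1:50] <- rev(pair2$input$values[1:50])
  rec2 <- predict_gru(model, pair2)
  expect_identical(length(rec2$prediction$values),
                   length(rec$prediction$values))
  expect_error(predict_gru(model, pair, washout = T_), "washout")
})

test_that("divergence is reported with diagnostics rather than NaNs", {
  pairs <- small_sine_pairs(2)
  # targets made constant post-washout: CC undefined -> abort
  pairs <- lapply(pairs, function(p) {
    p$target$values[] <- 1; p
  })
  cfg <- train_config(hidden_size = 8, n_epochs = 1, batch_size = 2,
                      washout = 50, seed = 1)
  expect_error(train_gru(pairs, cfg), "diverged")
})

test_that("cross-validation scores every vessel exactly once per fold design", {
  subjects <- lapply(1:3, function(s) small_sine_pairs(2)[1:2])
  for (s in 1:3) {
    for (i in 1:2) {
      subjects[[s]][[i]]$label <- sprintf("s%d_v%d", s, i)
      subjects[[s]][[i]]$input$label <- subjects[[s]][[i]]$label
    }
  }
  cfg <- train_config(hidden_size = 8, n_epochs = 2, batch_size = 2,
                      learning_rate = 0.01, washout = 50, seed = 3)
  tab <- crossvalidate_gru(subjects, cfg)
  expect_identical(nrow(tab), 6L)
  expect_identical(sort(tab$label),
                   sort(as.vector(outer(1:3, 1:2, function(s, i)
                     sprintf("s%d_v%d", s, i)))))
  expect_identical(anyDuplicated(tab$label), 0L)
  # permuting subject order leaves the per-vessel scores unchanged
  tab_perm <- crossvalidate_gru(subjects[c(2, 3, 1)], cfg)
  expect_equal(tab_perm$cc[order(tab_perm$label)],
               tab$cc[order(tab$label)], tolerance = 1e-12)
})

test_that("hyperparameter search returns the single point of a collapsed space", {
  subjects <- lapply(1:2, function(s) small_sine_pairs(1))
  space <- list(n_layers = 1L, hidden_size = 8L, loss = list("cc"),
                learning_rate = 0.01, l2 = 0,
                gradient_clipping = list(FALSE), dropout = 0,
                residual = list(FALSE), batch_size = 2L, n_epochs = 2L)
  best <- hyperparameter_search(subjects, space, n_evals = 50, seed = 1,
                                washout = 50)
  expect_identical(nrow(attr(best, "log")), 1L)
  expect_identical(best$hidden_size, 8L)
  expect_error(hyperparameter_search(subjects, space, n_evals = 0),
               "n_evals")
})

test_that("hyperparameter search rejects configurations that cannot train", {
  subjects <- lapply(1:2, function(s) small_sine_pairs(2))
  # a two-point learning-rate space where one point is degenerate
  # (nonpositive rate, cannot train): the search must log it at -Inf
  # and return the other point
  space <- list(n_layers = 1L, hidden_size = 8L, loss = list("cc"),
                learning_rate = list(-1, 0.01), l2 = 0,
                gradient_clipping = list(FALSE), dropout = 0,
                residual = list(FALSE), batch_size = 2L, n_epochs = 3L)
  best <- hyperparameter_search(subjects, space, n_evals = 6, seed = 2,
                                washout = 50)
  lg <- attr(best, "log")
  expect_true(all(c(-1, 0.01) %in% lg$learning_rate))
  expect_true(all(lg$mean_cc[lg$learning_rate == -1] == -Inf))
  expect_identical(best$learning_rate, 0.01)
})

test_that("Table-1-style presets load with the published values", {
  h <- gru_preset("human")
  expect_identical(h$n_layers, 1L)
  expect_identical(h$hidden_size, 88L)
  expect_identical(h$loss, "cc")
  expect_equal(h$learning_rate, 0.00121)
  expect_equal(h$l2, 0.0221)
  expect_identical(h$batch_size, 10L)
  expect_identical(h$n_epochs, 69L)
  expect_identical(h$washout, 250L)
  expect_false(h$residual)
  r <- gru_preset("rat")
  expect_identical(r$n_layers, 2L)
  expect_identical(r$hidden_size, 290L)
  expect_equal(r$dropout, 0.128)
  expect_true(r$residual)
  expect_identical(r$batch_size, 22L)
  expect_identical(r$n_epochs, 87L)
})

test_that("hidden-state PCA is a valid decomposition that tracks the input", {
  model <- fixture_small_model()
  trial <- generate_vessel_trial(vessel_trial_spec(n_vessels = 1,
                                                   seed = 31))
  pair <- make_target_pair(trial$series[[1]], band_spec(0.01, 0.1))
  pc <- hidden_state_pca(model, pair)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_equal(sum(pc$proportion), 1, tolerance = 1e-12)
  x_post <- pair$input$values[(model$config$washout + 1):
                                length(pair$input$values)]
  expect_gt(abs(cor(pc$scores[, 1], x_post)),
            abs(cor(pc$scores[, 3], x_post)))
})

test_that("model bundles round-trip through JSON", {
  model <- fixture_small_model()
  path <- tempfile(fileext = ".json")
  write_gru_model(model, path)
  back <- read_gru_model(path)
  trial <- generate_vessel_trial(vessel_trial_spec(n_vessels = 1,
                                                   seed = 55))
  pair <- make_target_pair(trial$series[[1]], band_spec(0.01, 0.1))
  r1 <- predict_gru(model, pair)
  r2 <- predict_gru(back, pair)
  expect_equal(r1$prediction$values, r2$prediction$values,
               tolerance = 1e-12)
  expect_equal(r1$cc, r2$cc, tolerance = 1e-12)
  unlink(path)
})
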