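# Shared fixtures, built once per test run and memoised. The heavy
# fixture (a forecaster trained under the study conditions) backs the
# synthetic-mirror tests; the small fixture backs unit tests that just
# need some trained model.

.fixture_env <- new.env(parent = emptyenv())

# Independent scalar implementation of the four GRU gate equations,
# written with plain loops and arithmetic only: the oracle against
# which gru_step is checked.
scalar_gru_oracle <- function(p, x, h_prev) {
  H <- length(h_prev)
  sig <- function(v) 1 / (1 + exp(-v))
  r <- z <- nn <- hh <- numeric(H)
  for (i in seq_len(H)) {
    ar <- p$b_ir[i] + p$b_hr[i]
    az <- p$b_iz[i] + p$b_hz[i]
    m <- p$b_hn[i]
    for (j in seq_along(x)) {
      ar <- ar + p$W_ir[i, j] * x[j]
      az <- az + p$W_iz[i, j] * x[j]
    }
    for (j in seq_len(H)) {
      ar <- ar + p$W_hr[i, j] * h_prev[j]
      az <- az + p$W_hz[i, j] * h_prev[j]
      m <- m + p$W_hn[i, j] * h_prev[j]
    }
    r[i] <- sig(ar); z[i] <- sig(az)
    an <- p$b_in[i] + r[i] * m
    for (j in seq_along(x)) an <- an + p$W_in[i, j] * x[j]
    nn[i] <- tanh(an)
    hh[i] <- (1 - z[i]) * nn[i] + z[i] * h_prev[i]
  }
  list(r = r, z = z, n = nn, h = hh)
}

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

human_band <- function() band_spec(0.01, 0.1)

# 24 synthetic trials x 5 vessels under the default study conditions
# (SNR ~ 1, 900 samples at 1 s): 120 vessel traces over 24 distinct
# shared slow components, so that held-out scoring averages over many
# independent component realisations.
fixture_subjects <- function() {
  memo("subjects", function() {
    lapply(1:24, function(s)
      generate_vessel_trial(vessel_trial_spec(n_vessels = 5,
                                              seed = 100 + s)))
  })
}

fixture_pairs <- function(trial) {
  lapply(trial$series, make_target_pair, band = human_band())
}

# Forecaster trained with the human preset on trials 1-12 (60 vessel
# traces); trials 13-24 are held out for scoring.
fixture_model <- function() {
  memo("model", function() {
    train_pairs <- unlist(lapply(fixture_subjects()[1:12], fixture_pairs),
                          recursive = FALSE)
    train_gru(train_pairs, gru_preset("human", seed = 1))
  })
}

# Held-out prediction records for real traces and their matched IAAFT
# surrogates.
fixture_mirror <- function() {
  memo("mirror", function() {
    model <- fixture_model()
    real_cc <- c(); surr_cc <- c(); lag_s <- c()
    for (si in 13:24) {
      tr <- fixture_subjects()[[si]]
      su <- surrogate_set(tr, seed = 500 + si)
      for (i in seq_along(tr$series)) {
        r <- predict_gru(model, fixture_pairs(tr)[[i]])
        s <- predict_gru(model, fixture_pairs(su)[[i]])
        real_cc <- c(real_cc, r$cc)
        surr_cc <- c(surr_cc, s$cc)
        lag_s <- c(lag_s, r$lag)
      }
    }
    list(real_cc = real_cc, surr_cc = surr_cc, lag_s = lag_s)
  })
}

# Small, quickly trained model for unit tests that only need a trained
# forecaster of some kind.
fixture_small_model <- function() {
  memo("small_model", function() {
    trial <- generate_vessel_trial(vessel_trial_spec(n_vessels = 8,
                                                     seed = 11))
    pairs <- fixture_pairs(trial)
    cfg <- train_config(hidden_size = 24, n_epochs = 15, batch_size = 4,
                        learning_rate = 0.005, loss = "cc",
                        washout = 250, seed = 2)
    train_gru(pairs, cfg)
  })
}
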