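test_that("percentile groups select the stated extremes with stable ties", {
  g <- percentile_groups(1:100, 0.05)
  expect_identical(g$top, 96:100)
  expect_identical(g$bottom, 1:5)
  expect_length(intersect(g$top, g$bottom), 0)
  # all-equal scores: documented tie rule (earliest bottom, latest top)
  ge <- percentile_groups(rep(1, 40), 0.1)
  expect_identical(ge$bottom, 1:4)
  expect_identical(ge$top, 37:40)
  expect_error(percentile_groups(1:5, 0.05), "too few")
  expect_error(percentile_groups(1:100, 0.6), "pct")
})

test_that("seed correlation maps behave like per-column Pearson correlation", {
  set.seed(1)
  m <- matrix(rnorm(300 * 5), 300, 5)
  seed <- m[, 2]
  cmap <- seed_correlation_map(seed, m)
  expect_length(cmap, 5)
  expect_equal(cmap[2], 1, tolerance = 1e-12)
  # column orthogonalised against the seed correlates at 0
  m2 <- m
  m2[, 4] <- residuals(lm(m[, 4] ~ seed))
  expect_lt(abs(seed_correlation_map(seed, m2)[4]), 1e-10)
  m3 <- m; m3[, 5] <- 2
  expect_warning(cm3 <- seed_correlation_map(seed, m3), "zero-variance")
  expect_true(is.na(cm3[5]))
})

test_that("difference maps are antisymmetric and flag coupled nodes", {
  set.seed(2)
  a <- matrix(runif(40, 0.1, 0.4), 8, 5)
  same <- difference_map(a, a)
  expect_equal(same$difference, rep(0, 5), tolerance = 1e-12)
  expect_false(any(same$significant))
  b <- a + matrix(rnorm(40, 0, 0.01), 8, 5)
  d1 <- difference_map(a, b)
  d2 <- difference_map(b, a)
  expect_equal(d1$difference, -d2$difference, tolerance = 1e-12)
  expect_error(difference_map(a[1, , drop = FALSE], a), ">= 2 maps")
})

test_that("global-coupling difference concentrates outside the DMN", {
  mk_maps <- function(gc, seeds) {
    lapply(seeds, function(sd) {
      s <- generate_network_session(network_session_spec(
        n_rois = 20, dmn_roi_indices = 1:5, global_coupling = gc,
        dmn_coupling = 1, noise_sd = 0.7, seed = sd))
      seed_correlation_map(global_signal <- rowMeans(s$roi_traces),
                           s$roi_traces)
    })
  }
  top <- mk_maps(1.5, 1:6)
  bottom <- mk_maps(0.3, 11:16)
  dm <- difference_map(top, bottom)
  expect_gt(mean(dm$difference[6:20]), mean(dm$difference[1:5]))
  expect_gt(mean(dm$difference[6:20]), 0)
})

test_that("intrinsic DMN correlation is the mean of correlations", {
  set.seed(3)
  comp <- rnorm(400)
  m <- cbind(comp, comp, comp)
  expect_equal(intrinsic_dmn_correlation(comp, m), 1, tolerance = 1e-12)
  # counterexample where mean-of-correlations != correlation-of-means
  v <- cbind(comp, -0.5 * comp)
  expect_equal(intrinsic_dmn_correlation(comp, v), 0, tolerance = 1e-12)
  expect_equal(cor(comp, rowMeans(v)), 1, tolerance = 1e-12)
  # independent noise voxels: near-zero index on average
  idx <- vapply(1:30, function(s) {
    set.seed(100 + s)
    intrinsic_dmn_correlation(rnorm(900), matrix(rnorm(900 * 4), 900, 4))
  }, numeric(1))
  expect_lt(abs(mean(idx)), 0.1)
  expect_error(intrinsic_dmn_correlation(comp, m[, 0]), "empty")
})

test_that("binned curves follow their construction rules", {
  s <- rnorm(200)
  curve <- binned_relationship(s, s, bin_pct = 0.02)
  expect_identical(nrow(curve), 50L)
  expect_equal(curve$mean_value, curve$mean_score, tolerance = 1e-12)
  expect_true(all(diff(curve$mean_score) > 0))
  # remainder joins the last bin
  c2 <- binned_relationship(rnorm(103), rnorm(103), bin_pct = 0.02)
  expect_identical(nrow(c2), 51L)
  expect_identical(sum(c2$n), 103L)
  expect_identical(c2$n[51], 3L)   # 103 = 50 bins of 2 + last bin of 3
  expect_error(binned_relationship(rnorm(10), rnorm(10), 0.02), "too few")
})

test_that("variance grouping tracks scale and ignores ordering", {
  set.seed(4)
  base <- rnorm(900)
  scales <- seq(0.5, 3, length.out = 30)
  sessions <- lapply(scales, function(sc)
    session_data(roi_traces = cbind(sc * base, sc * base + rnorm(900, 0, 1e-6)),
                 dt = 1))
  vg <- variance_groups(sessions, pct = 0.1)
  expect_identical(order(vg$variance), order(scales))
  expect_identical(vg$groups$top, 28:30)
  perm <- c(15:30, 1:14)
  vg2 <- variance_groups(sessions[perm], pct = 0.1)
  expect_identical(sort(perm[vg2$groups$top]), 28:30)
  # score comparison report
  vg3 <- variance_groups(sessions, pct = 0.1, scores = rev(scales))
  expect_named(vg3$overlap, c("top", "bottom"))
  expect_length(vg3$score_range$top, 2)
})

test_that("spectral reordering restores shuffled block structure", {
  set.seed(5)
  n <- 20
  block <- rep(c(1, 2), each = n / 2)
  C <- outer(block, block, function(a, b) ifelse(a == b, 0.8, -0.2))
  diag(C) <- 1
  C <- C + matrix(rnorm(n * n, 0, 0.01), n, n)
  C <- (C + t(C)) / 2
  perm0 <- sample(n)
  Cs <- C[perm0, perm0]
  p <- spectral_reorder(Cs)
  expect_identical(sort(p), 1:20)
  labels <- block[perm0][p]
  # blocks contiguous: exactly one label change along the ordering
  expect_identical(sum(diff(labels) != 0), 1L)
  # bandedness does not decrease
  adj_sum <- function(M) sum(abs(M[cbind(1:(n - 1), 2:n)]))
  expect_gte(adj_sum(Cs[p, p]), adj_sum(Cs))
  # identity matrix: affinity is uniform, any order valid; result is a
  # deterministic permutation
  pi1 <- spectral_reorder(diag(4))
  expect_identical(sort(pi1), 1:4)
  expect_identical(pi1, spectral_reorder(diag(4)))
  # perfectly anti-correlated blocks disconnect the affinity graph
  Cd <- matrix(-1, 4, 4)
  Cd[1:2, 1:2] <- 1; Cd[3:4, 3:4] <- 1
  expect_warning(pd <- spectral_reorder(Cd), "disconnected")
  expect_identical(sort(pd), 1:4)
  expect_error(spectral_reorder(matrix(1:6, 2, 3)), "square")
})

test_that("spectral_reorder always returns a bijection", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    m <- matrix(rnorm(n * 60), 60, n)
    p <- spectral_reorder(cor(m))
    expect_identical(sort(p), seq_len(n))
  }
})

test_that("session scoring orders strong vs weak shared-component sessions", {
  model <- fixture_small_model()
  mk <- function(gc, seed) generate_network_session(network_session_spec(
    n_rois = 10, dmn_roi_indices = 1:3, global_coupling = gc,
    dmn_coupling = 0.5, noise_sd = 0.7, seed = seed))
  strong <- lapply(1:4, function(s) mk(1.8, 200 + s))
  weak <- lapply(1:4, function(s) mk(0.3, 300 + s))
  tab <- score_sessions(model, c(strong, weak), roi = "roi010")
  expect_identical(nrow(tab), 8L)
  expect_true(all(is.na(tab$error)))
  expect_gt(mean(tab$cc[1:4]), mean(tab$cc[5:8]))
  tab2 <- score_sessions(model, c(strong, weak), roi = "roi010")
  expect_identical(tab$cc, tab2$cc)
  # missing ROI fails per-session, others proceed
  tab3 <- score_sessions(model, strong, roi = "nonexistent")
  expect_true(all(!is.na(tab3$error)))
})

test_that("probe preference maps have the grid shape", {
  model <- fixture_small_model()
  pm <- probe_preference_map(model, f0_grid = c(0.03, 0.2),
                             width_grid = c(0.005, 0.01), n_seeds = 2,
                             n_timepoints = 600)
  expect_identical(dim(pm), c(2L, 2L))
  expect_true(all(is.finite(pm)))
  expect_error(probe_preference_map(model, numeric(0), 0.01), "empty")
})
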