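test_that("half-sine template matches the hand-computed discretization", {
  tpl <- half_sine_template(16, 250)   # 4 samples at 250 Hz
  expect_equal(tpl$n_samples, 4)
  expect_equal(tpl$weights, c(0.2706, 0.6533, 0.6533, 0.2706),
               tolerance = 1e-4)
  for (w_ms in c(20, 36, 50, 60)) {
    tpl <- half_sine_template(w_ms, 250)
    expect_equal(sum(tpl$weights^2), 1, tolerance = 1e-12)
    expect_equal(tpl$weights, rev(tpl$weights))   # symmetric
  }
  # 50 ms at 250 Hz rounds up to 13 samples (52 ms)
  expect_equal(half_sine_template(50, 250)$n_samples, 13)
  expect_error(half_sine_template(4, 250), "under 2 samples")
})

test_that("template matching is a linear matched filter peaking at the onset", {
  tpl <- half_sine_template(50, 250)
  t_len <- 80
  x <- matrix(0, t_len, 2)
  t0 <- 40
  idx <- t0 - tpl$n_samples %/% 2 + seq_len(tpl$n_samples) - 1
  x[idx, 1] <- tpl$weights
  y <- pattern_match(x, tpl)
  expect_equal(which.max(y[, 1]), t0)
  expect_equal(max(y[, 1]), 1, tolerance = 1e-12)   # unit-energy autocorrelation
  expect_equal(y[, 2], rep(0, t_len))

  set.seed(1)
  x1 <- matrix(rnorm(t_len * 2), t_len)
  x2 <- matrix(rnorm(t_len * 2), t_len)
  expect_equal(pattern_match(2 * x1 - x2, tpl),
               2 * pattern_match(x1, tpl) - pattern_match(x2, tpl),
               tolerance = 1e-12)
})

test_that("spatial basis captures training covariance structure", {
  set.seed(2)
  # rank-1 data: one spatial pattern modulated over time
  pat <- rnorm(6)
  trials <- lapply(1:5, function(i) pat %o% rnorm(100))
  dset <- structure(list(trials = trials, fs = 250), class = "decomp_set")
  b <- fit_spatial_basis(dset, n_components = 1)
  expect_gt(b$eigenvalues[1] / sum(abs(b$eigenvalues)), 0.999)
  expect_error(fit_spatial_basis(dset, n_components = 4), "rank")

  # full-rank noise: requested component count is honored
  trials2 <- lapply(1:5, function(i) matrix(rnorm(6 * 200), 6))
  dset2 <- structure(list(trials = trials2, fs = 250), class = "decomp_set")
  b2 <- fit_spatial_basis(dset2, n_components = 4)
  proj <- project_epochs(b2, dset2)
  expect_equal(dim(proj[[1]]), c(200, 4))
  # standardized components have unit RMS on the training data
  expect_equal(sqrt(rowMeans(do.call(cbind, lapply(proj, t))^2)),
               rep(1, 4), tolerance = 1e-12)
})

test_that("E-step marginals equal brute-force enumeration (K = 1 and 2)", {
  set.seed(3)
  for (rep_i in 1:5) {
    t_len <- sample(30:60, 1)
    d_comp <- 3
    y <- matrix(rnorm(t_len * d_comp, sd = 1), t_len, d_comp)
    m1 <- matrix(rnorm(d_comp), 1)
    th1 <- c(runif(1, 3, 15), runif(1, 3, 15))
    fb <- dualseq:::fb_trial(y, m1, th1)
    or <- oracle_estep(y, m1, th1)
    expect_lt(max(abs(fb$gamma - or$gamma)), 1e-8)
    expect_equal(fb$loglik, or$loglik, tolerance = 1e-8)

    m2 <- matrix(rnorm(2 * d_comp), 2)
    th2 <- runif(3, 3, 15)
    for (gap in c(1, 5)) {
      fb2 <- dualseq:::fb_trial(y, m2, th2, min_gap = gap)
      or2 <- oracle_estep(y, m2, th2, min_gap = gap)
      expect_lt(max(abs(fb2$gamma - or2$gamma)), 1e-8)
      expect_equal(fb2$loglik, or2$loglik, tolerance = 1e-8)
    }
  }
})

test_that("EM concentrates on a planted onset and the likelihood never decreases", {
  tpl <- half_sine_template(50, 250)
  t_len <- 100
  t0 <- 42
  d_comp <- 4
  pat <- c(2, -1, 1.5, 0.5)
  x <- matrix(0, t_len, d_comp)
  idx <- t0 - tpl$n_samples %/% 2 + seq_len(tpl$n_samples) - 1
  x[idx, ] <- tpl$weights %o% pat
  matches <- list(pattern_match(x, tpl))
  fit <- em_fit(matches, 1)
  expect_equal(which.max(fit$gammas[[1]][, 1]), t0)
  expect_true(all(diff(fit$model$loglik_history) > -1e-6))

  # noisy multi-trial run: monotone likelihood is preserved
  set.seed(4)
  noisy <- lapply(1:10, function(i) {
    x2 <- x + matrix(rnorm(t_len * d_comp, sd = 0.8), t_len)
    pattern_match(x2, tpl)
  })
  fit2 <- em_fit(noisy, 2, min_gap = tpl$n_samples)
  # the duration update is moment-matched (generalized EM): the likelihood
  # may dip by at most the convergence tolerance at the final step
  h2 <- fit2$model$loglik_history
  expect_true(all(diff(h2) > -1e-3 * (1 + abs(h2[-length(h2)]))))
  expect_true(all(is.finite(fit2$model$magnitudes)))
  expect_true(all(fit2$model$theta > 0))
  # onset marginals are normalized and ordered in expectation
  g <- fit2$gammas[[1]]
  expect_equal(colSums(g), rep(1, 2), tolerance = 1e-9)
  e_t <- colSums(g * seq_len(nrow(g)))
  expect_true(all(diff(e_t) > 0))
})

test_that("cumulative fitting flags pure noise and recovers planted events", {
  set.seed(5)
  tpl <- half_sine_template(50, 250)
  noise <- lapply(1:40, function(i) matrix(rnorm(120 * 5, sd = 1), 120))
  noise <- lapply(noise, function(x) pattern_match(x, tpl) / 1.6)
  cf0 <- cumulative_fit(noise, k_max = 3, mag_floor = 0.2,
                        min_gap = tpl$n_samples)
  expect_true(cf0$no_events)
  expect_equal(cf0$k_events, 0L)

  # three well-separated strong events
  pats <- list(c(3, 0, 0, 0, 0), c(0, 3, 0, 0, 0), c(0, 0, 3, 0, 0))
  onsets <- c(30, 75, 120)
  trials <- lapply(1:30, function(i) {
    x <- matrix(rnorm(160 * 5, sd = 1), 160)
    for (k in 1:3) {
      t0 <- onsets[k] + sample(-8:8, 1)
      idx <- t0 - tpl$n_samples %/% 2 + seq_len(tpl$n_samples) - 1
      x[idx, ] <- x[idx, ] + tpl$weights %o% pats[[k]]
    }
    x
  })
  matches <- match_series(trials, tpl)
  cf <- cumulative_fit(matches, k_max = 5, min_gap = tpl$n_samples)
  expect_equal(cf$k_events, 3L)
  expect_true(all(diff(cf$accepted_logliks) > 0))
})

test_that("the stable-width rule reproduces its documented tie-break", {
  # profile over 20..60 ms: runs of K = 3 at 35-45 and K = 2 at 50-60;
  # equal length -> the run with larger widths wins, center 55
  ks <- c(6, 5, 4, 3, 3, 3, 2, 2, 2)
  widths <- seq(20, 60, by = 5)
  expect_equal(widths[dualseq:::stable_width_index(ks)], 55)
  # a single global plateau picks its center
  expect_equal(widths[dualseq:::stable_width_index(rep(3, 9))], 40)
  # even-length runs take the upper middle
  expect_equal(widths[dualseq:::stable_width_index(c(4, 3, 3, 3, 3, 2, 2, 1, 1))], 35)
  expect_error(dualseq:::stable_width_index(c(1, 2, 3, 4, 5, 6, 7, 8, 9)),
               "no stable width")
})

test_that("label tensors sum to one with capping and pure-Negative pads", {
  g <- matrix(0, 20, 2)
  g[5, 1] <- 0.75
  g[6, 1] <- 0.25
  g[5, 2] <- 0.5
  g[10, 2] <- 0.5
  dset <- structure(list(n_samples_full = 30, start_sample = 4),
                    class = "decomp_set")
  lab <- build_label_tensors(list(g), dset)[[1]]
  expect_equal(dim(lab), c(30, 3))
  expect_equal(rowSums(lab), rep(1, 30), tolerance = 1e-9)
  # timestep 5 of the window (full row 8): 0.75 + 0.5 = 1.25 -> rescaled by 0.8
  expect_equal(unname(lab[8, 1]), 0.6)
  expect_equal(unname(lab[8, 2]), 0.4)
  expect_equal(unname(lab[8, 3]), 0)
  # pads are pure Negative
  expect_equal(unname(lab[1:3, 3]), rep(1, 3))
  expect_equal(unname(lab[25:30, 3]), rep(1, 6))

  g_bad <- g; g_bad[1, 1] <- -0.1
  expect_error(build_label_tensors(list(g_bad), dset), "negative")
})
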