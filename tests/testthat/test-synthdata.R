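test_that("topographies are unit-norm, separable and deterministic", {
  tp <- make_topographies(6, 32, seed = 1)
  expect_equal(dim(tp), c(32, 6))
  expect_equal(colSums(tp^2), rep(1, 6), tolerance = 1e-12)
  cs <- crossprod(tp)
  diag(cs) <- 0
  expect_lt(max(abs(cs)), 0.3 + 1e-12)

  tp2 <- make_topographies(6, 32, seed = 1)
  expect_identical(tp, tp2)

  t22 <- make_topographies(2, 2, seed = 5)
  expect_equal(abs(sum(t22[, 1] * t22[, 2])), 0, tolerance = 0.3)

  expect_error(make_topographies(6, 4), "separable")
})

test_that("Long-condition truths are serial sequence A finishing before the SOA", {
  cfg <- sim_config(n_participants = 2, trials_per_condition = 4)
  set.seed(2)
  for (i in 1:50) {
    tr <- sample_trial_onsets(cfg, 1, "Long")
    expect_equal(tr$sequence_label, "A")
    expect_lt(tr$onset_R1, cfg$soa_long_ms)
    expect_true(tr$onset_E1 < tr$onset_C1 && tr$onset_C1 < tr$onset_R1)
    expect_true(tr$onset_E2 < tr$onset_C2 && tr$onset_C2 < tr$onset_R2)
    expect_gte(tr$rt1, tr$onset_R1)
    expect_gte(tr$rt2, tr$onset_R2 - cfg$soa_long_ms)
  }
})

test_that("Short-condition onsets follow the drawn label's ordering by construction", {
  mix <- matrix(0, 1, 6, dimnames = list(NULL, SEQUENCE_LABELS))
  mix[, "D"] <- 1
  cfg <- sim_config(n_participants = 1, trials_per_condition = 4,
                    strategy_mixture = mix)
  set.seed(3)
  for (i in 1:50) {
    tr <- sample_trial_onsets(cfg, 1, "Short")
    expect_equal(tr$sequence_label, "D")
    o <- unlist(tr[paste0("onset_", c("E1", "C1", "E2", "C2", "R1", "R2"))])
    expect_true(all(diff(o) > 0))   # E1<C1<E2<C2<R1<R2, Table row D
  }
})

test_that("generated stage durations have the configured means (3 SE at n = 1000)", {
  se <- sqrt(2 * (100 / 2)^2 / 1000)   # sd of a gamma(2, 50) mean over n
  # the Long-condition E1 onset is a single stage draw
  cfg <- sim_config(n_participants = 1, trials_per_condition = 2,
                    stage_mean_ms = list(task1 = c(100, 100, 100),
                                         task2 = c(100, 100, 100)))
  set.seed(5)
  e1 <- replicate(1000, sample_trial_onsets(cfg, 1, "Long")$onset_E1)
  expect_lt(abs(mean(e1) - 100), 3 * se)
})

test_that("noise-free rendering reproduces the template at the planted onset", {
  cfg <- sim_config(n_participants = 1, trials_per_condition = 1,
                    noise_sd = 0, n_channels = 8)
  topo <- make_topographies(6, 8, seed = 2)
  truth <- data.frame(participant = 1, condition = "Long",
                      sequence_label = "A",
                      onset_E1 = 150, onset_C1 = 300, onset_R1 = 450,
                      onset_E2 = 1350, onset_C2 = 1500, onset_R2 = 1650,
                      rt1 = 550, rt2 = 550, correct1 = TRUE, correct2 = TRUE)
  r <- render_epochs(truth, topo, cfg, task = 1)
  x <- r$epochs$data[1, , ]
  # correlation of the E1 channel pattern with the topography is 1 at onset
  c0 <- r$epochs$stim_sample[1] + round(150 * cfg$fs / 1000)
  expect_equal(abs(cor(x[, c0], topo[, 1])), 1, tolerance = 1e-10)
  # energy is confined to event windows
  w <- dualseq:::ms_to_samples(cfg$event_width_ms, cfg$fs)
  ev <- unlist(lapply(c(150, 300, 450), function(o) {
    c0 <- r$epochs$stim_sample[1] + round(o * cfg$fs / 1000)
    (c0 - w):(c0 + w)
  }))
  expect_equal(sum(x[, -ev]^2), 0, tolerance = 1e-20)
  # peak amplitude matches the configured scale
  expect_equal(max(abs(x)), cfg$amplitude * max(abs(topo[, 1:3])),
               tolerance = 0.05)
})

test_that("rendering with zero amplitude leaves pure centered noise", {
  cfg <- sim_config(n_participants = 1, trials_per_condition = 2,
                    amplitude = 0, seed = 9)
  ds <- generate_dataset(cfg)
  expect_lt(abs(mean(ds$task1$data)), 0.01)
  expect_equal(sd(as.vector(ds$task1$data)), cfg$noise_sd, tolerance = 0.01)
})

test_that("dataset generation is deterministic and bookkeeping is consistent", {
  cfg <- sim_config(n_participants = 2, trials_per_condition = 3, seed = 21)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$task1$data, d2$task1$data)
  expect_identical(d1$truth, d2$truth)

  expect_equal(n_trials(d1$task1), 2 * 3 * 2)  # participants x trials x conditions
  expect_equal(n_trials(d1$task2), n_trials(d1$task1))
  expect_true(all(d1$truth$sequence_label[d1$truth$condition == "Long"] == "A"))
  expect_true(all(d1$task1$stim_sample < d1$task1$rt_sample))
})

test_that("uniform strategy mixture yields near-uniform Short label frequencies", {
  mix <- matrix(1 / 6, 3, 6)
  cfg <- sim_config(n_participants = 3, trials_per_condition = 120,
                    strategy_mixture = mix, seed = 33)
  set.seed(33)
  labs <- replicate(720, sample_trial_onsets(cfg, sample(3, 1), "Short")$sequence_label)
  freq <- table(factor(labs, levels = SEQUENCE_LABELS)) / length(labs)
  se <- sqrt((1 / 6) * (5 / 6) / length(labs))
  expect_true(all(abs(freq - 1 / 6) < 3 * se))
})
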