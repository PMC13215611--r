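test_that("positional encoding follows the piecewise-linear contract", {
  p <- positional_encoding(10, 20, 30)
  expect_equal(p[10], 0)
  expect_equal(p[20], 1)
  expect_equal(p[15], 0.5)
  expect_true(all(p[1:10] == 0))
  expect_true(all(p[20:30] == 1))
  expect_true(all(diff(p) >= 0))
  expect_error(positional_encoding(20, 20, 30), "stim")
  expect_error(positional_encoding(25, 20, 30), "stim")
})

test_that("KL loss is exact on hand-computed cases and non-negative", {
  lab <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(kl_loss(lab, lab), 0)
  expect_equal(kl_loss(rbind(c(1, 0)), rbind(c(0.5, 0.5))), log(2),
               tolerance = 1e-12)
  expect_error(kl_loss(lab, rbind(c(1, 0))), "shape")
  set.seed(1)
  for (i in 1:20) {
    a <- matrix(rexp(12), 4); a <- a / rowSums(a)
    b <- matrix(rexp(12), 4); b <- b / rowSums(b)
    expect_gte(kl_loss(a, b), 0)
  }
})

tiny_config <- function(...) {
  model_config(n_channels = 4, fs = 250, n_classes = 3,
               spatial_features = 6, conv_features = 5,
               n_sequence_layers = 2, feature_dim = 8,
               dropout_rate = 0, seed = 42, ...)
}

test_that("temporal kernels round to 3 and 9 samples at 250 Hz", {
  cfg <- model_config(n_channels = 8, fs = 250)
  expect_equal(cfg$kernel_samples, c(3L, 9L))
})

test_that("forward pass yields normalized, deterministic, causal outputs", {
  cfg <- tiny_config()
  mod <- build_model(cfg)
  set.seed(2)
  t_len <- 40
  x <- matrix(rnorm(t_len * 4), t_len, 4)
  pos <- positional_encoding(5, 35, t_len)
  f1 <- dualseq:::forward_pass(mod$par, cfg, x, 1, pos, task = 1)
  f2 <- dualseq:::forward_pass(mod$par, cfg, x, 1, pos, task = 1)
  expect_equal(dim(f1$probs), c(t_len, 3))
  expect_equal(rowSums(f1$probs), rep(1, t_len), tolerance = 1e-6)
  expect_identical(f1$probs, f2$probs)
  # the two task heads share the encoder but differ
  f_t2 <- dualseq:::forward_pass(mod$par, cfg, x, 1, pos, task = 2)
  expect_identical(f1$embedding, f_t2$embedding)
  expect_false(identical(f1$probs, f_t2$probs))

  # causality: changing the future never changes past outputs
  x_trunc <- x
  x_trunc[26:t_len, ] <- 0
  f3 <- dualseq:::forward_pass(mod$par, cfg, x_trunc, 1, pos, task = 1)
  expect_equal(f1$probs[1:25, ], f3$probs[1:25, ], tolerance = 1e-6)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config()
  mod <- build_model(cfg)
  set.seed(3)
  b_sz <- 2; t_len <- 12
  x <- matrix(rnorm(t_len * b_sz * 4), t_len * b_sz, 4)
  pos <- runif(t_len * b_sz)
  lab <- matrix(rexp(t_len * b_sz * 3), t_len * b_sz, 3)
  lab <- lab / rowSums(lab)
  fwd <- dualseq:::forward_pass(mod$par, cfg, x, b_sz, pos, task = 1,
                                keep_cache = TRUE)
  dlogits <- (fwd$probs - lab) / nrow(lab)
  gr <- dualseq:::backward_pass(mod$par, cfg, fwd, dlogits, b_sz, task = 1)
  loss_fn <- function(par) {
    f <- dualseq:::forward_pass(par, cfg, x, b_sz, pos, task = 1)
    kl_loss(lab, f$probs)
  }
  eps <- 1e-6
  set.seed(4)
  for (nm in names(gr)) {
    for (rep_i in 1:2) {
      i <- sample(length(gr[[nm]]), 1)
      p_hi <- mod$par; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- mod$par; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      num <- (loss_fn(p_hi) - loss_fn(p_lo)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

# a tiny trainable problem: one strong event per class at fixed positions
tiny_trainset <- function(n = 24, t_len = 60, seed = 5) {
  set.seed(seed)
  data <- array(rnorm(n * 4 * t_len, sd = 0.3), dim = c(n, 4, t_len))
  lab <- matrix(0, t_len, 3)
  lab[20, 1] <- 1
  lab[40, 2] <- 1
  lab[-c(20, 40), 3] <- 1
  lab[, 3] <- 1 - lab[, 1] - lab[, 2]
  for (i in seq_len(n)) {
    data[i, 1, 16:24] <- data[i, 1, 16:24] + 2
    data[i, 2, 36:44] <- data[i, 2, 36:44] + 2
  }
  ep <- epoch_set(data, 250, stim_sample = rep(5, n), rt_sample = rep(55, n),
                  pre_pad_ms = 16, post_pad_ms = 16,
                  metadata = data.frame(trial = 1:n,
                                        participant = rep(1:4, each = n / 4),
                                        condition = "Long"))
  list(epochs = ep, labels = replicate(n, lab, simplify = FALSE))
}

test_that("training reduces loss, stops early and keeps the best weights", {
  ts <- tiny_trainset()
  cfg <- tiny_config()
  mod <- build_model(cfg)
  trained <- train_model(mod, ts$epochs, ts$epochs, ts$labels, ts$labels,
                         train_participants = 1:3, val_participants = 4,
                         lr = 5e-3, max_epochs = 40, batch_size = 8,
                         patience = 3, seed = 1)
  h <- trained$history
  expect_gt(nrow(h), 3)
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_equal(trained$best_epoch, which.min(h$val_loss))
  # patience: training never continues more than 3 epochs past the best
  expect_lte(nrow(h) - trained$best_epoch, 3)
  # reproducibility of the full training trajectory
  trained2 <- train_model(build_model(cfg), ts$epochs, ts$epochs,
                          ts$labels, ts$labels, 1:3, 4,
                          lr = 5e-3, max_epochs = 40, batch_size = 8,
                          patience = 3, seed = 1)
  expect_equal(trained$history, trained2$history, tolerance = 1e-12)
})

test_that("inference locates planted events and returns embeddings", {
  ts <- tiny_trainset(n = 32)
  cfg <- tiny_config()
  mod <- build_model(cfg)
  trained <- train_model(mod, ts$epochs, ts$epochs, ts$labels, ts$labels,
                         1:3, 4, lr = 5e-3, max_epochs = 60,
                         batch_size = 8, patience = 5, seed = 2)
  inf <- infer(trained, ts$epochs, task = 1)
  expect_length(inf$traces, 32)
  tr <- inf$traces[[1]]
  expect_equal(rowSums(tr), rep(1, nrow(tr)), tolerance = 1e-6)
  expect_equal(dim(inf$embeddings[[1]]), c(60, cfg$feature_dim))
  # the learned peaks sit near the planted label positions (within 3 samples)
  pk1 <- vapply(inf$traces, function(m) which.max(m[, 1]), 0L)
  pk2 <- vapply(inf$traces, function(m) which.max(m[, 2]), 0L)
  expect_lte(median(abs(pk1 - 20)), 3)
  expect_lte(median(abs(pk2 - 40)), 3)

  wrong <- ts$epochs
  wrong$data <- wrong$data[, 1:3, , drop = FALSE]
  expect_error(infer(trained, wrong), "channel-count mismatch")
})
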