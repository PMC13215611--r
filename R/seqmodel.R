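#' Sequence-model configuration
#'
#' Architecture hyperparameters of the causal spatiotemporal sequence
#' labeler: a per-timestep linear channel mix, temporal dropout, two
#' parallel causal temporal convolutions at a short and a long time scale,
#' an appended relative positional feature, a stack of causal gated
#' state-space sequence layers shared across tasks, and one linear softmax
#' head per task.
#'
#' @param n_channels input channel count.
#' @param fs sampling rate (Hz); temporal kernels are specified in ms and
#'   rounded to samples here.
#' @param n_classes classes per task head (K operations + Negative).
#' @param spatial_features width of the spatial (pointwise) mix.
#' @param conv_features features per temporal convolution branch.
#' @param temporal_kernel_ms the two temporal scales (ms).
#' @param n_sequence_layers stacked causal sequence-mixing layers.
#' @param feature_dim latent feature dimension of the sequence stack (the
#'   embedding dimension).
#' @param dropout_rate temporal dropout probability (whole timesteps zeroed
#'   during training).
#' @param seed integer seed for weight initialization.
#'
#' @return list of class `model_config`. The `sequence_layer` field records
#'   the causal layer implementation in use.
#' @export
model_config <- function(n_channels, fs = 250, n_classes = 4,
                         spatial_features = 32, conv_features = 32,
                         temporal_kernel_ms = c(12, 36),
                         n_sequence_layers = 5, feature_dim = 64,
                         dropout_rate = 0.1, seed = 1L) {
  kernels <- pmax(1L, as.integer(round(temporal_kernel_ms * fs / 1000)))
  stopifnot(n_sequence_layers >= 1, n_channels >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            length(kernels) == 2)
  structure(list(n_channels = n_channels, fs = fs, n_classes = n_classes,
                 spatial_features = spatial_features,
                 conv_features = conv_features,
                 temporal_kernel_ms = temporal_kernel_ms,
                 kernel_samples = kernels,
                 n_sequence_layers = n_sequence_layers,
                 feature_dim = feature_dim,
                 dropout_rate = dropout_rate,
                 sequence_layer = "gated diagonal state-space scan",
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Relative positional encoding
#'
#' A unit-interval series that is 0 until stimulus onset, increases linearly
#' from 0 to 1 between stimulus onset and RT, and remains at 1 thereafter,
#' encouraging the model to use relative rather than absolute time.
#'
#' @param stim_sample,rt_sample stimulus and RT samples (1-based).
#' @param n_samples series length.
#' @return numeric vector of length `n_samples` in [0, 1].
#' @export
positional_encoding <- function(stim_sample, rt_sample, n_samples) {
  if (rt_sample <= stim_sample) stop("need stim_sample < rt_sample")
  if (rt_sample > n_samples) stop("rt_sample beyond series")
  t <- seq_len(n_samples)
  p <- (t - stim_sample) / (rt_sample - stim_sample)
  pmin(pmax(p, 0), 1)
}

#' Build an untrained sequence model
#'
#' Initializes all weights (scaled Gaussian, deterministic given the config
#' seed). The per-feature decay gates of the sequence layers are initialized
#' to span slow and fast time constants.
#'
#' @param config a [model_config()].
#' @return list of class `seq_model` with `par` (named parameter list) and
#'   `config`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  gmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)),
                                  nr, nc)
  fs_ <- config$spatial_features
  fc <- config$conv_features
  f <- config$feature_dim
  k1 <- config$kernel_samples[1]
  k2 <- config$kernel_samples[2]
  par <- list(
    w_s = gmat(config$n_channels, fs_), b_s = numeric(fs_),
    c1_w = array(stats::rnorm(k1 * fs_ * fc, sd = 1 / sqrt(k1 * fs_)),
                 dim = c(k1, fs_, fc)),
    c1_b = numeric(fc),
    c2_w = array(stats::rnorm(k2 * fs_ * fc, sd = 1 / sqrt(k2 * fs_)),
                 dim = c(k2, fs_, fc)),
    c2_b = numeric(fc))
  d_in <- 2 * fc + 1
  for (l in seq_len(config$n_sequence_layers)) {
    din_l <- if (l == 1) d_in else f
    alpha0 <- seq(0.3, 0.95, length.out = f)
    par[[paste0("l", l, "_win")]] <- gmat(din_l, f)
    par[[paste0("l", l, "_bin")]] <- numeric(f)
    par[[paste0("l", l, "_a")]] <- log(alpha0 / (1 - alpha0))
    par[[paste0("l", l, "_wout")]] <- gmat(f, f)
    par[[paste0("l", l, "_bout")]] <- numeric(f)
  }
  par$h1_w <- gmat(f, config$n_classes); par$h1_b <- numeric(config$n_classes)
  par$h2_w <- gmat(f, config$n_classes); par$h2_b <- numeric(config$n_classes)
  structure(list(par = par, config = config), class = "seq_model")
}

#' @export
print.seq_model <- function(x, ...) {
  npar <- sum(vapply(x$par, length, 0L))
  cat(sprintf("<seq_model> %d channels -> %d classes x 2 tasks, %d parameters\n",
              x$config$n_channels, x$config$n_classes, npar))
  cat(sprintf("  %d x %s layers, kernels %s samples, F = %d\n",
              x$config$n_sequence_layers, x$config$sequence_layer,
              paste(x$config$kernel_samples, collapse = "/"),
              x$config$feature_dim))
  invisible(x)
}

add_bias <- function(m, b) sweep(m, 2, b, "+")

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# shift time-major (T*B) x F matrix down by `s` timesteps (zeros enter)
shift_down <- function(m, s, b_sz) {
  if (s == 0) return(m)
  tb <- nrow(m)
  out <- matrix(0, tb, ncol(m))
  out[(s * b_sz + 1):tb, ] <- m[1:(tb - s * b_sz), , drop = FALSE]
  out
}

shift_up <- function(m, s, b_sz) {
  if (s == 0) return(m)
  tb <- nrow(m)
  out <- matrix(0, tb, ncol(m))
  out[1:(tb - s * b_sz), ] <- m[(s * b_sz + 1):tb, , drop = FALSE]
  out
}

causal_conv_fwd <- function(h, w_arr, b, b_sz) {
  k <- dim(w_arr)[1]
  out <- matrix(0, nrow(h), dim(w_arr)[3])
  for (i in seq_len(k)) {
    out <- out + shift_down(h, i - 1L, b_sz) %*% w_arr[i, , ]
  }
  add_bias(out, b)
}

# Forward pass for one task over a time-major batch.
# X: (T*B) x C; pos: length T*B; drop_mask: length T*B multiplier or NULL.
forward_pass <- function(par, cfg, x, b_sz, pos, task,
                         drop_mask = NULL, keep_cache = FALSE) {
  h0 <- add_bias(x %*% par$w_s, par$b_s)
  if (!is.null(drop_mask)) h0 <- h0 * drop_mask
  c1_pre <- causal_conv_fwd(h0, par$c1_w, par$c1_b, b_sz)
  c2_pre <- causal_conv_fwd(h0, par$c2_w, par$c2_b, b_sz)
  z <- cbind(pmax(c1_pre, 0), pmax(c2_pre, 0), pos)
  layers <- vector("list", cfg$n_sequence_layers)
  for (l in seq_len(cfg$n_sequence_layers)) {
    w_in <- par[[paste0("l", l, "_win")]]
    alpha <- 1 / (1 + exp(-par[[paste0("l", l, "_a")]]))
    u <- tanh(add_bias(z %*% w_in, par[[paste0("l", l, "_bin")]]))
    h <- scan_forward_cpp(u, alpha, b_sz)
    y <- add_bias(h %*% par[[paste0("l", l, "_wout")]],
                  par[[paste0("l", l, "_bout")]])
    res <- ncol(z) == ncol(y)
    if (res) y <- y + z
    if (keep_cache) layers[[l]] <- list(z = z, u = u, h = h,
                                        alpha = alpha, res = res)
    z <- y
  }
  hw <- if (task == 1) par$h1_w else par$h2_w
  hb <- if (task == 1) par$h1_b else par$h2_b
  logits <- add_bias(z %*% hw, hb)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, embedding = z)
  if (keep_cache) {
    out$cache <- list(x = x, h0 = h0, c1_pre = c1_pre, c2_pre = c2_pre,
                      pos = pos, layers = layers, drop_mask = drop_mask)
  }
  out
}

# Backward pass; returns gradient list matching par's names (task head only
# for the given task). dlogits = (probs - labels) * weight per row.
backward_pass <- function(par, cfg, fwd, dlogits, b_sz, task) {
  grad <- list()
  cache <- fwd$cache
  z_top <- fwd$embedding
  hw_name <- if (task == 1) "h1_w" else "h2_w"
  hb_name <- if (task == 1) "h1_b" else "h2_b"
  grad[[hw_name]] <- crossprod(z_top, dlogits)
  grad[[hb_name]] <- colSums(dlogits)
  dz <- dlogits %*% t(par[[hw_name]])
  for (l in rev(seq_len(cfg$n_sequence_layers))) {
    lc <- cache$layers[[l]]
    dy <- dz
    grad[[paste0("l", l, "_wout")]] <- crossprod(lc$h, dy)
    grad[[paste0("l", l, "_bout")]] <- colSums(dy)
    dh <- dy %*% t(par[[paste0("l", l, "_wout")]])
    sb <- scan_backward_cpp(dh, lc$h, lc$u, lc$alpha, b_sz)
    du_pre <- sb$dU * (1 - lc$u^2)
    dalpha <- as.numeric(sb$dalpha)
    grad[[paste0("l", l, "_a")]] <- dalpha * lc$alpha * (1 - lc$alpha)
    grad[[paste0("l", l, "_win")]] <- crossprod(lc$z, du_pre)
    grad[[paste0("l", l, "_bin")]] <- colSums(du_pre)
    dz <- du_pre %*% t(par[[paste0("l", l, "_win")]])
    if (lc$res) dz <- dz + dy
  }
  fc <- cfg$conv_features
  dc1a <- dz[, seq_len(fc), drop = FALSE]
  dc2a <- dz[, fc + seq_len(fc), drop = FALSE]
  dc1 <- dc1a * (cache$c1_pre > 0)
  dc2 <- dc2a * (cache$c2_pre > 0)
  dh0 <- matrix(0, nrow(dz), cfg$spatial_features)
  for (br in list(list(w = "c1_w", b = "c1_b", d = dc1),
                  list(w = "c2_w", b = "c2_b", d = dc2))) {
    w_arr <- par[[br$w]]
    k <- dim(w_arr)[1]
    gw <- array(0, dim = dim(w_arr))
    for (i in seq_len(k)) {
      hs <- shift_down(cache$h0, i - 1L, b_sz)
      gw[i, , ] <- crossprod(hs, br$d)
      dh0 <- dh0 + shift_up(br$d %*% t(w_arr[i, , ]), i - 1L, b_sz)
    }
    grad[[br$w]] <- gw
    grad[[br$b]] <- colSums(br$d)
  }
  if (!is.null(cache$drop_mask)) dh0 <- dh0 * cache$drop_mask
  grad$w_s <- crossprod(cache$x, dh0)
  grad$b_s <- colSums(dh0)
  grad
}

#' Kullback-Leibler training loss
#'
#' Mean over timesteps of sum_c label_c log(label_c / pred_c), with
#' 0 log 0 = 0 and predictions floored at 1e-9. Zero when the prediction
#' equals the label; always non-negative.
#'
#' @param label T x C soft-label matrix (rows sum to 1).
#' @param pred T x C predicted probability matrix.
#' @return scalar loss.
#' @export
kl_loss <- function(label, pred) {
  if (!all(dim(label) == dim(pred))) stop("label/pred shape mismatch")
  p <- pmax(pred, 1e-9)
  terms <- ifelse(label > 0, label * (log(label) - log(p)), 0)
  mean(rowSums(terms))
}

nadam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

nadam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grad)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    m_hat <- state$m[[nm]] / bc1
    v_hat <- state$v[[nm]] / bc2
    m_bar <- beta1 * m_hat + ((1 - beta1) / bc1) * g    # Nesterov lookahead
    par[[nm]] <- par[[nm]] - lr * m_bar / (sqrt(v_hat) + eps)
  }
  list(par = par, state = state)
}

# Assemble a time-major batch from trial windows.
# trials: list of list(x = C x n_samples matrix source, window start/end,
# stim, rt, label = full-length label matrix or NULL)
make_batch <- function(items, n_classes) {
  b_sz <- length(items)
  t_max <- max(vapply(items, function(it) it$end - it$start + 1L, 0L))
  n_ch <- nrow(items[[1]]$x)
  x <- matrix(0, t_max * b_sz, n_ch)
  pos <- numeric(t_max * b_sz)
  lab <- matrix(0, t_max * b_sz, n_classes)
  lab[, n_classes] <- 1
  mask <- logical(t_max * b_sz)
  for (b in seq_len(b_sz)) {
    it <- items[[b]]
    len <- it$end - it$start + 1L
    rows <- (seq_len(len) - 1L) * b_sz + b
    x[rows, ] <- t(it$x[, it$start:it$end, drop = FALSE])
    stim_rel <- it$stim - it$start + 1L
    rt_rel <- it$rt - it$start + 1L
    pos[rows] <- positional_encoding(stim_rel, rt_rel, len)
    if (!is.null(it$label)) {
      lab[rows, ] <- it$label[it$start:it$end, , drop = FALSE]
    }
    mask[rows] <- TRUE
  }
  list(x = x, pos = pos, label = lab, mask = mask, t_len = t_max, b_sz = b_sz)
}

#' Train the sequence labeler on soft onset labels
#'
#' Joint training on both tasks with a shared encoder and task-specific
#' heads: each minibatch of one task's epochs is jitter-cropped, passed
#' through the encoder and that task's head, and scored with the KL loss
#' against the per-timestep soft labels; the per-epoch loss is the sum over
#' both tasks. Optimization uses NAdam (adaptive moments with Nesterov
#' lookahead). Training stops early when validation loss has not decreased
#' for `patience` consecutive epochs, and the weights of the best validation
#' epoch are returned.
#'
#' @param model a [build_model()] result.
#' @param epochs1,epochs2 normalized `epoch_set`s (Task 1 / Task 2 locked,
#'   training condition only, typically MAD z-scored Long trials).
#' @param labels1,labels2 per-trial full-length label tensors from
#'   [build_label_tensors()]; trials absent from the decomposition carry
#'   NULL and are skipped.
#' @param train_participants,val_participants participant id vectors from
#'   [split_by_participant()].
#' @param lr learning rate (default 5e-5).
#' @param max_epochs maximum training epochs.
#' @param batch_size trials per minibatch.
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed for jitter, dropout and batch order.
#' @param verbose print per-epoch losses.
#'
#' @return the model with trained parameters, plus `history` (data.frame of
#'   per-epoch train/validation loss) and `best_epoch`.
#' @export
train_model <- function(model, epochs1, epochs2, labels1, labels2,
                        train_participants, val_participants,
                        lr = 5e-5, max_epochs = 50, batch_size = 16,
                        patience = 3, seed = 1L, verbose = FALSE) {
  cfg <- model$config
  stopifnot(dim(epochs1$data)[2] == cfg$n_channels)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  task_data <- list(list(ep = epochs1, lab = labels1, task = 1),
                    list(ep = epochs2, lab = labels2, task = 2))
  has_lab <- function(td) !vapply(td$lab, is.null, TRUE)
  tr_idx <- lapply(task_data, function(td) {
    which(td$ep$metadata$participant %in% train_participants & has_lab(td))
  })
  va_idx <- lapply(task_data, function(td) {
    which(td$ep$metadata$participant %in% val_participants & has_lab(td))
  })
  if (any(vapply(tr_idx, length, 0L) == 0)) stop("no training trials")

  item_for <- function(td, i, jitter) {
    ep <- td$ep
    pre <- ms_to_samples(ep$pre_pad_ms, ep$fs)
    post <- ms_to_samples(ep$post_pad_ms, ep$fs)
    n_s <- dim(ep$data)[3]
    if (jitter) {
      wnd <- jitter_crop(ep$stim_sample[i], ep$rt_sample[i], pre, post, n_s)
    } else {
      wnd <- list(start = max(1L, ep$stim_sample[i] - pre),
                  end = min(n_s, ep$rt_sample[i] + post))
    }
    list(x = ep$data[i, , ], start = wnd$start, end = wnd$end,
         stim = ep$stim_sample[i], rt = ep$rt_sample[i],
         label = td$lab[[i]])
  }

  eval_loss <- function(par) {
    total <- 0
    for (ti in 1:2) {
      td <- task_data[[ti]]
      idx <- va_idx[[ti]]
      for (start in seq(1, length(idx), by = batch_size)) {
        ids <- idx[start:min(start + batch_size - 1, length(idx))]
        bt <- make_batch(lapply(ids, function(i) item_for(td, i, FALSE)),
                         cfg$n_classes)
        fw <- forward_pass(par, cfg, bt$x, bt$b_sz, bt$pos, td$task)
        total <- total + kl_loss(bt$label[bt$mask, , drop = FALSE],
                                 fw$probs[bt$mask, , drop = FALSE]) *
          sum(bt$mask)
      }
    }
    total / sum(vapply(1:2, function(ti) {
      td <- task_data[[ti]]
      sum(vapply(va_idx[[ti]], function(i) {
        pre <- ms_to_samples(td$ep$pre_pad_ms, td$ep$fs)
        post <- ms_to_samples(td$ep$post_pad_ms, td$ep$fs)
        min(dim(td$ep$data)[3], td$ep$rt_sample[i] + post) -
          max(1L, td$ep$stim_sample[i] - pre) + 1L
      }, 0L))
    }, 0))
  }

  par <- model$par
  state <- nadam_init(par)
  best <- list(loss = Inf, par = par, epoch = 0L)
  bad <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (ep_i in seq_len(max_epochs)) {
    tr_loss <- 0; tr_n <- 0
    for (ti in 1:2) {
      td <- task_data[[ti]]
      idx <- sample(tr_idx[[ti]])
      for (start in seq(1, length(idx), by = batch_size)) {
        ids <- idx[start:min(start + batch_size - 1, length(idx))]
        bt <- make_batch(lapply(ids, function(i) item_for(td, i, TRUE)),
                         cfg$n_classes)
        drop_mask <- NULL
        if (cfg$dropout_rate > 0) {
          keep <- stats::runif(bt$t_len * bt$b_sz) >= cfg$dropout_rate
          drop_mask <- ifelse(keep, 1 / (1 - cfg$dropout_rate), 0)
        }
        fw <- forward_pass(par, cfg, bt$x, bt$b_sz, bt$pos, td$task,
                           drop_mask = drop_mask, keep_cache = TRUE)
        n_m <- sum(bt$mask)
        loss <- kl_loss(bt$label[bt$mask, , drop = FALSE],
                        fw$probs[bt$mask, , drop = FALSE])
        if (!is.finite(loss)) stop("training loss diverged (NaN/Inf)")
        dlogits <- (fw$probs - bt$label) * (bt$mask / n_m)
        grad <- backward_pass(par, cfg, fw, dlogits, bt$b_sz, td$task)
        upd <- nadam_step(par, grad, state, lr)
        par <- upd$par; state <- upd$state
        tr_loss <- tr_loss + loss * n_m; tr_n <- tr_n + n_m
      }
    }
    vl <- eval_loss(par)
    history <- rbind(history, data.frame(epoch = ep_i,
                                         train_loss = tr_loss / tr_n,
                                         val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", ep_i,
                      tr_loss / tr_n, vl))
    }
    if (vl < best$loss) {
      best <- list(loss = vl, par = par, epoch = ep_i)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  model$par <- best$par
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

#' Inference: probability traces and embeddings
#'
#' Runs the trained model (no jitter, no dropout) over the full padded
#' window of every trial. Returns per-trial per-timestep class probabilities
#' for the requested task head and the latent embedding series taken after
#' the sequence-layer stack, before the heads.
#'
#' @param model a trained `seq_model`.
#' @param epochs a normalized `epoch_set` (any condition).
#' @param task which task head to use (1 or 2).
#' @param batch_size trials per inference batch.
#' @return list with `traces` (per-trial T x n_classes matrices, rows sum to
#'   1) and `embeddings` (per-trial T x F matrices).
#' @export
infer <- function(model, epochs, task = 1, batch_size = 32) {
  cfg <- model$config
  if (dim(epochs$data)[2] != cfg$n_channels) {
    stop("channel-count mismatch: model expects ", cfg$n_channels)
  }
  n <- n_trials(epochs)
  n_s <- dim(epochs$data)[3]
  traces <- vector("list", n)
  embeddings <- vector("list", n)
  cls <- if (cfg$n_classes == 4) c("E", "C", "R", "Negative") else NULL
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1, n)
    b_sz <- length(ids)
    x <- matrix(0, n_s * b_sz, cfg$n_channels)
    pos <- numeric(n_s * b_sz)
    for (b in seq_along(ids)) {
      i <- ids[b]
      rows <- (seq_len(n_s) - 1L) * b_sz + b
      x[rows, ] <- t(epochs$data[i, , ])
      pos[rows] <- positional_encoding(epochs$stim_sample[i],
                                       epochs$rt_sample[i], n_s)
    }
    fw <- forward_pass(model$par, cfg, x, b_sz, pos, task)
    for (b in seq_along(ids)) {
      rows <- (seq_len(n_s) - 1L) * b_sz + b
      tr <- fw$probs[rows, , drop = FALSE]
      if (!is.null(cls)) colnames(tr) <- cls
      traces[[ids[b]]] <- tr
      embeddings[[ids[b]]] <- fw$embedding[rows, , drop = FALSE]
    }
  }
  list(traces = traces, embeddings = embeddings)
}
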