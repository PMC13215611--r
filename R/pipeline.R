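#' Expected onset times from EM posteriors
#'
#' Posterior-mean onset per event, in ms relative to the task stimulus
#' (sample 1 of the cropped decomposition window is the stimulus).
#'
#' @param gammas per-trial T x K onset posteriors.
#' @param fs sampling rate (Hz).
#' @return trials x K matrix of onset times (ms).
#' @export
em_expected_onsets <- function(gammas, fs) {
  t(vapply(gammas, function(g) {
    (colSums(g * seq_len(nrow(g))) - 1) / fs * 1000
  }, numeric(ncol(gammas[[1]]))))
}

#' Peak-probability onset estimates from model traces
#'
#' Argmax of each operation's probability trace, in ms relative to the
#' stimulus sample of the epoch.
#'
#' @param traces per-trial T x n_classes probability matrices.
#' @param stim_sample per-trial stimulus samples.
#' @param fs sampling rate (Hz).
#' @param operations operation columns to locate.
#' @return trials x length(operations) matrix of onset times (ms).
#' @export
trace_peak_onsets <- function(traces, stim_sample, fs,
                              operations = c("E", "C", "R")) {
  if (length(stim_sample) == 1) stim_sample <- rep(stim_sample, length(traces))
  t(vapply(seq_along(traces), function(i) {
    pk <- vapply(operations, function(op) which.max(traces[[i]][, op]), 0L)
    (pk - stim_sample[i]) / fs * 1000
  }, numeric(length(operations))))
}

#' Restrict traces to each trial's own analysis window
#'
#' Zeroes operation probabilities outside [stimulus - pre-pad, RT +
#' post-pad]. Inference runs over the full padded storage array for
#' batching; samples beyond a trial's own window were never part of the
#' trial and carry no usable onset evidence.
#'
#' @param traces per-trial probability matrices from [infer()].
#' @param epochs the `epoch_set` they were computed on.
#' @return the cropped trace list.
#' @export
crop_traces <- function(traces, epochs) {
  pre <- ms_to_samples(epochs$pre_pad_ms, epochs$fs)
  post <- ms_to_samples(epochs$post_pad_ms, epochs$fs)
  n_s <- dim(epochs$data)[3]
  lapply(seq_along(traces), function(i) {
    m <- traces[[i]]
    lo <- max(1L, epochs$stim_sample[i] - pre)
    hi <- min(n_s, epochs$rt_sample[i] + post)
    out <- m
    k <- ncol(m) - 1L
    out[-(lo:hi), seq_len(k)] <- 0
    out
  })
}

#' Ground-truth onsets for one task
#'
#' Onset times of a task's three operations relative to that task's own
#' stimulus, in ms, for comparison with decomposition or model estimates.
#'
#' @param truth truth table from [generate_dataset()].
#' @param task 1 or 2.
#' @param config the [sim_config()] used to generate the data.
#' @return trials x 3 matrix (E, C, R onsets in ms).
#' @export
truth_onsets_task <- function(truth, task, config) {
  soa <- ifelse(truth$condition == "Short", config$soa_short_ms,
                config$soa_long_ms)
  if (task == 1) {
    as.matrix(truth[c("onset_E1", "onset_C1", "onset_R1")])
  } else {
    as.matrix(truth[c("onset_E2", "onset_C2", "onset_R2")]) - soa
  }
}

#' Run the full dual-task decoding pipeline on a dataset
#'
#' Orchestrates every stage on a (typically synthetic) dataset: participant
#' split, decomposition preprocessing, spatial basis from the training
#' split, event-width tuning and cumulative EM fit on Long-condition data
#' per task, soft-label construction, MAD z-scoring, sequence-model
#' training on Long trials, inference over all trials, embedding extraction
#' and cross-condition similarity, sequence-posterior decoding, and the
#' multiple-imputation behavioral analysis of Short-condition Task 1 RT and
#' accuracy.
#'
#' @param dataset a [generate_dataset()] result (or a compatible list).
#' @param seed integer seed for all stochastic stages.
#' @param widths_ms candidate event widths for tuning; set `tune = FALSE`
#'   to skip tuning and use `fixed_width_ms`.
#' @param tune logical; run event-width tuning.
#' @param fixed_width_ms width used when `tune = FALSE`.
#' @param fixed_k event count used when `tune = FALSE` (NULL runs the
#'   cumulative fit instead).
#' @param tune_max_trials Long trials per task used during width tuning
#'   (the final fit always uses all Long trials).
#' @param k_max maximum event count for cumulative fitting.
#' @param lr,max_epochs,batch_size,dropout_rate training hyperparameters.
#' @param spatial_features,conv_features,feature_dim model dimensions.
#' @param finetune_epochs extra training epochs at `lr / 5` after the main
#'   run (0 disables); sharpens per-timestep probabilities.
#' @param n_decode posterior draws per trial.
#' @param m_imputations imputations for the behavioral stage.
#' @param engine behavioral model engine ("lmm" or "fixed").
#' @param n_iter_sim,n_samp_sim embedding-similarity resampling sizes.
#' @param verbose print progress.
#'
#' @return list with components `split`, per-task `decomp` (basis, width,
#'   fit, gammas, label tensors, trial index), `model`, `inference` (traces
#'   and embeddings per task), `records`, `similarity`, `posteriors`
#'   (Short), `posteriors_long`, `behavior_fits`, `pooled_rt`,
#'   `contrasts_rt`, `pooled_acc`, and bookkeeping.
#' @export
run_pipeline <- function(dataset, seed = 1L,
                         widths_ms = seq(20, 60, by = 5), tune = TRUE,
                         fixed_width_ms = 50, fixed_k = NULL,
                         tune_max_trials = 120,
                         k_max = 6, lr = 2e-3, max_epochs = 60,
                         finetune_epochs = 30,
                         batch_size = 16, dropout_rate = 0.1,
                         spatial_features = 48, conv_features = 48,
                         feature_dim = 96,
                         n_decode = 1000, m_imputations = 100,
                         engine = "lmm", n_iter_sim = 1000,
                         n_samp_sim = 1000, verbose = FALSE) {
  config <- dataset$config
  say <- function(...) if (verbose) message(sprintf(...))
  split <- split_by_participant(dataset$task1, 0.85, seed = seed)
  say("split: train %s | validation %s",
      paste(split$train, collapse = ","),
      paste(split$validation, collapse = ","))

  decomp <- list()
  for (task in 1:2) {
    ep <- dataset[[paste0("task", task)]]
    long_idx <- which(ep$metadata$condition == "Long")
    dset <- prepare_for_decomposition(subset_trials(ep, long_idx))
    is_train <- dset$metadata$participant %in% split$train
    basis <- fit_spatial_basis(
      structure(list(trials = dset$trials[is_train],
                     fs = dset$fs), class = "decomp_set"))
    comp <- project_epochs(basis, dset)
    comp_tune <- comp[seq_len(min(length(comp), tune_max_trials))]
    factory <- function(width_ms) {
      match_series(comp_tune, half_sine_template(width_ms, config$fs))
    }
    if (tune) {
      say("task %d: tuning event width over %s ms", task,
          paste(range(widths_ms), collapse = "-"))
      tuned <- tune_event_width(factory, widths_ms, fs = config$fs,
                                k_max = k_max)
      width <- tuned$width_ms
      profile <- tuned$profile
      k_stable <- tuned$fit$k_events
    } else {
      width <- fixed_width_ms
      profile <- NULL
      k_stable <- fixed_k
    }
    tpl <- half_sine_template(width, config$fs)
    matches <- match_series(comp, tpl)
    # final model at the chosen width: event count fixed to the stable K
    # from tuning (the tuned width "giving K events" defines the model)
    if (is.null(k_stable)) {
      fit <- cumulative_fit(matches, k_max = k_max,
                            min_gap = tpl$n_samples)
    } else {
      fit <- em_fit(matches, k_stable, min_gap = tpl$n_samples)
      fit$k_events <- k_stable
      fit$no_events <- FALSE
    }
    say("task %d: width %g ms -> %d events", task, width, fit$k_events)
    labels <- build_label_tensors(fit$gammas, dset)
    decomp[[task]] <- list(dset = dset, basis = basis, width_ms = width,
                           profile = profile, fit = fit,
                           gammas = fit$gammas, labels = labels,
                           trial_ids = dset$metadata$trial)
  }

  # full-length label list aligned with each task's epoch set
  label_list <- lapply(1:2, function(task) {
    ep <- dataset[[paste0("task", task)]]
    out <- vector("list", n_trials(ep))
    ids <- match(decomp[[task]]$trial_ids, ep$metadata$trial)
    out[ids] <- decomp[[task]]$labels
    out
  })

  norm1 <- norm_stats(subset_trials(dataset$task1,
                                    dataset$task1$metadata$condition == "Long" &
                                      dataset$task1$metadata$participant %in% split$train))
  norm2 <- norm_stats(subset_trials(dataset$task2,
                                    dataset$task2$metadata$condition == "Long" &
                                      dataset$task2$metadata$participant %in% split$train))
  z1 <- mad_zscore(dataset$task1, norm1)
  z2 <- mad_zscore(dataset$task2, norm2)

  if (decomp[[1]]$fit$k_events != decomp[[2]]$fit$k_events) {
    stop("event counts differ between tasks (",
         decomp[[1]]$fit$k_events, " vs ", decomp[[2]]$fit$k_events,
         "); the shared sequence model needs a common class count")
  }
  long1 <- which(z1$metadata$condition == "Long")
  long2 <- which(z2$metadata$condition == "Long")
  k_ev <- decomp[[1]]$fit$k_events
  cfg <- model_config(config$n_channels, fs = config$fs,
                      n_classes = k_ev + 1, dropout_rate = dropout_rate,
                      spatial_features = spatial_features,
                      conv_features = conv_features,
                      feature_dim = feature_dim, seed = seed)
  model <- build_model(cfg)
  say("training sequence model (%d classes/task)", cfg$n_classes)
  model <- train_model(model,
                       subset_trials(z1, long1), subset_trials(z2, long2),
                       label_list[[1]][long1], label_list[[2]][long2],
                       split$train, split$validation,
                       lr = lr, max_epochs = max_epochs,
                       batch_size = batch_size, seed = seed,
                       verbose = verbose)

  if (finetune_epochs > 0) {
    say("fine-tuning at lr %g", lr / 5)
    model <- train_model(model,
                         subset_trials(z1, long1), subset_trials(z2, long2),
                         label_list[[1]][long1], label_list[[2]][long2],
                         split$train, split$validation,
                         lr = lr / 5, max_epochs = finetune_epochs,
                         batch_size = batch_size, seed = seed + 7L,
                         verbose = verbose)
  }

  inf1 <- infer(model, z1, task = 1)
  inf2 <- infer(model, z2, task = 2)

  rec1 <- extract_operation_embeddings(inf1$traces, inf1$embeddings,
                                       z1$metadata, task = 1)
  rec2 <- extract_operation_embeddings(inf2$traces, inf2$embeddings,
                                       z2$metadata, task = 2)
  records <- rbind(rec1, rec2)
  # Long-condition records come from held-out participants only
  use <- records$condition == "Short" |
    (records$condition == "Long" &
       records$participant %in% split$validation)
  similarity <- similarity_resampling(records[use, ],
                                      n_iter = n_iter_sim,
                                      n_samp = n_samp_sim, seed = seed)

  ct1 <- crop_traces(inf1$traces, z1)
  ct2 <- crop_traces(inf2$traces, z2)
  short_idx <- which(z1$metadata$condition == "Short")
  posteriors <- decode_sequences(ct1[short_idx], ct2[short_idx],
                                 z1$stim_sample[short_idx],
                                 z2$stim_sample[short_idx],
                                 config$fs, config$soa_short_ms,
                                 n = n_decode, seed = seed)
  posteriors$trial <- z1$metadata$trial[short_idx]
  posteriors_long <- decode_sequences(ct1[long1], ct2[long1],
                                      z1$stim_sample[long1],
                                      z2$stim_sample[long1],
                                      config$fs, config$soa_long_ms,
                                      n = n_decode, seed = seed + 1L)
  posteriors_long$trial <- z1$metadata$trial[long1]

  beh_short <- dataset$behavior[match(posteriors$trial,
                                      dataset$behavior$trial), ]
  beh_short <- data.frame(participant = beh_short$participant,
                          rt_ms = beh_short$rt1_ms,
                          correct = beh_short$correct1)
  fits <- impute_and_fit(posteriors, beh_short, m = m_imputations,
                         engine = engine, seed = seed)
  pooled_rt <- pool_rubin(fits$rt$est, fits$rt$se)
  contrasts_rt <- pairwise_contrasts(fits$rt, fits$terms)
  pooled_acc <- if (!is.null(fits$acc)) {
    pool_rubin(fits$acc$est, fits$acc$se)
  } else NULL

  list(split = split, decomp = decomp, label_list = label_list,
       model = model, inference = list(inf1, inf2),
       records = records, similarity = similarity,
       posteriors = posteriors, posteriors_long = posteriors_long,
       behavior_fits = fits, pooled_rt = pooled_rt,
       contrasts_rt = contrasts_rt, pooled_acc = pooled_acc,
       norm = list(norm1, norm2), dataset = dataset)
}
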