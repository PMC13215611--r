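#' Simulation configuration for synthetic dual-task EEG
#'
#' Defines the generative conditions: two tasks of three operations each
#' (Encoding, Central, Response), operation onsets marked by brief
#' topographic half-sine events, gamma-distributed (shape 2) stage durations,
#' a Short (300 ms) and a Long (1200 ms) stimulus-onset asynchrony, and
#' per-participant mixtures over the six valid cross-task sequence strategies
#' in the Short condition. Behavior (RT, accuracy) depends on the sequence
#' through configurable shifts.
#'
#' @param n_participants number of simulated participants.
#' @param trials_per_condition trials per participant per SOA condition.
#' @param fs sampling rate (Hz).
#' @param n_channels number of channels (>= 2).
#' @param event_width_ms width of the half-sine event marking each onset.
#' @param stage_mean_ms list with elements `task1`, `task2`: mean durations
#'   (ms) of the three within-task stages (stimulus to E, E to C, C to R).
#' @param soa_short_ms,soa_long_ms stimulus-onset asynchronies (ms).
#' @param strategy_mixture `n_participants` x 6 matrix of Short-condition
#'   probabilities over sequence labels A-F (rows sum to 1), or NULL for the
#'   default heterogeneous mixtures (each participant prefers one label).
#' @param amplitude event peak amplitude (signal units).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param noise_ar AR(1) coefficient for temporally colored noise (0 = white).
#' @param motor_delay_ms mean gamma-distributed gap from the final Response
#'   onset to the recorded RT.
#' @param short_gap_mean_ms mean gap between consecutive onsets when Short
#'   condition onsets are laid out in the order of the drawn sequence label.
#' @param e2_delay_mean_ms mean sensory delay flooring the Task 2 Encoding
#'   onset after the Task 2 stimulus.
#' @param behavior_effects list with `rt1_shift_ms` and `acc1_logit`: named
#'   per-sequence (A-F) additive RT shifts (ms) and accuracy logit shifts.
#' @param acc_base_logit baseline correctness logit for both tasks.
#' @param seed integer seed controlling the whole dataset.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 6,
                       trials_per_condition = 120,
                       fs = 250,
                       n_channels = 32,
                       event_width_ms = 50,
                       stage_mean_ms = list(task1 = c(150, 150, 150),
                                            task2 = c(150, 150, 150)),
                       soa_short_ms = 300,
                       soa_long_ms = 1200,
                       strategy_mixture = NULL,
                       amplitude = 1,
                       noise_sd = 0.6,
                       noise_ar = 0,
                       motor_delay_ms = 50,
                       short_gap_mean_ms = 90,
                       e2_delay_mean_ms = 60,
                       behavior_effects = list(
                         rt1_shift_ms = c(A = 0, B = 15, C = 25,
                                          D = 50, E = 35, F = 45),
                         acc1_logit = c(A = 0, B = 0.5, C = 0.5,
                                        D = 0.7, E = 0.7, F = 0.7)),
                       acc_base_logit = 2,
                       seed = 1L) {
  if (is.null(strategy_mixture)) {
    strategy_mixture <- default_strategy_mixture(n_participants)
  }
  strategy_mixture <- as.matrix(strategy_mixture)
  cfg <- list(n_participants = n_participants,
              trials_per_condition = trials_per_condition,
              fs = fs, n_channels = n_channels,
              event_width_ms = event_width_ms,
              stage_mean_ms = stage_mean_ms,
              soa_short_ms = soa_short_ms, soa_long_ms = soa_long_ms,
              strategy_mixture = strategy_mixture,
              amplitude = amplitude, noise_sd = noise_sd,
              noise_ar = noise_ar,
              motor_delay_ms = motor_delay_ms,
              short_gap_mean_ms = short_gap_mean_ms,
              e2_delay_mean_ms = e2_delay_mean_ms,
              behavior_effects = behavior_effects,
              acc_base_logit = acc_base_logit,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$fs > 0, cfg$n_channels >= 2,
            cfg$event_width_ms > 0,
            all(unlist(cfg$stage_mean_ms) > 0),
            cfg$soa_short_ms > 0, cfg$soa_long_ms > 0,
            cfg$motor_delay_ms > 0, cfg$short_gap_mean_ms > 0,
            cfg$e2_delay_mean_ms > 0,
            nrow(cfg$strategy_mixture) == cfg$n_participants,
            ncol(cfg$strategy_mixture) == 6)
  if (any(cfg$strategy_mixture < 0) ||
      any(abs(rowSums(cfg$strategy_mixture) - 1) > 1e-8)) {
    stop("strategy_mixture rows must be probability vectors over A-F")
  }
  invisible(cfg)
}

# Heterogeneous but deterministic default: participant i puts half its mass
# on label ((i - 1) mod 6) + 1 and spreads the rest uniformly, emulating the
# marked inter-individual strategy differences seen in dual-task data.
default_strategy_mixture <- function(n_participants) {
  m <- matrix(0.1, n_participants, 6,
              dimnames = list(NULL, SEQUENCE_LABELS))
  for (i in seq_len(n_participants)) {
    m[i, ((i - 1) %% 6) + 1] <- 0.5
  }
  m
}

#' Generate distinguishable operation topographies
#'
#' Produces one unit-norm channel vector per operation with pairwise absolute
#' cosine similarity at most 0.3, so that the six operations are spatially
#' separable. Vectors start as random directions and are shrunk toward an
#' orthonormal frame just enough to satisfy the similarity bound.
#'
#' @param n_operations number of topographies (<= `n_channels`).
#' @param n_channels channel count.
#' @param seed integer seed (deterministic output).
#' @param max_abs_cos pairwise absolute cosine bound.
#'
#' @return `n_channels` x `n_operations` matrix of unit-norm columns.
#' @export
make_topographies <- function(n_operations, n_channels, seed = 1L,
                              max_abs_cos = 0.3) {
  if (n_operations > n_channels) {
    stop("cannot build ", n_operations, " separable topographies with only ",
         n_channels, " channels")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  g <- matrix(stats::rnorm(n_channels * n_operations), n_channels)
  v <- normalize_cols(g)
  q <- qr.Q(qr(g))[, seq_len(n_operations), drop = FALSE]
  # align signs so the blend does not cancel
  sgn <- sign(colSums(q * v)); sgn[sgn == 0] <- 1
  q <- sweep(q, 2, sgn, "*")
  w <- 0
  repeat {
    t_mat <- normalize_cols((1 - w) * v + w * q)
    cs <- crossprod(t_mat)
    diag(cs) <- 0
    if (max(abs(cs)) <= max_abs_cos) break
    w <- if (w == 0) 0.25 else min(1, w + 0.25)
  }
  t_mat
}

normalize_cols <- function(m) {
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

rgamma_stage <- function(n, mean_ms) {
  stats::rgamma(n, shape = 2, scale = mean_ms / 2)
}

#' Sample ground-truth onsets and behavior for one trial
#'
#' Long condition: the serial sequence A by construction; Task 1 onsets are
#' cumulative gamma (shape 2) stage durations resampled until Task 1 finishes
#' before the Task 2 stimulus; Task 2 onsets follow the same scheme offset by
#' the Long SOA. Short condition: a sequence label is drawn from the
#' participant's strategy mixture and the six onsets are laid out as
#' cumulative gamma gaps in the order dictated by the label (so the label's
#' ordering holds by construction); the Task 2 Encoding onset is floored at
#' SOA plus a sensory delay. RTs are the final Response onset of each task
#' plus a gamma motor delay, with the configured per-sequence RT shift added
#' to Task 1; correctness is Bernoulli with a per-sequence logit shift.
#'
#' Uses R's global RNG stream.
#'
#' @param config a [sim_config()].
#' @param participant participant index (row of the strategy mixture).
#' @param condition `"Short"` or `"Long"`.
#'
#' @return One-row data.frame of trial truth: participant, condition,
#'   sequence_label, onset_E1..onset_R2 (ms from the Task 1 stimulus),
#'   rt1 (ms from Task 1 stimulus), rt2 (ms from Task 2 stimulus),
#'   correct1, correct2.
#' @export
sample_trial_onsets <- function(config, participant, condition) {
  condition <- match.arg(condition, c("Short", "Long"))
  soa <- if (condition == "Short") config$soa_short_ms else config$soa_long_ms
  ops <- c("E1", "C1", "R1", "E2", "C2", "R2")
  onsets <- numeric(6)
  names(onsets) <- ops
  if (condition == "Long") {
    label <- "A"
    repeat {
      on1 <- cumsum(rgamma_stage(3, config$stage_mean_ms$task1))
      if (on1[3] < soa) break
    }
    on2 <- soa + cumsum(rgamma_stage(3, config$stage_mean_ms$task2))
    onsets[] <- c(on1, on2)
  } else {
    label <- sample(SEQUENCE_LABELS, 1,
                    prob = config$strategy_mixture[participant, ])
    order_ops <- sequence_orders()[[label]]
    t_cur <- rgamma_stage(1, config$stage_mean_ms$task1[1])
    onsets[order_ops[1]] <- t_cur  # always E1
    for (op in order_ops[-1]) {
      t_cur <- t_cur + rgamma_stage(1, config$short_gap_mean_ms)
      if (op == "E2") {
        t_cur <- max(t_cur, soa + rgamma_stage(1, config$e2_delay_mean_ms))
      }
      onsets[op] <- t_cur
    }
  }
  shift <- config$behavior_effects$rt1_shift_ms[label]
  rt1 <- onsets["R1"] +
    max(rgamma_stage(1, config$motor_delay_ms) + shift, 1)
  rt2 <- (onsets["R2"] - soa) + rgamma_stage(1, config$motor_delay_ms)
  p1 <- stats::plogis(config$acc_base_logit +
                        config$behavior_effects$acc1_logit[label])
  p2 <- stats::plogis(config$acc_base_logit)
  data.frame(participant = participant, condition = condition,
             sequence_label = label,
             onset_E1 = onsets["E1"], onset_C1 = onsets["C1"],
             onset_R1 = onsets["R1"], onset_E2 = onsets["E2"],
             onset_C2 = onsets["C2"], onset_R2 = onsets["R2"],
             rt1 = unname(rt1), rt2 = unname(rt2),
             correct1 = stats::rbinom(1, 1, p1) == 1,
             correct2 = stats::rbinom(1, 1, p2) == 1,
             row.names = NULL)
}

#' Render epochs from ground-truth onsets
#'
#' Builds one task-locked `epoch_set` from a truth table: every operation
#' onset within the epoch window contributes `amplitude * topography *
#' half-sine(event_width)` centered at its onset, on top of Gaussian noise.
#' Events of the other task that fall inside the window are rendered too
#' (they are present in the recording), which is what makes the Short
#' condition genuinely overlapping.
#'
#' @param truths truth table as returned by [sample_trial_onsets()] (stacked).
#' @param topographies channels x 6 matrix, columns ordered E1,C1,R1,E2,C2,R2.
#' @param config a [sim_config()].
#' @param task 1 or 2; epochs are time-locked to that task's stimulus.
#' @param pre_pad_ms,post_pad_ms retained padding (ms).
#'
#' @return list with `epochs` (an `epoch_set`) and `truth` (the input table,
#'   aligned row-for-row with the epochs).
#' @export
render_epochs <- function(truths, topographies, config, task = 1,
                          pre_pad_ms = 250, post_pad_ms = 300) {
  stopifnot(task %in% c(1, 2), ncol(topographies) == 6,
            nrow(topographies) == config$n_channels)
  fs <- config$fs
  n_tr <- nrow(truths)
  soa <- ifelse(truths$condition == "Short",
                config$soa_short_ms, config$soa_long_ms)
  lock_ms <- if (task == 1) rep(0, n_tr) else soa
  rt_ms <- if (task == 1) truths$rt1 else truths$rt2
  own <- if (task == 1) c("onset_E1", "onset_C1", "onset_R1") else
    c("onset_E2", "onset_C2", "onset_R2")
  own_rel <- sweep(as.matrix(truths[own]), 1, lock_ms, "-")
  if (any(own_rel < 0) || any(own_rel > rt_ms)) {
    stop("truncation error: a task-", task,
         " onset falls outside its [stimulus, RT] window")
  }

  pre <- ms_to_samples(pre_pad_ms, fs)
  post <- ms_to_samples(post_pad_ms, fs)
  stim_sample <- pre + 1L
  rt_sample <- stim_sample + ms_to_samples(rt_ms, fs)
  n_samples <- max(rt_sample) + post
  w <- ms_to_samples(config$event_width_ms, fs)
  w <- max(w, 2L)
  shape <- sin(pi * (seq_len(w) - 0.5) / w)  # raw half-sine, peak ~ 1

  noise <- stats::rnorm(n_tr * config$n_channels * n_samples,
                        sd = config$noise_sd)
  data <- array(noise, dim = c(n_tr, config$n_channels, n_samples))
  if (config$noise_ar != 0) {
    a <- config$noise_ar
    sc <- sqrt(1 - a^2)  # keep marginal sd at noise_sd
    for (s in 2:n_samples) {
      data[, , s] <- a * data[, , s - 1] + sc * data[, , s]
    }
  }

  onset_cols <- c("onset_E1", "onset_C1", "onset_R1",
                  "onset_E2", "onset_C2", "onset_R2")
  half <- w %/% 2
  for (k in seq_len(6)) {
    centers <- stim_sample +
      ms_to_samples(truths[[onset_cols[k]]] - lock_ms, fs)
    topo <- config$amplitude * topographies[, k]
    for (i in seq_len(n_tr)) {
      idx <- centers[i] - half + seq_len(w) - 1L
      keep <- idx >= 1L & idx <= n_samples
      if (!any(keep)) next
      data[i, , idx[keep]] <- data[i, , idx[keep]] +
        outer(topo, shape[keep])
    }
  }

  metadata <- data.frame(
    trial = seq_len(n_tr),
    participant = truths$participant,
    condition = truths$condition,
    task = task,
    soa_ms = soa,
    rt_ms = rt_ms,
    correct = if (task == 1) truths$correct1 else truths$correct2)
  list(epochs = epoch_set(data, fs, stim_sample, rt_sample,
                          pre_pad_ms, post_pad_ms, metadata),
       truth = truths)
}

#' Generate a complete synthetic dual-task dataset
#'
#' Orchestrates topography construction, trial-truth sampling and epoch
#' rendering. Two task-aligned epoch sets are produced from the same
#' underlying trials: Task 1 epochs time-locked to the Task 1 stimulus and
#' Task 2 epochs to the Task 2 stimulus.
#'
#' @param config a [sim_config()].
#'
#' @return list of class `dualseq_dataset` with elements `task1`, `task2`
#'   (epoch sets), `behavior` (per-trial RT/accuracy table), `truth`
#'   (ground-truth onsets and sequence labels), `topographies`, `config`.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  topo <- make_topographies(6, config$n_channels,
                            seed = config$seed + 1000L)
  grid <- expand.grid(trial_in_cell = seq_len(config$trials_per_condition),
                      condition = c("Short", "Long"),
                      participant = seq_len(config$n_participants),
                      stringsAsFactors = FALSE)
  truths <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sample_trial_onsets(config, grid$participant[i], grid$condition[i])
  }))
  truths$trial <- seq_len(nrow(truths))
  truths <- truths[c("trial", setdiff(names(truths), "trial"))]

  r1 <- render_epochs(truths, topo, config, task = 1)
  r2 <- render_epochs(truths, topo, config, task = 2)
  behavior <- data.frame(trial = truths$trial,
                         participant = truths$participant,
                         condition = truths$condition,
                         soa_ms = ifelse(truths$condition == "Short",
                                         config$soa_short_ms,
                                         config$soa_long_ms),
                         rt1_ms = truths$rt1, rt2_ms = truths$rt2,
                         correct1 = truths$correct1,
                         correct2 = truths$correct2)
  structure(list(task1 = r1$epochs, task2 = r2$epochs,
                 behavior = behavior, truth = truths,
                 topographies = topo, config = config),
            class = "dualseq_dataset")
}

#' @export
print.dualseq_dataset <- function(x, ...) {
  cat(sprintf("<dualseq_dataset> %d trials (%d participants), %d channels @ %g Hz\n",
              nrow(x$truth), x$config$n_participants, x$config$n_channels,
              x$config$fs))
  print(table(condition = x$truth$condition, label = x$truth$sequence_label))
  invisible(x)
}
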