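#' Condition epochs for event decomposition
#'
#' Applies the decomposition front-end: average reference per sample,
#' zero-phase band-pass filtering (forward-backward Butterworth), exclusion
#' of trials with RT below `min_rt_s`, and cropping of each trial to
#' [stimulus onset, RT + `post_rt_ms`]. The extra samples after RT make the
#' final Response event estimable.
#'
#' @param epochs an `epoch_set`.
#' @param low,high band-pass edges in Hz (must satisfy low < high < fs/2).
#' @param min_rt_s minimum reaction time in seconds; faster trials are
#'   dropped.
#' @param post_rt_ms window retained after RT (ms); converted to samples by
#'   rounding up.
#' @param order Butterworth order (applied twice by filtfilt).
#'
#' @return A `decomp_set`: list with `trials` (list of channels x T
#'   matrices, each starting at stimulus onset), `fs`, `metadata`,
#'   `rt_sample` (RT index within each cropped trial), `start_sample` (index
#'   of the crop start within the source epochs), `n_samples_full`.
#' @export
prepare_for_decomposition <- function(epochs, low = 1, high = 50,
                                      min_rt_s = 0.2, post_rt_ms = 50,
                                      order = 4) {
  fs <- epochs$fs
  if (!(low < high)) stop("need low < high")
  if (high >= fs / 2) stop("high edge must be below Nyquist (", fs / 2, " Hz)")
  rt_s <- (epochs$rt_sample - epochs$stim_sample) / fs
  keep <- rt_s >= min_rt_s
  if (!any(keep)) stop("degenerate input: no trial with RT >= ", min_rt_s, " s")
  epochs <- subset_trials(epochs, keep)

  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  post <- as.integer(ceiling(post_rt_ms * fs / 1000))
  n_samples <- dim(epochs$data)[3]
  n_ch <- dim(epochs$data)[2]
  trials <- vector("list", n_trials(epochs))
  rt_crop <- integer(n_trials(epochs))
  for (i in seq_len(n_trials(epochs))) {
    x <- epochs$data[i, , ]                       # channels x samples
    x <- sweep(x, 2, colMeans(x), "-")            # average reference
    xf <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
    s0 <- epochs$stim_sample[i]
    s1 <- min(epochs$rt_sample[i] + post, n_samples)
    trials[[i]] <- xf[, s0:s1, drop = FALSE]
    rt_crop[i] <- epochs$rt_sample[i] - s0 + 1L
  }
  structure(list(trials = trials, fs = fs, metadata = epochs$metadata,
                 rt_sample = rt_crop,
                 start_sample = epochs$stim_sample,
                 n_samples_full = n_samples),
            class = "decomp_set")
}

#' @export
print.decomp_set <- function(x, ...) {
  lens <- vapply(x$trials, ncol, 0L)
  cat(sprintf("<decomp_set> %d trials, %d channels, T in [%d, %d] @ %g Hz\n",
              length(x$trials), nrow(x$trials[[1]]), min(lens), max(lens),
              x$fs))
  invisible(x)
}

#' Robust per-channel normalization statistics
#'
#' Median and median absolute deviation per channel, computed from
#' training-split trials only so that no validation information leaks into
#' the normalization.
#'
#' @param epochs an `epoch_set` restricted to the training split.
#' @return list of class `norm_stats` with per-channel `median` and `mad`
#'   (raw MAD, unscaled).
#' @export
norm_stats <- function(epochs) {
  n_ch <- dim(epochs$data)[2]
  med <- numeric(n_ch)
  mad_raw <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    v <- as.vector(epochs$data[, ch, ])
    med[ch] <- stats::median(v)
    mad_raw[ch] <- stats::median(abs(v - med[ch]))
  }
  if (any(mad_raw <= 0)) {
    stop("degenerate channel: MAD = 0 for channel(s) ",
         paste(which(mad_raw <= 0), collapse = ", "))
  }
  structure(list(median = med, mad = mad_raw), class = "norm_stats")
}

#' MAD z-scoring
#'
#' Per channel, z = (x - median) / (1.4826 * MAD). The 1.4826 factor makes
#' the scale consistent with the standard deviation under normality.
#'
#' @param epochs an `epoch_set`.
#' @param stats a [norm_stats()] object estimated on the training split.
#' @return the epoch set with normalized data.
#' @export
mad_zscore <- function(epochs, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  n_ch <- dim(epochs$data)[2]
  stopifnot(length(stats$median) == n_ch)
  for (ch in seq_len(n_ch)) {
    epochs$data[, ch, ] <- (epochs$data[, ch, ] - stats$median[ch]) /
      (1.4826 * stats$mad[ch])
  }
  epochs
}

#' Participant-level train/validation split
#'
#' Partitions participants (never trials) into training and validation sets
#' by a deterministic seeded shuffle, so no participant contributes to both
#' sides.
#'
#' @param participants vector of per-trial participant ids, or an
#'   `epoch_set` with a `participant` metadata column.
#' @param train_fraction fraction of participants assigned to training.
#' @param seed integer seed.
#' @return list with `train` and `validation` participant id vectors.
#' @export
split_by_participant <- function(participants, train_fraction = 0.85,
                                 seed = 1L) {
  if (inherits(participants, "epoch_set")) {
    participants <- participants$metadata$participant
  }
  ids <- unique(participants)
  if (length(ids) < 2) stop("cannot split: need at least 2 participants")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  ids <- sample(ids)
  n_train <- round(length(ids) * train_fraction)
  n_train <- max(1L, min(length(ids) - 1L, n_train))
  list(train = sort(ids[seq_len(n_train)]),
       validation = sort(ids[-seq_len(n_train)]))
}

#' Jittered training window for one trial
#'
#' Draws a window start uniformly within the pre-stimulus pad and a window
#' end uniformly within the post-RT pad (integers, inclusive). Samples
#' outside the original [stimulus, RT] core carry pure Negative labels, so
#' jittering teaches the model not to rely on absolute position.
#'
#' @param stim_sample,rt_sample stimulus and RT sample of the trial.
#' @param pre_pad_samples,post_pad_samples available pad widths in samples.
#' @param n_samples trial length (windows are clamped inside the trial).
#' @return list with `start` and `end` sample indices.
#' @export
jitter_crop <- function(stim_sample, rt_sample, pre_pad_samples,
                        post_pad_samples, n_samples) {
  if (pre_pad_samples < 0 || post_pad_samples < 0) {
    stop("pads missing: pad widths must be >= 0")
  }
  start <- stim_sample - sample.int(pre_pad_samples + 1L, 1L) + 1L
  end <- rt_sample + sample.int(post_pad_samples + 1L, 1L) - 1L
  list(start = max(1L, start), end = min(n_samples, end))
}
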