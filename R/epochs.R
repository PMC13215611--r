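#' Epoched multichannel time-series container
#'
#' An `epoch_set` holds a trials x channels x samples array together with the
#' per-trial bookkeeping the pipeline needs: the stimulus-locked sample, the
#' reaction-time sample, the padding kept before stimulus and after RT, and a
#' per-trial metadata table.
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate in Hz.
#' @param stim_sample integer vector, 1-based stimulus-onset sample per trial.
#' @param rt_sample integer vector, 1-based reaction-time sample per trial.
#' @param pre_pad_ms padding retained before stimulus onset (ms).
#' @param post_pad_ms padding retained after RT (ms).
#' @param metadata data.frame with one row per trial.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, stim_sample, rt_sample,
                      pre_pad_ms = 250, post_pad_ms = 300,
                      metadata = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  n_trials <- dim(data)[1]
  n_samples <- dim(data)[3]
  stim_sample <- as.integer(stim_sample)
  rt_sample <- as.integer(rt_sample)
  if (length(stim_sample) == 1) stim_sample <- rep(stim_sample, n_trials)
  stopifnot(length(stim_sample) == n_trials, length(rt_sample) == n_trials)
  if (any(stim_sample < 1) || any(stim_sample >= rt_sample) ||
      any(rt_sample > n_samples)) {
    stop("epoch_set invariant violated: need 1 <= stim_sample < rt_sample <= n_samples")
  }
  if (is.null(metadata)) metadata <- data.frame(trial = seq_len(n_trials))
  stopifnot(nrow(metadata) == n_trials)
  structure(
    list(data = data, fs = fs, stim_sample = stim_sample,
         rt_sample = rt_sample, pre_pad_ms = pre_pad_ms,
         post_pad_ms = post_pad_ms, metadata = metadata),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  pads: %g ms pre-stimulus, %g ms post-RT\n",
              x$pre_pad_ms, x$post_pad_ms))
  if (!is.null(x$metadata$condition)) {
    print(table(condition = x$metadata$condition))
  }
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an `epoch_set`.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset an epoch set by trial index
#' @param epochs an `epoch_set`.
#' @param idx integer or logical trial index.
#' @export
subset_trials <- function(epochs, idx) {
  idx <- seq_len(n_trials(epochs))[idx]
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$fs,
            epochs$stim_sample[idx], epochs$rt_sample[idx],
            epochs$pre_pad_ms, epochs$post_pad_ms,
            epochs$metadata[idx, , drop = FALSE])
}

#' Save / load an epoch set
#'
#' Convenience persistence using R's native serialization. Metadata tables
#' round-trip as part of the object; use [utils::write.csv] on
#' `epochs$metadata` for an interoperable export.
#'
#' @param epochs an `epoch_set`.
#' @param path file path.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "epoch_set"))
  x
}

ms_to_samples <- function(ms, fs) as.integer(floor(ms * fs / 1000 + 0.5))
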