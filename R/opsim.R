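#' Extract per-operation embedding records
#'
#' For each trial and operation, finds the peak of that operation's
#' predicted probability trace and averages the embedding series over a
#' window (default 13 samples, 52 ms at 250 Hz) centered on the peak,
#' truncated at trial edges. Operations whose peak probability is below
#' `min_peak` are skipped (and counted in the `n_skipped` attribute).
#'
#' @param traces per-trial T x n_classes probability matrices ([infer()]).
#' @param embeddings per-trial T x F embedding matrices ([infer()]).
#' @param metadata per-trial data.frame with at least `trial`,
#'   `participant`, `condition` columns.
#' @param task task index recorded in the output.
#' @param window_samples averaging window length (centered on the peak).
#' @param min_peak minimum peak probability for a usable record.
#' @param operations operation class names (columns of the traces).
#'
#' @return data.frame of embedding records: trial, participant, task,
#'   operation, condition, peak_sample, then the embedding vector columns
#'   V1..VF. Attribute `n_skipped` counts low-peak skips.
#' @export
extract_operation_embeddings <- function(traces, embeddings, metadata,
                                         task = 1, window_samples = 13,
                                         min_peak = 0.1,
                                         operations = c("E", "C", "R")) {
  stopifnot(length(traces) == length(embeddings),
            length(traces) == nrow(metadata))
  if (length(traces) == 0) stop("empty traces")
  half <- window_samples %/% 2
  recs <- list()
  n_skipped <- 0L
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    em <- embeddings[[i]]
    t_len <- nrow(tr)
    for (op in operations) {
      p <- tr[, op]
      peak <- which.max(p)
      if (p[peak] < min_peak) {
        n_skipped <- n_skipped + 1L
        next
      }
      lo <- max(1L, peak - half)
      hi <- min(t_len, peak + half)
      vec <- colMeans(em[lo:hi, , drop = FALSE])
      recs[[length(recs) + 1L]] <- data.frame(
        trial = metadata$trial[i], participant = metadata$participant[i],
        task = task, operation = op, condition = metadata$condition[i],
        peak_sample = peak, rbind(stats::setNames(vec, paste0("V", seq_along(vec)))))
    }
  }
  if (length(recs) == 0) stop("no usable embedding records")
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# exact mean pairwise cosine distance between two sets of unit row vectors
cross_mean_cos_dist <- function(u1, u2) {
  1 - sum(colMeans(u1) * colMeans(u2))
}

# exact mean pairwise cosine distance within a set (i != j pairs)
within_mean_cos_dist <- function(u) {
  n <- nrow(u)
  s <- colSums(u)
  (n * n - sum(s^2)) / (n * (n - 1))  # = 1 - (|s|^2 - n)/(n(n-1))
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Cross-condition embedding similarity by resampling
#'
#' Tests whether Short-condition operations occupy the same embedding
#' regions as their Long-condition counterparts. Per task and operation,
#' three sets are formed: Short same-operation, Long same-operation, and
#' Long other-operations. In each resampling iteration, each set is
#' resampled with replacement (`n_samp` rows) and two statistics are
#' computed against the within-Long same-operation baseline:
#' |cross-set mean pairwise cosine distance (Short-same vs Long-same) -
#' within-Long mean pairwise distance| ("same") and the analog with
#' Long-other ("other"). Mean pairwise cosine distances are computed in
#' closed form (they reduce to inner products of mean unit vectors), so the
#' statistics are exact for each resample. When operations embed identically
#' across conditions the "same" statistic concentrates near 0 while the
#' "other" statistic stays well above it.
#'
#' @param records embedding-record data.frame from
#'   [extract_operation_embeddings()] (both conditions, one task or more).
#' @param n_iter resampling iterations.
#' @param n_samp resample size per set.
#' @param seed integer seed.
#'
#' @return data.frame of class `similarity_summary`: per task, operation and
#'   statistic ("same", "other"): median, ci_low, ci_high (2.5/97.5
#'   percentiles over iterations).
#' @export
similarity_resampling <- function(records, n_iter = 1000, n_samp = 1000,
                                  seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  vcols <- grep("^V", names(records))
  out <- list()
  for (task in sort(unique(records$task))) {
    rt <- records[records$task == task, ]
    ops <- sort(unique(rt$operation))
    for (op in ops) {
      sets <- list(
        short_same = as.matrix(rt[rt$condition == "Short" &
                                    rt$operation == op, vcols]),
        long_same = as.matrix(rt[rt$condition == "Long" &
                                   rt$operation == op, vcols]),
        long_other = as.matrix(rt[rt$condition == "Long" &
                                    rt$operation != op, vcols]))
      for (nm in names(sets)) {
        if (nrow(sets[[nm]]) == 0) {
          stop("empty embedding set: ", nm, " for task ", task,
               " operation ", op)
        }
      }
      sets <- lapply(sets, unit_rows)
      stat_same <- numeric(n_iter)
      stat_other <- numeric(n_iter)
      for (it in seq_len(n_iter)) {
        rs <- lapply(sets, function(u) {
          u[sample.int(nrow(u), n_samp, replace = TRUE), , drop = FALSE]
        })
        d_within <- within_mean_cos_dist(rs$long_same)
        stat_same[it] <- abs(cross_mean_cos_dist(rs$short_same,
                                                 rs$long_same) - d_within)
        stat_other[it] <- abs(cross_mean_cos_dist(rs$short_same,
                                                  rs$long_other) - d_within)
      }
      q_s <- stats::quantile(stat_same, c(0.5, 0.025, 0.975), names = FALSE)
      q_o <- stats::quantile(stat_other, c(0.5, 0.025, 0.975), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        task = task, operation = op,
        statistic = c("same", "other"),
        median = c(q_s[1], q_o[1]),
        ci_low = c(q_s[2], q_o[2]),
        ci_high = c(q_s[3], q_o[3]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("similarity_summary", class(res))
  res
}
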