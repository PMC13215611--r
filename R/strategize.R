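#' @name sequence-taxonomy
#' @title Cross-task operation-sequence taxonomy
#' @description Each dual-task trial interleaves the three Task 1 operations
#'   (E1, C1, R1) with the three Task 2 operations (E2, C2, R2) while
#'   preserving each task's internal Encoding -> Central -> Response order.
#'   Of the 20 such interleavings, exactly six begin with E1 and end with R2;
#'   these carry the labels A-F. Everything else is INVALID.
NULL

#' @export
SEQUENCE_LABELS <- c("A", "B", "C", "D", "E", "F")

OP_NAMES <- c("E1", "C1", "R1", "E2", "C2", "R2")

# canonical label -> ordering map
sequence_orders <- function() {
  list(A = c("E1", "C1", "R1", "E2", "C2", "R2"),
       B = c("E1", "C1", "E2", "R1", "C2", "R2"),
       C = c("E1", "E2", "C1", "R1", "C2", "R2"),
       D = c("E1", "C1", "E2", "C2", "R1", "R2"),
       E = c("E1", "E2", "C1", "C2", "R1", "R2"),
       F = c("E1", "E2", "C2", "C1", "R1", "R2"))
}

#' Enumerate order-preserving interleavings of the two tasks
#'
#' Brute-force enumeration of all interleavings of (E1, C1, R1) and
#' (E2, C2, R2) that preserve within-task order, and the constrained subset
#' that begins with E1 and ends with R2. The constrained subset is exactly
#' the six labeled sequences: the serial sequence A plus five others in
#' which Task 2 operations begin before Task 1 completes.
#'
#' @return list with `all` (character vector of all interleavings, as
#'   "op1>op2>..." strings), `valid` (named list mapping labels A-F to
#'   operation orderings), `n_all`, `n_valid`.
#' @export
enumerate_valid_sequences <- function() {
  task1 <- c("E1", "C1", "R1")
  task2 <- c("E2", "C2", "R2")
  pos <- utils::combn(6, 3)
  all_seqs <- apply(pos, 2, function(p) {
    s <- character(6)
    s[p] <- task1
    s[setdiff(1:6, p)] <- task2
    paste(s, collapse = ">")
  })
  constrained <- all_seqs[startsWith(all_seqs, "E1") &
                            endsWith(all_seqs, "R2")]
  canon <- vapply(sequence_orders(), paste, "", collapse = ">")
  stopifnot(setequal(constrained, canon))
  valid <- sequence_orders()[match(constrained, canon)]
  names(valid) <- names(canon)[match(constrained, canon)]
  valid <- valid[order(names(valid))]
  list(all = all_seqs, valid = valid,
       n_all = length(all_seqs), n_valid = length(valid))
}

#' Classify six onsets into a sequence label
#'
#' Sorts the six onset times (already on a common clock) and matches the
#' resulting cross-task interleaving against the A-F taxonomy. Any ordering
#' outside the taxonomy, and any exact tie between onsets, yields INVALID.
#'
#' @param onsets named numeric vector with elements E1, C1, R1, E2, C2, R2.
#' @return single character label in A-F or "INVALID".
#' @export
classify_sequence <- function(onsets) {
  onsets <- onsets[OP_NAMES]
  if (anyNA(onsets)) stop("onsets must be named E1, C1, R1, E2, C2, R2")
  if (anyDuplicated(onsets)) return("INVALID")
  key <- paste(OP_NAMES[order(onsets)], collapse = ">")
  canon <- vapply(sequence_orders(), paste, "", collapse = ">")
  hit <- names(canon)[canon == key]
  if (length(hit) == 1) hit else "INVALID"
}

#' Sample constrained onset draws from per-task probability traces
#'
#' Aligns the Task 2 trace onto the Task 1 clock by shifting it by the SOA,
#' then repeatedly samples the six operation onsets independently from each
#' operation's probability-over-time trace (normalized to a distribution)
#' and retains draws satisfying both within-task ordering constraints
#' (E1 < C1 < R1 and E2 < C2 < R2). Each retained draw also carries its
#' predicted probability (the product of the six sampled onsets'
#' probabilities), so posteriors can weight sequences by how probable the
#' model found them, not only by how often they were drawn.
#'
#' @param trace1,trace2 T x 4 probability matrices for Task 1 / Task 2 with
#'   columns E, C, R, Negative (rows sum to 1).
#' @param stim1,stim2 stimulus-onset sample of each trace (1-based).
#' @param fs sampling rate (Hz).
#' @param soa_ms stimulus-onset asynchrony (ms).
#' @param n number of draws.
#'
#' @return list with `draws` (retained draws x 6 matrix of onset times in ms
#'   on the Task 1 clock, columns E1..R2), `n_drawn`, `n_retained`,
#'   `undecodable` (TRUE when some operation carries essentially no
#'   probability mass).
#' @export
sample_onsets <- function(trace1, trace2, stim1, stim2, fs, soa_ms,
                          n = 1000) {
  stopifnot(ncol(trace1) == 4, ncol(trace2) == 4)
  times1 <- (seq_len(nrow(trace1)) - stim1) / fs * 1000
  times2 <- (seq_len(nrow(trace2)) - stim2) / fs * 1000 + soa_ms
  draw_op <- function(p, times) {
    tot <- sum(p)
    if (!is.finite(tot) || tot < 1e-6) return(NULL)
    idx <- sample.int(length(p), n, replace = TRUE, prob = p)
    list(t = times[idx], w = p[idx] / tot)
  }
  cols <- vector("list", 6)
  names(cols) <- OP_NAMES
  wts <- matrix(1, n, 6)
  for (k in 1:3) {
    d1 <- draw_op(trace1[, k], times1)
    d2 <- draw_op(trace2[, k], times2)
    if (is.null(d1) || is.null(d2)) {
      return(list(draws = matrix(numeric(0), 0, 6,
                                 dimnames = list(NULL, OP_NAMES)),
                  weights = numeric(0),
                  n_drawn = n, n_retained = 0L, undecodable = TRUE))
    }
    cols[[k]] <- d1$t; wts[, k] <- d1$w
    cols[[k + 3]] <- d2$t; wts[, k + 3] <- d2$w
  }
  m <- do.call(cbind, cols)
  keep <- m[, "E1"] < m[, "C1"] & m[, "C1"] < m[, "R1"] &
    m[, "E2"] < m[, "C2"] & m[, "C2"] < m[, "R2"]
  list(draws = m[keep, , drop = FALSE],
       weights = apply(wts[keep, , drop = FALSE], 1, prod),
       n_drawn = n, n_retained = sum(keep), undecodable = FALSE)
}

#' Posterior over sequence labels from retained onset draws
#'
#' Label probabilities are the (optionally weighted) relative frequencies
#' of the retained draws. With weights from [sample_onsets()], each draw
#' counts proportionally to its predicted probability.
#'
#' @param draws retained draw matrix from [sample_onsets()].
#' @param n_drawn number of draws originally taken.
#' @param weights optional per-draw weights; NULL counts draws equally.
#' @return list of class `sequence_posterior`: `counts` (unweighted) and
#'   normalized `prob` over A-F and INVALID, `n_drawn`, `n_retained`,
#'   `mode`.
#' @export
sequence_posterior <- function(draws, n_drawn = nrow(draws),
                               weights = NULL) {
  if (nrow(draws) == 0) {
    stop("no retained draws: trial is undecodable")
  }
  labels <- apply(draws, 1, classify_sequence)
  lv <- c(SEQUENCE_LABELS, "INVALID")
  f <- factor(labels, levels = lv)
  counts <- table(f)
  if (is.null(weights)) {
    prob <- as.numeric(counts) / sum(counts)
  } else {
    stopifnot(length(weights) == nrow(draws), all(weights >= 0))
    wsum <- vapply(lv, function(l) sum(weights[f == l]), 0)
    prob <- wsum / sum(wsum)
  }
  names(prob) <- lv
  structure(list(counts = as.integer(counts), prob = prob,
                 n_drawn = n_drawn, n_retained = nrow(draws),
                 mode = lv[which.max(prob)]),
            class = "sequence_posterior")
}

#' Decode sequence posteriors for a set of trials
#'
#' Runs [sample_onsets()] + [sequence_posterior()] over paired Task 1 / Task
#' 2 probability traces and tabulates the per-trial posterior over sequence
#' labels.
#'
#' @param traces1,traces2 lists of T x 4 probability matrices (one per
#'   trial), as produced by [infer()].
#' @param stim1,stim2 per-trial stimulus samples for each task's trace.
#' @param fs sampling rate (Hz).
#' @param soa_ms per-trial SOA (ms).
#' @param n draws per trial.
#' @param seed integer seed.
#' @param weight_draws weight each retained draw by its predicted
#'   probability (default TRUE); FALSE counts draws equally.
#'
#' @return data.frame with one row per trial: `n_retained`, posterior
#'   columns `p_A`..`p_F`, `p_INVALID`, posterior `mode` ("UNDECODABLE" when
#'   no draw survives), `undecodable`.
#' @export
decode_sequences <- function(traces1, traces2, stim1, stim2, fs, soa_ms,
                             n = 1000, seed = 1L, weight_draws = TRUE) {
  stopifnot(length(traces1) == length(traces2))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  if (length(stim1) == 1) stim1 <- rep(stim1, length(traces1))
  if (length(stim2) == 1) stim2 <- rep(stim2, length(traces2))
  if (length(soa_ms) == 1) soa_ms <- rep(soa_ms, length(traces1))
  lv <- c(SEQUENCE_LABELS, "INVALID")
  out <- lapply(seq_along(traces1), function(i) {
    s <- sample_onsets(traces1[[i]], traces2[[i]], stim1[i], stim2[i],
                       fs, soa_ms[i], n = n)
    if (s$undecodable || s$n_retained == 0) {
      p <- rep(NA_real_, 7)
      return(data.frame(trial = i, n_retained = s$n_retained,
                        rbind(stats::setNames(p, paste0("p_", lv))),
                        mode = "UNDECODABLE", undecodable = TRUE))
    }
    post <- sequence_posterior(s$draws, s$n_drawn,
                               weights = if (weight_draws) s$weights)
    data.frame(trial = i, n_retained = post$n_retained,
               rbind(stats::setNames(post$prob, paste0("p_", lv))),
               mode = post$mode, undecodable = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
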