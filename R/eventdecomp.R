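#' Spatial basis from training-set covariance
#'
#' Eigendecomposition of the channel covariance averaged over all training
#' trials; the top components define the reduced spatial basis in which
#' template matching and EM run. Projected component series are standardized
#' by their training-set standard deviation, so event magnitudes are on a
#' comparable scale across components.
#'
#' @param train a `decomp_set` restricted to training-split trials.
#' @param n_components number of retained components (default 10).
#' @return list of class `spatial_basis`: `weights` (channels x D),
#'   `eigenvalues`, `comp_sd`, `n_components`.
#' @export
fit_spatial_basis <- function(train, n_components = 10) {
  stopifnot(inherits(train, "decomp_set"))
  n_ch <- nrow(train$trials[[1]])
  covs <- lapply(train$trials, function(x) stats::cov(t(x)))
  cbar <- Reduce(`+`, covs) / length(covs)
  eg <- eigen(cbar, symmetric = TRUE)
  pos <- sum(eg$values > max(eg$values) * 1e-10)
  if (n_components > pos) {
    stop("requested ", n_components, " components but covariance rank is ", pos)
  }
  w <- eg$vectors[, seq_len(n_components), drop = FALSE]
  proj <- lapply(train$trials, function(x) crossprod(w, x))  # D x T
  comp_sd <- sqrt(rowMeans(do.call(cbind, proj)^2))
  structure(list(weights = w, eigenvalues = eg$values,
                 comp_sd = comp_sd, n_components = n_components),
            class = "spatial_basis")
}

#' Project a decomposition set into a spatial basis
#'
#' @param basis a [fit_spatial_basis()] result.
#' @param dset a `decomp_set`.
#' @return list of T x D standardized component-series matrices, one per
#'   trial.
#' @export
project_epochs <- function(basis, dset) {
  lapply(dset$trials, function(x) {
    p <- crossprod(basis$weights, x) / basis$comp_sd   # D x T
    t(p)
  })
}

#' Unit-energy half-sine event template
#'
#' The assumed waveform of the brief multivariate event marking an operation
#' onset: a positive half-sine of the given width, discretized at `fs` and
#' normalized to unit energy.
#'
#' @param width_ms event width in ms.
#' @param fs sampling rate (Hz).
#' @return list of class `event_template`: `width_ms`, `n_samples`,
#'   `weights` (sum of squares = 1).
#' @export
half_sine_template <- function(width_ms, fs) {
  w <- as.integer(floor(width_ms * fs / 1000 + 0.5))
  if (w < 2) stop("template width ", width_ms, " ms is under 2 samples at ",
                  fs, " Hz")
  raw <- sin(pi * (seq_len(w) - 0.5) / w)
  structure(list(width_ms = width_ms, n_samples = w,
                 weights = raw / sqrt(sum(raw^2))),
            class = "event_template")
}

#' Centered template cross-correlation
#'
#' Matched-filter series y_d(t) = sum_i x_d(t + i - floor(W/2)) p(i), with
#' zero padding at the edges; peaks where the component series contains the
#' template.
#'
#' @param comp T x D component-series matrix.
#' @param template an [half_sine_template()].
#' @return T x D match series.
#' @export
pattern_match <- function(comp, template) {
  p <- template$weights
  w <- length(p)
  t_len <- nrow(comp)
  if (t_len <= w) stop("series shorter than template")
  half <- w %/% 2
  y <- matrix(0, t_len, ncol(comp))
  for (i in seq_len(w)) {
    shift <- (i - 1L) - half
    src <- seq_len(t_len) + shift
    ok <- src >= 1L & src <= t_len
    y[ok, ] <- y[ok, ] + p[i] * comp[src[ok], , drop = FALSE]
  }
  y
}

#' Template-match series for a set of trials
#'
#' Applies [pattern_match()] to every trial and (by default) standardizes
#' the match series to unit root-mean-square across all trials and
#' components: the EM emission model assumes unit-variance noise in the
#' match series, and matched filtering band-limited data inflates the
#' output variance well above the component variance.
#'
#' @param comp list of T x D component-series matrices ([project_epochs()]).
#' @param template an [half_sine_template()].
#' @param standardize divide by the pooled match RMS.
#' @return list of T x D match-series matrices.
#' @export
match_series <- function(comp, template, standardize = TRUE) {
  y <- lapply(comp, function(x) pattern_match(x, template))
  if (standardize) {
    rms <- sqrt(mean(unlist(lapply(y, function(m) colMeans(m^2)))))
    y <- lapply(y, function(m) m / rms)
  }
  y
}

# discretized gamma(shape 2) stage-duration pmf over 1..t_len samples:
# CDF differences on sample-width bins, renormalized over the trial support.
# min_gap forces a minimum duration (events occupy one template width, so
# two onsets cannot be closer than the width without describing the same
# pattern twice).
gamma_duration_pmf <- function(theta, t_len, min_gap = 1) {
  p <- diff(stats::pgamma(0:t_len, shape = 2, scale = max(theta, 1e-3)))
  if (min_gap > 1) p[seq_len(min(min_gap - 1, t_len))] <- 0
  s <- sum(p)
  if (s <= 0) {   # mass outside support; fall back to uniform
    lo <- min(min_gap, t_len)
    p <- c(rep(0, lo - 1), rep(1, t_len - lo + 1))
    s <- sum(p)
  }
  p / s
}

# y_t = sum_{s < t} x_s d_{t-s}, via FFT convolution
causal_conv <- function(x, d) {
  t_len <- length(x)
  z <- stats::convolve(x, rev(d), type = "open")
  y <- c(0, z[seq_len(t_len - 1)])
  pmax(y, 0)
}

# E-step for one trial: gamma-constrained forward-backward over
# (event index x time). Returns per-event posterior onset marginals
# (columns sum to 1) and the trial log-likelihood.
fb_trial <- function(y, m, theta, min_gap = 1) {
  t_len <- nrow(y)
  k_ev <- nrow(m)
  logg <- y %*% t(m)
  logg <- sweep(logg, 2, 0.5 * rowSums(m^2), "-")
  offs <- apply(logg, 2, max)
  g <- exp(sweep(logg, 2, offs, "-"))
  dur <- lapply(seq_len(k_ev + 1), function(j) {
    gap <- if (j >= 2 && j <= k_ev) min_gap else 1
    gamma_duration_pmf(theta[j], t_len, min_gap = gap)
  })

  alpha <- matrix(0, t_len, k_ev)
  log_scale <- 0
  a <- dur[[1]] * g[, 1]
  s <- sum(a)
  if (s <= 0) stop("non-finite likelihood: forward mass vanished")
  alpha[, 1] <- a / s
  log_scale <- log_scale + log(s)
  if (k_ev > 1) {
    for (k in 2:k_ev) {
      a <- causal_conv(alpha[, k - 1], dur[[k]]) * g[, k]
      s <- sum(a)
      if (s <= 0) stop("non-finite likelihood: forward mass vanished")
      alpha[, k] <- a / s
      log_scale <- log_scale + log(s)
    }
  }
  # closing stage: duration from last onset to the trial end boundary (T+1)
  close_w <- rev(dur[[k_ev + 1]])            # close_w[t] = d_K(T + 1 - t)
  lik <- sum(alpha[, k_ev] * close_w)
  if (lik <= 0 || !is.finite(lik)) stop("non-finite likelihood")
  loglik <- log(lik) + log_scale + sum(offs)

  beta <- matrix(0, t_len, k_ev)
  beta[, k_ev] <- close_w / sum(close_w)
  if (k_ev > 1) {
    for (k in (k_ev - 1):1) {
      wgt <- g[, k + 1] * beta[, k + 1]
      b <- rev(causal_conv(rev(wgt), dur[[k + 1]]))
      sb <- sum(b)
      if (sb <= 0) stop("non-finite likelihood: backward mass vanished")
      beta[, k] <- b / sb
    }
  }
  gam <- alpha * beta
  cs <- colSums(gam)
  bad <- !is.finite(cs) | cs <= 0
  if (any(bad)) {   # forward/backward supports lost to underflow
    gam[, bad] <- alpha[, bad, drop = FALSE]
    cs[bad] <- colSums(gam[, bad, drop = FALSE])
  }
  gam <- sweep(gam, 2, cs, "/")
  list(gamma = gam, loglik = loglik)
}

#' EM fit of K onset events with gamma-distributed stage durations
#'
#' Models each trial as K ordered latent event onsets separated by K + 1
#' gamma(shape 2) stage durations (boundaries anchored at the trial edges),
#' with per-component emission evidence from the template-match series:
#' log g_k(t) = sum_d (m[k,d] y_d(t) - m[k,d]^2 / 2), the log-likelihood
#' ratio of a Gaussian channel containing the event pattern versus not. The
#' E-step is an exact forward-backward dynamic program over (event index x
#' time); the M-step updates magnitudes by posterior-weighted averages of
#' the match series and stage scales from expected durations (theta =
#' E[duration] / 2). The duration update is moment-matched rather than an
#' exact maximizer of the truncated discretized gamma, so the algorithm is
#' a generalized EM: the log-likelihood is non-decreasing up to the
#' convergence tolerance (iteration stops at the first non-improving
#' step).
#'
#' @param matches list of T x D match-series matrices (one per trial).
#' @param k_events number of events K.
#' @param init optional `event_model` to initialize from.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param min_gap minimum separation (samples) between consecutive onsets,
#'   typically the template width; trial-edge stages are unconstrained.
#'
#' @return list with `model` (class `event_model`: `k_events`, `magnitudes`
#'   K x D, `theta` stage scales in samples, `loglik`, `n_iter`,
#'   `loglik_history`) and `gammas` (per-trial T x K posterior onset
#'   marginals, columns summing to 1).
#' @export
em_fit <- function(matches, k_events, init = NULL, max_iter = 200,
                   tol = 1e-4, min_gap = 1) {
  t_lens <- vapply(matches, nrow, 0L)
  t_need <- (k_events - 1) * min_gap + 2
  if (any(t_lens < max(t_need, k_events + 1))) {
    stop("infeasible: ", k_events, " events need trials of at least ",
         max(t_need, k_events + 1), " samples")
  }
  d_comp <- ncol(matches[[1]])
  if (is.null(init)) {
    m <- matrix(0, k_events, d_comp)
    theta <- rep(mean(t_lens) / (k_events + 1) / 2, k_events + 1)
  } else {
    m <- init$magnitudes
    theta <- init$theta
    stopifnot(nrow(m) == k_events, length(theta) == k_events + 1)
  }
  ll_prev <- -Inf
  history <- numeric(0)
  gammas <- NULL
  for (iter in seq_len(max_iter)) {
    num <- matrix(0, k_events, d_comp)
    onset_exp <- matrix(0, length(matches), k_events)
    ll <- 0
    gammas <- vector("list", length(matches))
    for (i in seq_along(matches)) {
      fb <- fb_trial(matches[[i]], m, theta, min_gap = min_gap)
      gammas[[i]] <- fb$gamma
      ll <- ll + fb$loglik
      num <- num + crossprod(fb$gamma, matches[[i]])
      onset_exp[i, ] <- colSums(fb$gamma * seq_len(t_lens[i]))
    }
    history <- c(history, ll)
    if (!is.finite(ll)) stop("non-finite likelihood during EM")
    m <- num / length(matches)
    durs <- cbind(onset_exp[, 1],
                  if (k_events > 1) onset_exp[, -1, drop = FALSE] -
                    onset_exp[, -k_events, drop = FALSE],
                  t_lens + 1 - onset_exp[, k_events])
    theta <- pmax(colMeans(durs) / 2, 0.5)
    if (is.finite(ll_prev) &&
        (ll - ll_prev) / (abs(ll_prev) + 1e-12) < tol) break
    ll_prev <- ll
  }
  model <- structure(list(k_events = k_events, magnitudes = m,
                          theta = theta, loglik = ll,
                          n_iter = iter, loglik_history = history),
                     class = "event_model")
  list(model = model, gammas = gammas)
}

#' @export
print.event_model <- function(x, ...) {
  cat(sprintf("<event_model> K = %d events, loglik = %.2f (%d EM iterations)\n",
              x$k_events, x$loglik, x$n_iter))
  cat("  stage scales (samples):",
      paste(sprintf("%.1f", x$theta), collapse = ", "), "\n")
  cat("  event magnitude norms:",
      paste(sprintf("%.3f", sqrt(rowSums(x$magnitudes^2))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Cumulative fitting of the event count
#'
#' Starts from a single event and adds events one at a time: events 1..K are
#' initialized from the K-event solution and the new event starts in the
#' final stage (its duration split in half); a freshly initialized fit of
#' the same size is run alongside and the higher-likelihood solution is
#' kept (EM is a local optimizer, and the warm start alone can trap the new
#' event in the wrong stage). A K+1-event model is accepted only if the
#' log-likelihood improves and every event's magnitude norm exceeds
#' `mag_floor` (on standardized components) and no two events carry
#' near-collinear magnitude patterns (pairwise |cosine| below `dup_cos`):
#' a new event whose pattern duplicates an existing one is riding the same
#' underlying multivariate change (the template's match ridge spans twice
#' the event width, so a copy of an event offset by one width still scores),
#' not marking a distinct operation. Otherwise the last accepted model is
#' returned. Pure-noise data where even the first event fails the floor
#' yields a flagged zero-event result.
#'
#' @param matches list of T x D match-series matrices.
#' @param k_max maximum event count to attempt.
#' @param mag_floor minimum event magnitude norm for acceptance.
#' @param dup_cos maximum pairwise |cosine| between event magnitude vectors.
#' @param penalty "bic" requires the log-likelihood gain of an added event
#'   to exceed half its added parameter count times log(n observations)
#'   (the BIC criterion; the likelihood spans every sample of every trial,
#'   so n is the total sample count) - a guard against over-segmentation;
#'   "none" accepts any positive gain.
#' @param ... passed to [em_fit()].
#'
#' @return list with `model`, `gammas`, `k_events`, `no_events` flag, and
#'   `accepted_logliks` (strictly increasing across accepted models).
#' @export
cumulative_fit <- function(matches, k_max = 8, mag_floor = 0.05,
                           dup_cos = 0.8, penalty = c("bic", "none"),
                           ...) {
  penalty <- match.arg(penalty)
  stopifnot(k_max >= 1)
  t_min <- min(vapply(matches, nrow, 0L))
  k_max <- min(k_max, t_min - 1L)
  fit <- em_fit(matches, 1, ...)
  if (sqrt(sum(fit$model$magnitudes^2)) < mag_floor) {
    return(list(model = NULL, gammas = NULL, k_events = 0L,
                no_events = TRUE, accepted_logliks = numeric(0)))
  }
  accepted <- fit
  lls <- fit$model$loglik
  d_comp <- ncol(matches[[1]])
  gain_floor <- if (penalty == "bic") {
    0.5 * (d_comp + 1) * log(sum(vapply(matches, nrow, 0L)))
  } else 0
  k <- 1L
  while (k < k_max) {
    prev <- accepted$model
    init <- list(magnitudes = rbind(prev$magnitudes,
                                    rep(0, ncol(prev$magnitudes))),
                 theta = c(prev$theta[seq_len(k)],
                           rep(prev$theta[k + 1] / 2, 2)))
    cand <- tryCatch(em_fit(matches, k + 1L, init = init, ...),
                     error = function(e) NULL)
    fresh <- tryCatch(em_fit(matches, k + 1L, ...),
                      error = function(e) NULL)
    if (!is.null(fresh) &&
        (is.null(cand) || fresh$model$loglik > cand$model$loglik)) {
      cand <- fresh
    }
    if (is.null(cand)) break
    norms <- sqrt(rowSums(cand$model$magnitudes^2))
    mu <- cand$model$magnitudes / norms
    cs <- tcrossprod(mu)
    diag(cs) <- 0
    if (cand$model$loglik > prev$loglik + gain_floor &&
        all(norms >= mag_floor) && max(abs(cs)) < dup_cos) {
      accepted <- cand
      lls <- c(lls, cand$model$loglik)
      k <- k + 1L
    } else break
  }
  list(model = accepted$model, gammas = accepted$gammas,
       k_events = accepted$model$k_events, no_events = FALSE,
       accepted_logliks = lls)
}

#' Tune the event width by stability of the event count
#'
#' Runs the cumulative fit for each candidate width and selects the most
#' stable width: the center of the longest run of consecutive widths
#' yielding the same event count (ties broken toward the run containing the
#' larger widths).
#'
#' @param match_factory function(width_ms) returning the match-series list
#'   for that width.
#' @param widths_ms sorted candidate widths (>= 3 values), default 20-60 ms
#'   in 5 ms steps.
#' @param min_run minimum stable-run length.
#' @param fs sampling rate (Hz); when given, each width's fit enforces a
#'   minimum inter-onset gap of one template width.
#' @param ... passed to [cumulative_fit()].
#'
#' @return list with `width_ms` (chosen), `fit` (the chosen width's
#'   cumulative fit), and `profile` (data.frame width_ms, k_events).
#' @export
tune_event_width <- function(match_factory, widths_ms = seq(20, 60, by = 5),
                             min_run = 3, fs = NULL, ...) {
  stopifnot(length(widths_ms) >= 3, !is.unsorted(widths_ms))
  fits <- lapply(widths_ms, function(w) {
    gap <- if (is.null(fs)) 1 else half_sine_template(w, fs)$n_samples
    cumulative_fit(match_factory(w), min_gap = gap, ...)
  })
  ks <- vapply(fits, function(f) as.integer(f$k_events), 0L)
  center <- stable_width_index(ks, min_run)
  list(width_ms = widths_ms[center], fit = fits[[center]],
       profile = data.frame(width_ms = widths_ms, k_events = ks))
}

# index of the most stable width: center of the longest run of consecutive
# equal event counts; ties broken toward the run containing larger widths;
# even-length runs take the upper middle
stable_width_index <- function(ks, min_run = 3) {
  r <- rle(ks)
  starts <- cumsum(r$lengths) - r$lengths + 1
  best <- which(r$lengths == max(r$lengths))
  best <- best[length(best)]
  if (r$lengths[best] < min_run) {
    stop("no stable width: longest constant-K run has length ",
         r$lengths[best], " < ", min_run)
  }
  starts[best] - 1 + ceiling((r$lengths[best] + 1) / 2)
}

#' Soft per-timestep class labels from onset posteriors
#'
#' Places each event's posterior onset marginal on the full padded epoch
#' timeline and adds a Negative class so every timestep sums to exactly 1.
#' If the event probabilities at a timestep sum above 1, they are rescaled
#' to 1 (Negative becomes 0). Pad samples outside the decomposition window
#' are pure Negative.
#'
#' @param gammas per-trial T x K posterior onset marginals (within the
#'   cropped decomposition window).
#' @param dset the `decomp_set` the gammas were fitted on (provides the
#'   window placement inside the full epochs).
#' @param class_names names for the K event classes; defaults to E, C, R
#'   when K = 3.
#'
#' @return list of full-length T_full x (K + 1) label matrices, final
#'   column "Negative".
#' @export
build_label_tensors <- function(gammas, dset, class_names = NULL) {
  k_ev <- ncol(gammas[[1]])
  if (is.null(class_names)) {
    class_names <- if (k_ev == 3) c("E", "C", "R") else paste0("op", seq_len(k_ev))
  }
  stopifnot(length(class_names) == k_ev)
  lapply(seq_along(gammas), function(i) {
    g <- gammas[[i]]
    if (any(g < 0)) stop("negative probabilities in onset distribution")
    t_full <- dset$n_samples_full
    lab <- matrix(0, t_full, k_ev + 1,
                  dimnames = list(NULL, c(class_names, "Negative")))
    rows <- dset$start_sample[i] + seq_len(nrow(g)) - 1L
    lab[rows, seq_len(k_ev)] <- g
    tot <- rowSums(lab[, seq_len(k_ev), drop = FALSE])
    over <- tot > 1
    if (any(over)) {
      lab[over, seq_len(k_ev)] <- lab[over, seq_len(k_ev), drop = FALSE] /
        tot[over]
      tot[over] <- 1
    }
    lab[, k_ev + 1] <- 1 - tot
    lab
  })
}
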