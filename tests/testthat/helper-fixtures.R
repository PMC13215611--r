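# Shared fixtures, built once per test session.
#
# Problem sizes are scaled for a fast default test run: the generator keeps
# the study conditions (SNR, stage structure, SOAs, strategy mixtures) at
# their defaults and only the trial count per participant is reduced.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# independent re-implementation of the discretized stage-duration pmf,
# used by brute-force oracles
oracle_duration_pmf <- function(theta, t_len, min_gap = 1) {
  edges <- stats::pgamma(0:t_len, shape = 2, scale = theta)
  p <- edges[-1] - edges[-(t_len + 1)]
  if (min_gap > 1) p[seq_len(min_gap - 1)] <- 0
  p / sum(p)
}

# brute-force E-step for K = 1 or 2 events by exhaustive enumeration of
# ordered onset placements; independent of the forward-backward code path
oracle_estep <- function(y, m, theta, min_gap = 1) {
  t_len <- nrow(y)
  k <- nrow(m)
  logg <- y %*% t(m) - matrix(0.5 * rowSums(m^2), t_len, k, byrow = TRUE)
  g <- exp(logg)
  d <- lapply(seq_len(k + 1), function(j) {
    gap <- if (j >= 2 && j <= k) min_gap else 1
    oracle_duration_pmf(theta[j], t_len, gap)
  })
  gam <- matrix(0, t_len, k)
  lik <- 0
  if (k == 1) {
    for (t1 in 1:t_len) {
      w <- d[[1]][t1] * g[t1, 1] * d[[2]][t_len + 1 - t1]
      gam[t1, 1] <- gam[t1, 1] + w
      lik <- lik + w
    }
  } else if (k == 2) {
    for (t1 in 1:(t_len - 1)) {
      for (t2 in (t1 + 1):t_len) {
        w <- d[[1]][t1] * g[t1, 1] * d[[2]][t2 - t1] * g[t2, 2] *
          d[[3]][t_len + 1 - t2]
        gam[t1, 1] <- gam[t1, 1] + w
        gam[t2, 2] <- gam[t2, 2] + w
        lik <- lik + w
      }
    }
  } else stop("oracle supports K <= 2")
  list(gamma = sweep(gam, 2, colSums(gam), "/"), loglik = log(lik))
}
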