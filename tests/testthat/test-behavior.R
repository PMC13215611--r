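# builds a posterior table + behavior table with known label-RT structure
make_behavior_sim <- function(n_per = 30, n_participants = 4,
                              labels = c("A", "D"), effect = 50,
                              conc = 1, seed = 1) {
  set.seed(seed)
  n <- n_per * n_participants
  lab <- sample(labels, n, replace = TRUE)
  participant <- rep(seq_len(n_participants), each = n_per)
  p_int <- stats::rnorm(n_participants, 0, 20)
  rt <- 500 + effect * (lab == "D") + p_int[participant] +
    stats::rnorm(n, 0, 30)
  pm <- matrix(0, n, 7,
               dimnames = list(NULL, paste0("p_", c(SEQUENCE_LABELS, "INVALID"))))
  for (i in seq_len(n)) {
    if (conc >= 1) {
      pm[i, paste0("p_", lab[i])] <- 1
    } else {
      pm[i, paste0("p_", lab[i])] <- conc
      others <- setdiff(labels, lab[i])
      pm[i, paste0("p_", others)] <- (1 - conc) / length(others)
    }
  }
  posteriors <- data.frame(trial = seq_len(n), n_retained = 1000, pm,
                           mode = lab, undecodable = FALSE)
  behavior <- data.frame(participant = participant, rt_ms = rt,
                         correct = stats::runif(n) < 0.9)
  list(posteriors = posteriors, behavior = behavior, labels = lab)
}

test_that("Rubin pooling matches the hand-computed example", {
  p <- pool_rubin(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$u_within, 1)
  expect_equal(p$b_between, 1)
  expect_equal(p$t_total, 1 + (1 + 1 / 3) * 1, tolerance = 1e-12)  # 2.3333
  expect_equal(p$df, (3 - 1) * (1 + 1 / ((1 + 1 / 3)))^2)
  expect_true(p$ci_low < 2 && p$ci_high > 2)
})

test_that("identical imputations collapse pooling to the single fit", {
  p <- pool_rubin(rep(1.7, 10), rep(0.4, 10))
  expect_equal(p$b_between, 0)
  expect_equal(p$t_total, p$u_within)
  expect_equal(p$se, 0.4)
  expect_equal(p$df, Inf)
  expect_error(pool_rubin(1, 1), "at least 2")
})

test_that("total variance never falls below within-imputation variance", {
  set.seed(2)
  for (i in 1:20) {
    est <- rnorm(8)
    se <- runif(8, 0.1, 2)
    p <- pool_rubin(est, se)
    expect_gte(p$t_total, p$u_within)
    expect_equal(p$estimate, mean(est))
  }
})

test_that("Holm adjustment is exact on the worked example and edge cases", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # step-down: adjusted values are monotone in the sorted order
  set.seed(3)
  p <- runif(10)
  a <- holm_adjust(p)
  expect_true(all(diff(a[order(p)]) >= -1e-12))
})

test_that("degenerate posteriors give identical imputations and B = 0", {
  sim <- make_behavior_sim(conc = 1, seed = 4)
  fits <- impute_and_fit(sim$posteriors, sim$behavior, m = 5,
                         engine = "fixed", fit_accuracy = FALSE, seed = 1)
  expect_equal(fits$m, 5)
  d_col <- fits$rt$est[, "sequenceD"]
  expect_equal(diff(range(d_col)), 0)
  pooled <- pool_rubin(fits$rt$est, fits$rt$se)
  expect_equal(pooled$b_between[pooled$term == "sequenceD"], 0)
})

test_that("a planted RT shift for label D is recovered from soft posteriors", {
  sim <- make_behavior_sim(n_per = 60, conc = 0.85, effect = 50, seed = 5)
  fits <- impute_and_fit(sim$posteriors, sim$behavior, m = 25,
                         engine = "fixed", fit_accuracy = FALSE, seed = 2)
  pooled <- pool_rubin(fits$rt$est, fits$rt$se)
  d <- pooled[pooled$term == "sequenceD", ]
  expect_gt(d$estimate, 0)
  expect_gt(d$ci_low, 0)          # CI excludes 0
  # label noise attenuates but the estimate stays in a sane range
  expect_lt(abs(d$estimate - 50), 30)

  ctr <- pairwise_contrasts(fits$rt, fits$terms)
  expect_true("D-A" %in% ctr$contrast)
  expect_equal(ctr$estimate[ctr$contrast == "D-A"], d$estimate,
               tolerance = 1e-9)
  expect_true(all(ctr$p_holm >= ctr$p - 1e-12))
})

test_that("the mixed-model engine runs and agrees with the planted effect", {
  sim <- make_behavior_sim(n_per = 40, n_participants = 5, conc = 1,
                           effect = 60, seed = 6)
  fits <- impute_and_fit(sim$posteriors, sim$behavior, m = 3,
                         engine = "lmm", fit_accuracy = TRUE, seed = 3)
  pooled <- pool_rubin(fits$rt$est, fits$rt$se)
  d <- pooled[pooled$term == "sequenceD", ]
  expect_equal(d$estimate, 60, tolerance = 15)
  expect_false(is.null(fits$acc))
  expect_equal(ncol(fits$acc$est), length(fits$terms))
})

test_that("undecodable and INVALID-only trials are excluded up front", {
  sim <- make_behavior_sim(seed = 7)
  sim$posteriors$undecodable[1:5] <- TRUE
  sim$posteriors[6, grep("^p_", names(sim$posteriors))] <- 0
  sim$posteriors$p_INVALID[6] <- 1
  fits <- impute_and_fit(sim$posteriors, sim$behavior, m = 2,
                         engine = "fixed", fit_accuracy = FALSE, seed = 1)
  expect_equal(fits$n_trials, nrow(sim$posteriors) - 6)
})

test_that("with no planted effects, Holm-adjusted contrasts control false positives", {
  set.seed(21)
  n_rep <- 30
  sig <- total <- 0
  for (r in seq_len(n_rep)) {
    sim <- make_behavior_sim(n_per = 40, n_participants = 4,
                             labels = c("A", "B", "D"), effect = 0,
                             conc = 0.9, seed = 100 + r)
    fits <- impute_and_fit(sim$posteriors, sim$behavior, m = 10,
                           engine = "fixed", fit_accuracy = FALSE, seed = r)
    ctr <- pairwise_contrasts(fits$rt, fits$terms)
    sig <- sig + sum(ctr$p_holm < 0.05)
    total <- total + nrow(ctr)
  }
  # family-wise control: the significant fraction stays at or below 0.05
  # within binomial error
  expect_lte(sig / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})
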