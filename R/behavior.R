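#' Multiple imputation of sequence labels with per-imputation model fits
#'
#' Propagates trial-level sequence uncertainty into behavioral models. For
#' each of `m` imputations, one label per trial is drawn from its posterior
#' over A-F (INVALID mass is dropped and the posterior renormalized; trials
#' with all mass on INVALID or undecodable trials are excluded up front),
#' and two models are fitted with sequence A as the reference level: a
#' linear mixed model `rt ~ sequence + (1 | participant)` and a logistic
#' mixed model for correctness. Imputations where a label level is absent
#' leave that coefficient missing (excluded from pooling, counted in the
#' log); non-converging mixed fits fall back to fixed participant effects.
#'
#' @param posteriors data.frame from [decode_sequences()] (columns
#'   `p_A`..`p_F`, `p_INVALID`, `undecodable`), aligned with `behavior`.
#' @param behavior data.frame with `participant`, `rt_ms` and `correct`
#'   columns for the analyzed task.
#' @param m number of imputations (default 100).
#' @param engine "lmm" for lme4 mixed models, "fixed" for fixed-effects
#'   (participant indicator) fits.
#' @param fit_accuracy also fit the logistic correctness model.
#' @param seed integer seed.
#'
#' @return list of class `imputation_fits`: `rt` and (optionally) `acc`,
#'   each with per-imputation coefficient matrix `est`, standard-error
#'   matrix `se`, and covariance arrays `vcov`; plus `m`, `n_trials`,
#'   `labels_used` and a `log` of anomalies.
#' @export
impute_and_fit <- function(posteriors, behavior, m = 100,
                           engine = c("lmm", "fixed"),
                           fit_accuracy = TRUE, seed = 1L) {
  engine <- match.arg(engine)
  stopifnot(nrow(posteriors) == nrow(behavior), m >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  pcols <- paste0("p_", SEQUENCE_LABELS)
  pm <- as.matrix(posteriors[pcols])
  keep <- !posteriors$undecodable & rowSums(pm, na.rm = TRUE) > 0
  pm <- pm[keep, , drop = FALSE]
  pm <- pm / rowSums(pm)
  beh <- behavior[keep, , drop = FALSE]
  n_tr <- nrow(beh)
  if (n_tr == 0) stop("no decodable trials")

  # coefficient layout fixed across imputations: intercept + label contrasts
  present_any <- SEQUENCE_LABELS[colSums(pm) > 0]
  if (length(present_any) < 2) stop("need at least 2 distinct labels")
  terms_all <- c("(Intercept)", paste0("sequence", setdiff(present_any, "A")))
  log_msgs <- character(0)

  fit_one <- function(df, family) {
    if (engine == "lmm") {
      fit <- tryCatch({
        if (is.null(family)) {
          lme4::lmer(y ~ sequence + (1 | participant), data = df,
                     control = lme4::lmerControl(calc.derivs = FALSE))
        } else {
          lme4::glmer(y ~ sequence + (1 | participant), data = df,
                      family = family, nAGQ = 0)
        }
      }, error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) {
        est <- lme4::fixef(fit)
        vc <- as.matrix(stats::vcov(fit))
        return(list(est = est, vcov = vc, fallback = FALSE))
      }
    }
    # fixed-effects fallback / engine
    fit <- if (is.null(family)) {
      stats::lm(y ~ sequence + factor(participant), data = df)
    } else {
      stats::glm(y ~ sequence + factor(participant), data = df,
                 family = family)
    }
    cf <- stats::coef(fit)
    sel <- names(cf) %in% terms_all
    est <- cf[sel]
    vc <- stats::vcov(fit)[sel, sel, drop = FALSE]
    list(est = est, vcov = vc, fallback = engine == "lmm")
  }

  run_model <- function(y, family) {
    k <- length(terms_all)
    est <- matrix(NA_real_, m, k, dimnames = list(NULL, terms_all))
    se <- est
    vcv <- array(NA_real_, c(k, k, m))
    for (imp in seq_len(m)) {
      lab <- vapply(seq_len(n_tr), function(i) {
        sample(SEQUENCE_LABELS, 1, prob = pm[i, ])
      }, "")
      df <- data.frame(y = y, participant = beh$participant,
                       sequence = factor(lab, levels = c("A", setdiff(SEQUENCE_LABELS, "A"))))
      df$sequence <- droplevels(df$sequence)
      if (nlevels(df$sequence) < 2) {
        log_msgs <<- c(log_msgs,
                       sprintf("imputation %d: single label level, skipped", imp))
        next
      }
      res <- fit_one(df, family)
      if (res$fallback) {
        log_msgs <<- c(log_msgs,
                       sprintf("imputation %d: mixed fit failed, fixed-effects fallback", imp))
      }
      hit <- intersect(names(res$est), terms_all)
      est[imp, hit] <- res$est[hit]
      ii <- match(hit, names(res$est))
      se[imp, hit] <- sqrt(diag(res$vcov))[ii]
      vcv[match(hit, terms_all), match(hit, terms_all), imp] <-
        res$vcov[ii, ii]
      missing_terms <- setdiff(terms_all, hit)
      if (length(missing_terms)) {
        log_msgs <<- c(log_msgs,
                       sprintf("imputation %d: term(s) %s absent", imp,
                               paste(missing_terms, collapse = ", ")))
      }
    }
    list(est = est, se = se, vcov = vcv)
  }

  out <- list(rt = run_model(beh$rt_ms, NULL))
  if (fit_accuracy) {
    out$acc <- run_model(as.numeric(beh$correct), stats::binomial())
  }
  out$m <- m
  out$n_trials <- n_tr
  out$terms <- terms_all
  out$log <- log_msgs
  class(out) <- "imputation_fits"
  out
}

#' Pool multiply-imputed estimates with Rubin's rules
#'
#' Q-bar = mean estimate; U-bar = mean squared standard error (within
#' variance); B = sample variance of estimates (between variance);
#' T = U-bar + (1 + 1/m) B; df = (m - 1)(1 + U-bar / ((1 + 1/m) B))^2.
#' Confidence intervals and p-values use the t distribution with df degrees
#' of freedom; when B = 0 all imputations agreed and the normal reference
#' (df = Inf) is used.
#'
#' @param est vector (or matrix, imputations x terms) of per-imputation
#'   estimates.
#' @param se matching standard errors.
#' @param conf confidence level.
#' @return data.frame: term, estimate, se, u_within, b_between, t_total,
#'   df, ci_low, ci_high, p, m (imputations actually pooled).
#' @export
pool_rubin <- function(est, se, conf = 0.95) {
  if (is.null(dim(est))) {
    est <- matrix(est, ncol = 1, dimnames = list(NULL, "estimate"))
    se <- matrix(se, ncol = 1)
  }
  out <- lapply(seq_len(ncol(est)), function(j) {
    e <- est[, j]; s <- se[, j]
    ok <- !is.na(e) & !is.na(s)
    e <- e[ok]; s <- s[ok]
    m <- length(e)
    if (m < 2) stop("pooling needs at least 2 imputations with estimates")
    qbar <- mean(e)
    ubar <- mean(s^2)
    b <- stats::var(e)
    t_tot <- ubar + (1 + 1 / m) * b
    df <- if (b > 0) (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2 else Inf
    tq <- stats::qt(1 - (1 - conf) / 2, df)
    p <- 2 * stats::pt(-abs(qbar) / sqrt(t_tot), df)
    data.frame(term = colnames(est)[j], estimate = qbar, se = sqrt(t_tot),
               u_within = ubar, b_between = b, t_total = t_tot, df = df,
               ci_low = qbar - tq * sqrt(t_tot),
               ci_high = qbar + tq * sqrt(t_tot), p = p, m = m)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Holm step-down adjustment
#'
#' Step-down Holm correction: p-values are sorted ascending, the i-th
#' smallest is multiplied by (k - i + 1), monotonicity is enforced and
#' values capped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Pooled pairwise sequence contrasts with Holm adjustment
#'
#' Computes every pairwise contrast between sequence labels per imputation
#' (difference of coefficients, standard error from the coefficient
#' covariance), pools each contrast across imputations with Rubin's rules,
#' and Holm-adjusts the pooled p-values.
#'
#' @param fits one model's element of an [impute_and_fit()] result (e.g.
#'   `fits$rt`).
#' @param terms full coefficient layout (the `terms` element of the fits).
#' @return data.frame: contrast, estimate, se, df, ci_low, ci_high, p,
#'   p_holm.
#' @export
pairwise_contrasts <- function(fits, terms) {
  labs <- c("A", sub("^sequence", "", terms[-1]))
  k <- length(terms)
  m <- nrow(fits$est)
  pairs <- utils::combn(labs, 2)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    w <- numeric(k)
    if (a != "A") w[match(paste0("sequence", a), terms)] <- -1
    if (b != "A") w[match(paste0("sequence", b), terms)] <- 1
    est_j <- numeric(m); se_j <- numeric(m)
    for (imp in seq_len(m)) {
      e <- fits$est[imp, ]
      v <- fits$vcov[, , imp]
      if (anyNA(e[w != 0]) || anyNA(v[w != 0, w != 0])) {
        est_j[imp] <- NA; se_j[imp] <- NA
      } else {
        est_j[imp] <- sum(w * e)
        se_j[imp] <- sqrt(drop(t(w) %*% v %*% w))
      }
    }
    pooled <- tryCatch(pool_rubin(est_j, se_j), error = function(e) NULL)
    if (is.null(pooled)) next
    pooled$term <- paste0(b, "-", a)
    out[[length(out) + 1L]] <- pooled
  }
  res <- do.call(rbind, out)
  res$p_holm <- holm_adjust(res$p)
  names(res)[names(res) == "term"] <- "contrast"
  rownames(res) <- NULL
  res[c("contrast", "estimate", "se", "df", "ci_low", "ci_high",
        "p", "p_holm")]
}
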