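# From-scratch survival statistics. The Cox model is fitted by
# Newton-Raphson on the partial likelihood with optional ridge penalty;
# risk-set sums are accumulated with reverse cumulative sums so one
# evaluation of (loglik, score, information) is O(n p^2) after sorting.

rev_cumsum <- function(v) rev(cumsum(rev(v)))

# Partial log-likelihood, score and information at beta, on data sorted by
# increasing time. Ties: breslow (tied events share the full risk set) or
# efron (tied events progressively discount their own weight). Risk-set
# sums S0, S1 and S2 at each tie block come from reverse cumulative sums,
# so one evaluation is O(n p^2) plus vectorized arithmetic over blocks;
# only the Efron correction loops over blocks explicitly.
cox_derivs <- function(Xs, ts, es, beta, ties) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  eta <- drop(Xs %*% beta)
  m <- max(eta)
  w <- exp(eta - m)
  # block structure over tied times: block[i] = first index of i's tie block
  first <- c(TRUE, ts[-1] != ts[-n])
  block_start <- which(first)
  block_id <- cumsum(first)
  cw <- rev_cumsum(w)
  cwX <- matrix(0, n, p)
  for (a in seq_len(p)) cwX[, a] <- rev_cumsum(w * Xs[, a])
  npair <- p * (p + 1) / 2
  cwXX <- matrix(0, n, npair)
  pair_a <- integer(npair)
  pair_b <- integer(npair)
  k <- 0L
  for (a in seq_len(p)) for (b in a:p) {
    k <- k + 1L
    pair_a[k] <- a
    pair_b[k] <- b
    cwXX[, k] <- rev_cumsum(w * Xs[, a] * Xs[, b])
  }
  ev <- es == 1
  d_per_block <- tabulate(block_id[ev], nbins = length(block_start))
  bi <- which(d_per_block > 0)           # blocks containing events
  i0 <- block_start[bi]                  # risk-set start per event block
  db <- d_per_block[bi]
  S0 <- cw[i0]
  S1 <- cwX[i0, , drop = FALSE]
  S2 <- cwXX[i0, , drop = FALSE]
  loglik <- sum(eta[ev] - m)
  score <- colSums(Xs[ev, , drop = FALSE])
  info <- matrix(0, p, p)
  if (ties == "breslow") {
    loglik <- loglik - sum(db * log(S0))
    xbar <- S1 / S0
    score <- score - colSums(db * xbar)
    for (k in seq_len(npair)) {
      a <- pair_a[k]
      b <- pair_b[k]
      v <- sum(db * (S2[, k] / S0 - xbar[, a] * xbar[, b]))
      info[a, b] <- info[a, b] + v
      if (a != b) info[b, a] <- info[b, a] + v
    }
  } else {
    block_end <- c(block_start[-1] - 1L, n)
    for (j in seq_along(bi)) {
      b_ <- bi[j]
      d_idx <- (block_start[b_]:block_end[b_])
      d_idx <- d_idx[es[d_idx] == 1]
      d <- db[j]
      xd <- Xs[d_idx, , drop = FALSE]
      wd <- sum(w[d_idx])
      sd1 <- colSums(w[d_idx] * xd)
      sd2v <- numeric(npair)
      for (k in seq_len(npair))
        sd2v[k] <- sum(w[d_idx] * Xs[d_idx, pair_a[k]] * Xs[d_idx, pair_b[k]])
      for (l in seq_len(d) - 1L) {
        f <- l / d
        S0l <- S0[j] - f * wd
        S1l <- S1[j, ] - f * sd1
        xbar <- S1l / S0l
        loglik <- loglik - log(S0l)
        score <- score - xbar
        for (k in seq_len(npair)) {
          a <- pair_a[k]
          b2 <- pair_b[k]
          v <- (S2[j, k] - f * sd2v[k]) / S0l - xbar[a] * xbar[b2]
          info[a, b2] <- info[a, b2] + v
          if (a != b2) info[b2, a] <- info[b2, a] + v
        }
      }
    }
  }
  list(loglik = loglik, score = score, info = info)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial log-likelihood, optionally penalized by a
#' ridge term `-ridge_lambda * sum(beta^2)`, by Newton-Raphson with
#' step-halving. Convergence is declared when the largest absolute
#' component of the (penalized) score falls below `tol_score` or the
#' relative change in penalized log-likelihood falls below `tol_loglik`.
#'
#' @param X covariate matrix (samples x covariates) or a numeric vector.
#' @param time positive follow-up times.
#' @param event 0/1 event indicators; at least one event required.
#' @param ridge_lambda nonnegative L2 penalty multiplier (0 = none).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param max_iter maximum Newton iterations.
#' @param tol_score,tol_loglik convergence tolerances.
#'
#' @return An object of class `cox_fit` with elements `coefficients`,
#'   `standard_errors`, `log_likelihood`, `null_log_likelihood`,
#'   `converged`, `n_iterations`, `ridge_lambda`, `ties`, `score_max`
#'   (largest absolute penalized score component at the solution).
#'   A coefficient path diverging beyond `|beta| > 15` is reported as a
#'   possible perfectly separating covariate with `converged = FALSE`.
#' @export
fit_cox <- function(X, time, event, ridge_lambda = 0,
                    ties = c("breslow", "efron"),
                    max_iter = 30, tol_score = 1e-8, tol_loglik = 1e-10) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("fit_cox: X must be finite")
  check_time_event(time, event)
  if (nrow(X) != length(time)) stopf("fit_cox: X rows must match time length")
  if (sum(event) == 0) stopf("fit_cox: no events in data")
  if (ridge_lambda < 0) stopf("fit_cox: ridge_lambda must be >= 0")
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  # center covariates for numerical stability; partial likelihood and beta
  # are invariant to the shift
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  o <- order(time)
  Xs <- Xc[o, , drop = FALSE]
  ts <- time[o]
  es <- event[o]

  beta <- numeric(p)
  dv <- cox_derivs(Xs, ts, es, beta, ties)
  null_ll <- dv$loglik
  pen_ll <- function(d, b) d$loglik - ridge_lambda * sum(b^2)
  ll <- pen_ll(dv, beta)
  converged <- FALSE
  sep_flag <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- dv$score - 2 * ridge_lambda * beta
    H <- dv$info + diag(2 * ridge_lambda, p)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new_dv <- cox_derivs(Xs, ts, es, new_beta, ties)
    new_ll <- pen_ll(new_dv, new_beta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll) && halvings < 20L) {
      halvings <- halvings + 1L
      new_beta <- beta + step / 2^halvings
      new_dv <- cox_derivs(Xs, ts, es, new_beta, ties)
      new_ll <- pen_ll(new_dv, new_beta)
    }
    rel_change <- abs(new_ll - ll) / max(1, abs(ll))
    beta <- new_beta
    dv <- new_dv
    ll <- new_ll
    g <- dv$score - 2 * ridge_lambda * beta
    if (max(abs(beta)) > 15) {
      sep_flag <- TRUE
      break
    }
    if (max(abs(g)) < tol_score || rel_change < tol_loglik) {
      converged <- TRUE
      break
    }
  }
  if (sep_flag)
    warnf("fit_cox: |beta| diverging; a covariate may perfectly separate survival")
  H <- dv$info + diag(2 * ridge_lambda, p)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, p) else sqrt(pmax(diag(vc), 0))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    standard_errors = stats::setNames(se, colnames(X)),
    log_likelihood = dv$loglik,
    null_log_likelihood = null_ll,
    converged = converged && !sep_flag,
    n_iterations = iter,
    ridge_lambda = ridge_lambda,
    ties = ties,
    score_max = max(abs(dv$score - 2 * ridge_lambda * beta))
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties, lambda=%g, %sconverged, %d iter)\n",
              x$ties, x$ridge_lambda, if (x$converged) "" else "NOT ",
              x$n_iterations))
  print(cbind(coef = x$coefficients, se = x$standard_errors))
  invisible(x)
}

#' Linear predictor (risk score) of a Cox fit
#'
#' Computes `X %*% beta` with no centering; larger values mean higher
#' hazard.
#'
#' @param fit a `cox_fit`.
#' @param X covariate matrix with columns matching the fit.
#' @return numeric risk score per sample.
#' @export
linear_predictor <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(fit$coefficients))
    stopf("linear_predictor: X has %d columns, fit has %d coefficients",
          ncol(X), length(fit$coefficients))
  drop(X %*% fit$coefficients)
}

#' Wald tests for Cox coefficients
#'
#' @param fit a converged `cox_fit`.
#' @return data.frame with `coef`, `se`, `z` and two-sided `p` per
#'   covariate.
#' @export
wald_test <- function(fit) {
  if (!inherits(fit, "cox_fit")) stopf("wald_test: need a cox_fit")
  if (!isTRUE(fit$converged)) stopf("wald_test: fit did not converge")
  z <- fit$coefficients / fit$standard_errors
  data.frame(
    coef = fit$coefficients,
    se = fit$standard_errors,
    z = z,
    p = 2 * pnorm(-abs(z)),
    row.names = names(fit$coefficients)
  )
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs ranked concordantly by the risk score.
#' A pair (i, j) is comparable when `event[i] == 1` and
#' `time[i] < time[j]` (tied event times are not comparable); it is
#' concordant when `risk[i] > risk[j]`, and tied risks count 1/2.
#'
#' @param time follow-up times.
#' @param event 0/1 indicators.
#' @param risk numeric risk scores (higher = shorter expected survival).
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(time, event, risk) {
  check_time_event(time, event)
  n <- length(time)
  if (length(risk) != n) stopf("concordance_index: lengths differ")
  if (!all(is.finite(risk))) stopf("concordance_index: risk must be finite")
  is_ev <- matrix(event == 1, n, n)
  comp <- outer(time, time, "<") & is_ev
  n_comp <- sum(comp)
  if (n_comp == 0L) stopf("concordance_index: no comparable pairs")
  conc <- sum(outer(risk, risk, ">") & comp)
  ties <- sum(outer(risk, risk, "==") & comp)
  (conc + 0.5 * ties) / n_comp
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up times.
#' @param event 0/1 indicators.
#' @return data.frame of class `kaplan_meier` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`
#'   (right-continuous step function).
#' @export
kaplan_meier <- function(time, event) {
  check_time_event(time, event)
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
            class = c("kaplan_meier", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over pooled distinct event times with the
#' hypergeometric variance, referred to a chi-square with 1 df.
#'
#' @param time_a,event_a first group.
#' @param time_b,event_b second group.
#' @return list with `statistic`, `p.value`, `observed_a`, `expected_a`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stopf("logrank_test: both groups must be nonempty")
  check_time_event(time_a, event_a)
  check_time_event(time_b, event_b)
  if (sum(event_a) + sum(event_b) == 0)
    stopf("logrank_test: no events in either group")
  dt <- sort(unique(c(time_a[event_a == 1], time_b[event_b == 1])))
  OmE <- 0
  V <- 0
  O <- 0
  E <- 0
  for (t in dt) {
    n1 <- sum(time_a >= t)
    n2 <- sum(time_b >= t)
    nt <- n1 + n2
    d1 <- sum(time_a == t & event_a == 1)
    d <- d1 + sum(time_b == t & event_b == 1)
    if (nt == 0 || d == 0) next
    e1 <- d * n1 / nt
    O <- O + d1
    E <- E + e1
    OmE <- OmE + (d1 - e1)
    if (nt > 1)
      V <- V + d * (n1 / nt) * (1 - n1 / nt) * (nt - d) / (nt - 1)
  }
  stat <- if (V > 0) OmE^2 / V else 0
  list(statistic = stat,
       p.value = if (V > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1,
       observed_a = O, expected_a = E)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test using the normal approximation with tie
#' correction and continuity correction. The statistic is the
#' Mann-Whitney U for the first sample.
#'
#' @param a,b numeric vectors.
#' @return list with `statistic` (U) and `p.value`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stopf("wilcoxon_ranksum: both samples must be nonempty")
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- table(c(a, b))
  N <- n1 + n2
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p.value = 1))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = U, p.value = min(1, 2 * pnorm(-abs(z))))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test with normal approximation, tie correction
#' and continuity correction; zero differences are dropped.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list with `statistic` (V, sum of positive ranks) and `p.value`.
#' @export
wilcoxon_signedrank <- function(a, b) {
  if (length(a) != length(b)) stopf("wilcoxon_signedrank: unequal lengths")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p.value = 1))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  nt <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(nt^3 - nt) / 48
  if (sigma2 <= 0) return(list(statistic = V, p.value = 1))
  z <- V - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = V, p.value = min(1, 2 * pnorm(-abs(z))))
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return sample correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("pearson_correlation: unequal lengths")
  if (length(x) < 3) stopf("pearson_correlation: need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("pearson_correlation: inputs must be finite")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) stopf("pearson_correlation: zero variance input")
  max(-1, min(1, sum(dx * dy) / sqrt(sx * sy)))
}
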