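#' Weighted Kaplan-Meier estimator
#'
#' Product-limit estimator of the survival function, optionally weighted
#' (e.g. by IPTW weights). The returned grid holds the distinct event times;
#' S(0) = 1 is implicit.
#'
#' @param time follow-up times (months, > 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @param weights optional non-negative per-subject weights (default 1).
#' @return a [survival_curve()].
#' @export
kaplan_meier <- function(time, event, weights = NULL) {
  n <- length(time)
  if (n == 0L) stop("kaplan_meier: empty input")
  stopifnot(length(event) == n, all(event %in% c(0, 1)), all(time > 0))
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stop("invalid weights")
  if (sum(weights) <= 0) stop("weights must not be all zero")

  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; w_s <- weights[ord]
  if (sum(e_s) == 0) {
    grid <- unique(t_s)
    return(survival_curve(grid, rep(1, length(grid))))
  }
  tailw <- rev(cumsum(rev(w_s)))          # weighted at-risk just before t
  first <- match(t_s, t_s)                # first row of each tied-time block
  blocks <- sort(unique(first))
  dw <- rowsum(w_s * e_s, first)[, 1]     # weighted events per block
  atrisk <- tailw[blocks]
  keep <- dw > 0
  surv <- cumprod(1 - dw[keep] / atrisk[keep])
  survival_curve(t_s[blocks][keep], surv)
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank chi-square statistic with 1 degree of freedom,
#' optionally subject-weighted (the weighted form is used for IPTW-adjusted
#' group comparisons: weights enter the event and at-risk counts).
#'
#' @param group binary group labels (two distinct values).
#' @param time follow-up times.
#' @param event event indicators (1 = event).
#' @param weights optional non-negative subject weights.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
log_rank_test <- function(group, time, event, weights = NULL) {
  n <- length(time)
  stopifnot(length(group) == n, length(event) == n)
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2L) stop("log_rank_test requires exactly two non-empty groups")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))

  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; w_s <- weights[ord]; g_s <- g[ord] == 1L
  tail_all <- rev(cumsum(rev(w_s)))
  tail_g1 <- rev(cumsum(rev(w_s * g_s)))
  first <- match(t_s, t_s)
  blocks <- sort(unique(first))
  dw <- rowsum(w_s * e_s, first)[, 1]
  d1 <- rowsum(w_s * e_s * g_s, first)[, 1]
  nw <- tail_all[blocks]; n1 <- tail_g1[blocks]
  keep <- dw > 0 & nw > 0
  dw <- dw[keep]; d1 <- d1[keep]; nw <- nw[keep]; n1 <- n1[keep]
  O1 <- sum(d1)
  E1 <- sum(dw * n1 / nw)
  vterm <- dw * (n1 / nw) * (1 - n1 / nw) * (nw - dw) / pmax(nw - 1, 1)
  V <- sum(vterm[nw > 1])
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Cox proportional hazards fit with Breslow baseline
#'
#' Maximizes the (optionally weighted) Cox partial likelihood with Breslow
#' handling of ties and returns coefficients, Wald standard errors and the
#' Breslow cumulative baseline hazard on the event-time grid. Columns that are
#' constant (non-identifiable) are flagged: their coefficient is reported as 0
#' with an infinite standard error.
#'
#' @param X numeric design matrix (may have zero columns for a baseline-only
#'   fit).
#' @param time follow-up times.
#' @param event event indicators.
#' @param weights optional case weights.
#' @param robust use a robust sandwich variance (required for weighted fits
#'   whose weights are estimated, e.g. IPTW).
#' @return an object of class `cox_fit`.
#' @export
fit_cox <- function(X, time, event, weights = NULL, robust = FALSE) {
  X <- as.matrix(X)
  n <- length(time)
  stopifnot(nrow(X) == n || ncol(X) == 0L, length(event) == n)
  if (sum(event) == 0) stop("fit_cox: no events")
  if (ncol(X) > 0L && n <= ncol(X)) stop("fit_cox: more covariates than subjects")
  if (is.null(weights)) weights <- rep(1, n)

  p <- ncol(X)
  beta <- numeric(p); se <- rep(NA_real_, p); loglik <- NA_real_
  flagged <- logical(p)
  if (p > 0L) {
    sds <- apply(X, 2, stats::sd)
    flagged <- sds == 0
    keep <- which(!flagged)
    if (length(keep) > 0L) {
      df <- data.frame(.time = time, .event = event)
      Xk <- X[, keep, drop = FALSE]
      fit <- tryCatch(
        survival::coxph(survival::Surv(.time, .event) ~ Xk, data = df,
                        weights = weights, ties = "breslow", robust = robust,
                        control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
        error = function(e) stop("fit_cox: fit failed (", conditionMessage(e), ")"))
      b <- stats::coef(fit)
      if (any(!is.finite(b))) stop("fit_cox: singular or non-identifiable design")
      vcv <- if (robust) fit$var else fit$var
      beta[keep] <- as.numeric(b)
      se[keep] <- sqrt(diag(as.matrix(vcv)))
      loglik <- fit$loglik[length(fit$loglik)]
    } else {
      loglik <- cox_null_loglik(time, event, weights)
    }
    se[flagged] <- Inf
  } else {
    loglik <- cox_null_loglik(time, event, weights)
  }

  eta <- if (p > 0L) drop(X %*% beta) else rep(0, n)
  bl <- breslow_baseline(time, event, eta, weights)
  structure(list(beta = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 flagged = stats::setNames(flagged, colnames(X)),
                 baseline_times = bl$times, baseline_hazard = bl$hazard,
                 loglik = loglik, n = n, n_event = sum(event), robust = robust),
            class = "cox_fit")
}

cox_null_loglik <- function(time, event, weights) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; weights <- weights[ord]
  ll <- 0
  for (t in unique(time[event == 1])) {
    at <- sum(weights[time >= t])
    ll <- ll + sum(weights[time == t & event == 1]) * (-log(at))
  }
  ll
}

# Breslow cumulative baseline hazard H0(t) at the distinct event times, given
# linear predictors eta (uncentered: H0 refers to eta = 0).
breslow_baseline <- function(time, event, eta, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(time))
  ut <- sort(unique(time[event == 1]))
  risk <- weights * exp(eta)
  increments <- vapply(ut, function(t) {
    sum(weights[time == t & event == 1]) / sum(risk[time >= t])
  }, numeric(1))
  list(times = ut, hazard = cumsum(increments))
}

#' Predicted survival curve from a Cox fit
#'
#' S(t | x) = exp(-H0(t) exp(x'beta)) with the Breslow baseline.
#'
#' @param fit a `cox_fit`.
#' @param x encoded covariate vector (or matrix of rows).
#' @return a [survival_curve()] (or list of curves for a matrix).
#' @export
predict_cox_curve <- function(fit, x) {
  stopifnot(inherits(fit, "cox_fit"))
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  eta <- if (length(fit$beta) > 0L) drop(xm %*% fit$beta) else rep(0, nrow(xm))
  curves <- lapply(eta, function(e) {
    survival_curve(fit$baseline_times, exp(-fit$baseline_hazard * exp(e)))
  })
  if (is.matrix(x) && nrow(x) > 1L) curves else curves[[1L]]
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, ", events =", x$n_event,
      ", p =", length(x$beta), ", loglik =", format(x$loglik), "\n")
  invisible(x)
}

#' Logistic regression with odds ratios
#'
#' Maximum-likelihood (IRLS) fit returning coefficients, Wald standard errors
#' and odds ratios with 95\% confidence intervals. Complete or quasi-complete
#' separation is flagged as an error rather than returning a diverged fit.
#'
#' @param X numeric design matrix (no intercept column; one is added).
#' @param y binary outcome (0/1).
#' @param weights optional case weights.
#' @return an object of class `logistic_fit`.
#' @export
fit_logistic <- function(X, y, weights = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(y %in% c(0, 1)))
  if (length(unique(y)) != 2L) stop("fit_logistic: outcome has a single class")
  if (is.null(weights)) weights <- rep(1, n)
  df <- data.frame(.y = y)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ X, data = df, family = stats::binomial(), weights = weights),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  b <- stats::coef(fit)
  if (any(!is.finite(b))) stop("fit_logistic: non-identifiable design (aliased columns)")
  fv <- stats::fitted(fit)
  degenerate <- any(fv < 1e-8 | fv > 1 - 1e-8)
  if ((separation || degenerate) && max(abs(b[-1])) > 10) {
    stop("fit_logistic: complete or quasi-complete separation detected")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  nm <- c("(Intercept)",
          if (is.null(colnames(X))) paste0("x", seq_len(ncol(X))) else colnames(X))
  names(b) <- names(se) <- nm
  or <- exp(b); lo <- exp(b - 1.96 * se); hi <- exp(b + 1.96 * se)
  structure(list(beta = b, se = se, or = or, or_low = lo, or_high = hi,
                 fitted = as.numeric(stats::fitted(fit)), n = n),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n, "\n")
  print(data.frame(beta = x$beta, se = x$se, OR = x$or,
                   CI95 = sprintf("[%.3g, %.3g]", x$or_low, x$or_high)))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction (large-sample convention used throughout).
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi_square_2x2: zero margin")
  }
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expd)^2 / expd)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Restricted mean survival time from a curve
#'
#' Area under the step survival curve on [0, tau], carrying the last value
#' forward when the grid ends before tau.
#'
#' @param curve a [survival_curve()].
#' @param tau horizon (months, >= 0).
#' @return RMST in months.
#' @export
rmst_from_curve <- function(curve, tau) {
  stopifnot(inherits(curve, "survival_curve"))
  if (tau < 0) stop("rmst_from_curve: negative tau")
  if (tau == 0) return(0)
  tt <- c(0, curve$times[curve$times < tau], tau)
  # value over [tt[i], tt[i+1]) is S at tt[i] (right-continuous step curve)
  sv <- eval_curve(curve, tt[-length(tt)])
  sum(diff(tt) * sv)
}
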