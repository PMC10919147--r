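#' Harrell's concordance index
#'
#' Fraction of admissible pairs ordered correctly by a risk score. A pair is
#' admissible when the smaller observed time carries an event (the subject
#' with shorter time is known to have failed first); tied observed times are
#' not admissible. Higher risk is expected to pair with shorter survival.
#' Ties in the risk score count 0.5.
#'
#' @param risk per-subject risk score (higher = worse prognosis).
#' @param time follow-up times.
#' @param event event indicators.
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 2L || sum(event) == 0) stop("concordance_index: need >= 2 subjects and >= 1 event")
  conc <- 0; total <- 0
  for (i in which(event == 1)) {
    cmp <- time > time[i]
    if (!any(cmp)) next
    total <- total + sum(cmp)
    conc <- conc + sum(risk[i] > risk[cmp]) + 0.5 * sum(risk[i] == risk[cmp])
  }
  if (total == 0) stop("concordance_index: no admissible pairs")
  conc / total
}

#' Bootstrap confidence interval for the concordance index
#'
#' Nonparametric percentile bootstrap over subjects.
#'
#' @inheritParams concordance_index
#' @param n_boot number of resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with `estimate`, `lower`, `upper`.
#' @export
concordance_ci <- function(risk, time, event, n_boot = 200, seed = 1L,
                           level = 0.95) {
  est <- concordance_index(risk, time, event)
  set.seed(seed)
  n <- length(risk)
  bs <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(concordance_index(risk[idx], time[idx], event[idx]),
             error = function(e) NA_real_)
  }, numeric(1))
  qs <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  list(estimate = est, lower = unname(qs[1]), upper = unname(qs[2]))
}

# Left limit G(t-) of a step curve.
eval_curve_left <- function(curve, t) {
  if (length(curve$times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, curve$times, left.open = TRUE)
  c(1, curve$surv)[idx + 1L]
}

#' Brier score and integrated Brier score with IPCW
#'
#' Graf-style inverse-probability-of-censoring-weighted Brier score
#' BS(t) at each grid time, using a Kaplan-Meier estimate of the censoring
#' distribution G (censoring treated as the event); the integrated score is
#' the trapezoidal average of BS(t) over the grid. Grid times beyond the last
#' follow-up are dropped with a warning.
#'
#' @param curves list of per-subject [survival_curve()] predictions.
#' @param time follow-up times.
#' @param event event indicators.
#' @param grid evaluation times (months).
#' @return list with `grid`, `bs` (per-time Brier scores) and `ibs`.
#' @export
integrated_brier <- function(curves, time, event, grid) {
  n <- length(time)
  stopifnot(length(curves) == n, length(event) == n, length(grid) >= 1L)
  grid <- sort(unique(grid))
  beyond <- grid > max(time)
  if (any(beyond)) {
    warning("dropping ", sum(beyond), " grid time(s) beyond the last follow-up")
    grid <- grid[!beyond]
  }
  if (length(grid) == 0L) stop("integrated_brier: empty evaluation grid")
  cens_km <- kaplan_meier(time, 1 - event)
  # predicted S_i(t) matrix: subjects x grid
  S <- t(vapply(curves, function(cv) eval_curve(cv, grid), numeric(length(grid))))
  S <- matrix(S, nrow = n)
  g_at_ti <- eval_curve_left(cens_km, time)   # G(t_i-)
  g_at_t <- eval_curve(cens_km, grid)         # G(t)
  bs <- vapply(seq_along(grid), function(k) {
    t <- grid[k]
    dead <- time <= t & event == 1
    alive <- time > t
    contrib <- numeric(n)
    contrib[dead] <- S[dead, k]^2 / g_at_ti[dead]
    contrib[alive] <- (1 - S[alive, k])^2 / g_at_t[k]
    mean(contrib)
  }, numeric(1))
  ibs <- if (length(grid) == 1L) bs else {
    sum(diff(grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) /
      (max(grid) - min(grid))
  }
  list(grid = grid, bs = bs, ibs = ibs)
}

#' Bootstrap CI for the integrated Brier score
#' @inheritParams integrated_brier
#' @param n_boot number of resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @export
ibs_ci <- function(curves, time, event, grid, n_boot = 200, seed = 1L,
                   level = 0.95) {
  est <- suppressWarnings(integrated_brier(curves, time, event, grid)$ibs)
  set.seed(seed)
  n <- length(time)
  bs <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(
      suppressWarnings(integrated_brier(curves[idx], time[idx], event[idx], grid)$ibs),
      error = function(e) NA_real_)
  }, numeric(1))
  qs <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  list(estimate = est, lower = unname(qs[1]), upper = unname(qs[2]))
}

#' Inverse probability of treatment weights
#'
#' Estimates propensity by logistic regression on the encoded covariates and
#' returns weights 1/e for the treated group and 1/(1-e) for the control
#' group, optionally stabilized by the marginal group probabilities and
#' truncated at the 1st/99th weight percentiles (guards against the extreme
#' weights an ~90/10 arm imbalance can produce). Standardized mean
#' differences before and after weighting are reported for every design
#' column as a balance diagnostic.
#'
#' @param X encoded covariate matrix.
#' @param group binary group indicator (0/1).
#' @param stabilize multiply weights by marginal group probabilities.
#' @param truncate quantile bounds for weight truncation, or NULL to disable.
#' @return object of class `iptw_weights`: `weights`, `propensity`,
#'   `truncation`, `smd` (data.frame: covariate, before, after).
#' @export
iptw_weights <- function(X, group, stabilize = TRUE, truncate = c(0.01, 0.99)) {
  X <- as.matrix(X)
  stopifnot(length(group) == nrow(X), all(group %in% c(0, 1)))
  if (length(unique(group)) != 2L) stop("iptw_weights: both groups must be present")
  keep <- apply(X, 2, function(x) stats::sd(x) > 0)  # drop empty dummy levels
  Xk <- X[, keep, drop = FALSE]
  # A separated propensity fit is not fatal for weighting: clip the fitted
  # propensities away from 0/1 (then truncate weights as usual).
  pfit <- tryCatch(fit_logistic(Xk, group), error = function(e) NULL)
  if (is.null(pfit)) {
    gfit <- suppressWarnings(
      stats::glm.fit(cbind(1, Xk), group, family = stats::binomial()))
    e <- pmin(pmax(gfit$fitted.values, 0.01), 0.99)
  } else {
    e <- pfit$fitted
  }
  if (is.null(truncate) && any(e <= 0 | e >= 1)) {
    stop("iptw_weights: degenerate propensity of 0/1 with truncation disabled")
  }
  w <- ifelse(group == 1, 1 / e, 1 / (1 - e))
  if (stabilize) {
    pg <- mean(group)
    w <- ifelse(group == 1, pg, 1 - pg) * w
  }
  if (!is.null(truncate)) {
    qs <- stats::quantile(w, truncate)
    w <- pmin(pmax(w, qs[1]), qs[2])
  }
  smd_before <- apply(X, 2, smd_one, group = group, weights = rep(1, nrow(X)))
  smd_after <- apply(X, 2, smd_one, group = group, weights = w)
  structure(list(weights = w, propensity = e,
                 truncation = if (is.null(truncate)) NULL else as.numeric(truncate),
                 smd = data.frame(covariate = colnames(X),
                                  before = unname(smd_before),
                                  after = unname(smd_after))),
            class = "iptw_weights")
}

# Weighted standardized mean difference for one covariate column. The
# denominator pools the *unweighted* group variances (the usual convention,
# so before/after SMDs share a scale).
smd_one <- function(x, group, weights) {
  w1 <- weights[group == 1]; w0 <- weights[group == 0]
  x1 <- x[group == 1]; x0 <- x[group == 0]
  m1 <- sum(w1 * x1) / sum(w1); m0 <- sum(w0 * x0) / sum(w0)
  v1 <- stats::var(x1); v0 <- stats::var(x0)
  denom <- sqrt((v1 + v0) / 2)
  if (denom == 0) return(0)
  (m1 - m0) / denom
}

#' @export
print.iptw_weights <- function(x, ...) {
  cat("<iptw_weights> n =", length(x$weights),
      sprintf("| weight range [%.3g, %.3g] | max |SMD| after = %.3f\n",
              min(x$weights), max(x$weights), max(abs(x$smd$after))))
  invisible(x)
}
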