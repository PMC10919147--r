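#' Time-dependent Shapley attribution of a predicted survival function
#'
#' Explains one patient's predicted survival curve under one arm as a sum of
#' per-variable attribution functions phi_j(t): for every grid time,
#' baseline(t) + sum_j phi_j(t) equals the model's prediction S(t | x)
#' (local accuracy). A variable's "absence" is realized by substituting its
#' value from background-sample rows (marginal expectation). Attributions are
#' computed per raw covariate (a categorical variable is one player, not its
#' one-hot columns), and always within one arm: the treatment indicator
#' routes the prediction through a different risk head and is never a player.
#'
#' `mode = "exact"` enumerates all 2^p coalitions (p <= 12);
#' `mode = "sampled"` averages marginal contributions over `n_perm` seeded
#' random permutations of the players.
#'
#' @param model a `svt_cfmodel`.
#' @param x a single covariate row (data.frame, model schema).
#' @param background data.frame of background rows (typically a seeded sample
#'   of ~100 training rows).
#' @param arm 0 (RT) or 1 (CRT): which counterfactual prediction to explain.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_perm permutations for sampled mode.
#' @param seed seed for sampled mode.
#' @param grid evaluation times; default: deciles of the model grid.
#' @return object of class `attribution_series`: `phi` (features x grid),
#'   `baseline` (background-average prediction), `grid`, `prediction`.
#' @export
survshap_t <- function(model, x, background, arm = 1,
                       mode = c("sampled", "exact"), n_perm = 50, seed = 1L,
                       grid = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(x), nrow(x) == 1L, is.data.frame(background))
  if (nrow(background) == 0L) stop("survshap_t: empty background sample")
  feats <- names(x)
  p <- length(feats)
  if (mode == "exact" && p > 12L) {
    stop("survshap_t: exact mode supports at most 12 features")
  }
  if (is.null(grid)) {
    gsrc <- if (!is.null(model$grid)) model$grid else stop("survshap_t: supply a grid")
    grid <- unique(stats::quantile(gsrc, probs = seq(0.1, 1, by = 0.1), type = 1))
  }
  B <- nrow(background)

  # value of a coalition: background rows with coalition features replaced by
  # x's values, predictions averaged over the background
  predict_surv <- function(df) surv_matrix(model, df, arm, grid)
  coalition_value <- function(members) {
    df <- background
    for (j in members) df[[feats[j]]] <- rep(x[[feats[j]]], B)
    colMeans(predict_surv(df))
  }

  phi <- matrix(0, p, length(grid), dimnames = list(feats, NULL))
  baseline <- coalition_value(integer(0))
  if (mode == "exact") {
    n_sub <- 2L^p
    vals <- matrix(NA_real_, n_sub, length(grid))
    sizes <- integer(n_sub)
    for (m in 0:(n_sub - 1L)) {
      members <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
      sizes[m + 1L] <- length(members)
      vals[m + 1L, ] <- if (length(members) == 0L) baseline else coalition_value(members)
    }
    wts <- factorial(0:(p - 1L)) * factorial(p - 1L - (0:(p - 1L))) / factorial(p)
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      for (m in 0:(n_sub - 1L)) {
        if (bitwAnd(m, bit) != 0L) next
        s <- sizes[m + 1L]
        phi[j, ] <- phi[j, ] + wts[s + 1L] * (vals[bitwOr(m, bit) + 1L, ] - vals[m + 1L, ])
      }
    }
  } else {
    set.seed(seed)
    for (r in seq_len(n_perm)) {
      perm <- sample.int(p)
      v_prev <- baseline
      members <- integer(0)
      for (j in perm) {
        members <- c(members, j)
        v_new <- coalition_value(members)
        phi[j, ] <- phi[j, ] + (v_new - v_prev) / n_perm
        v_prev <- v_new
      }
    }
  }
  pred <- drop(predict_surv(x))
  structure(list(phi = phi, baseline = baseline, grid = grid,
                 prediction = pred, arm = arm, mode = mode),
            class = "attribution_series")
}

#' @export
print.attribution_series <- function(x, ...) {
  imp <- attribution_importance(x)
  cat("<attribution_series>", nrow(x$phi), "features,", length(x$grid),
      "grid times; top:", names(sort(imp, decreasing = TRUE))[1], "\n")
  invisible(x)
}

# Time-integrated absolute attribution per feature (trapezoid over the grid).
attribution_importance <- function(att) {
  g <- att$grid
  if (length(g) == 1L) return(abs(att$phi[, 1]))
  apply(abs(att$phi), 1, function(a) {
    sum(diff(g) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
  })
}

#' Aggregate attribution rankings over patients
#'
#' For each patient, features are ranked by their time-integrated absolute
#' attribution; the counts of each feature at each rank position are
#' tabulated (each patient contributes exactly one rank permutation).
#'
#' @param attributions list of `attribution_series` over patients (same
#'   feature set).
#' @return matrix features x rank positions of counts; every column sums to
#'   the number of patients.
#' @export
aggregate_rankings <- function(attributions) {
  if (length(attributions) == 0L) stop("aggregate_rankings: no attributions")
  feats <- rownames(attributions[[1]]$phi)
  p <- length(feats)
  M <- matrix(0L, p, p, dimnames = list(feats, paste0("rank", seq_len(p))))
  for (att in attributions) {
    imp <- attribution_importance(att)
    rk <- rank(-imp, ties.method = "first")
    for (j in seq_len(p)) M[j, rk[j]] <- M[j, rk[j]] + 1L
  }
  M
}

#' Recommendation-behavior odds ratios
#'
#' Multivariate logistic regression of the recommended arm (1 = recommended
#' chemoradiotherapy) on the encoded covariates of the evaluation split. An
#' odds ratio below 1 marks a feature that pushes the model toward
#' recommending radiotherapy alone. If the model recommends a single arm for
#' everyone (as a Cox T-learner can), the fit is flagged not-estimable
#' rather than attempted.
#'
#' @param covariates evaluation-split covariate rows.
#' @param recommended vector of recommended arms (0/1).
#' @param encoder optional shared encoder.
#' @return list: `estimable` flag, and when estimable a `fit`
#'   (`logistic_fit`) plus an `or_table` data.frame.
#' @export
behavior_odds_ratios <- function(covariates, recommended, encoder = NULL) {
  stopifnot(nrow(covariates) == length(recommended))
  if (length(unique(recommended)) < 2L) {
    return(list(estimable = FALSE,
                reason = "all patients recommended the same arm"))
  }
  if (is.null(encoder)) encoder <- build_encoder(covariates)
  X <- encode_covariates(encoder, covariates)
  X <- X[, apply(X, 2, function(v) stats::sd(v) > 0), drop = FALSE]
  fit <- tryCatch(fit_logistic(X, as.integer(recommended)),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(estimable = FALSE, reason = conditionMessage(fit)))
  }
  tab <- data.frame(term = names(fit$beta), or = fit$or,
                    or_low = fit$or_low, or_high = fit$or_high,
                    row.names = NULL)
  list(estimable = TRUE, fit = fit, or_table = tab[tab$term != "(Intercept)", ])
}
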