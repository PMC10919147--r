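#' Median survival time from a predicted curve
#'
#' The outcome functional used for individual treatment effects: the
#' smallest grid time at which predicted survival drops to 0.5 or below
#' (first crossing). If the curve never reaches 0.5 within the horizon, the
#' horizon is returned with `reached = FALSE`.
#'
#' @param curve a [survival_curve()].
#' @param horizon months (> 0); default 60 (the 5-year evaluation window).
#' @return list with `median` (months) and `reached` (logical).
#' @export
median_survival <- function(curve, horizon = 60) {
  stopifnot(inherits(curve, "survival_curve"), horizon > 0)
  hit <- which(curve$surv <= 0.5 & curve$times <= horizon)
  if (length(hit) == 0L) list(median = horizon, reached = FALSE)
  else list(median = curve$times[hit[1]], reached = TRUE)
}

#' Individual treatment effects and recommendations
#'
#' For every patient: predict the counterfactual survival curves, extract the
#' predicted median survival under each arm, set
#' ITE = median(CRT) - median(RT), and recommend chemoradiotherapy when
#' ITE > 0, radiotherapy when ITE < 0, and chemoradiotherapy on ties (the
#' guideline standard of care carries the tie: the model must make a positive
#' case for withholding chemotherapy).
#'
#' @param model a `svt_cfmodel`.
#' @param covariates covariate rows to score.
#' @param horizon months for median extraction (default 60).
#' @param actual optional vector of actually received arms (0/1); fills the
#'   consistency flag.
#' @return data.frame of class `ite_result`: `median_rt`, `median_crt`,
#'   `reached_rt`, `reached_crt`, `ite`, `recommended`, and (when `actual`
#'   is given) `actual`, `consistent`.
#' @export
compute_ite_and_recommend <- function(model, covariates, horizon = 60,
                                      actual = NULL) {
  curves <- predict_counterfactual_curves(model, covariates)
  n <- length(curves$rt)
  m0 <- vapply(curves$rt, function(cv) unlist(median_survival(cv, horizon)), numeric(2))
  m1 <- vapply(curves$crt, function(cv) unlist(median_survival(cv, horizon)), numeric(2))
  out <- data.frame(
    median_rt = m0[1, ], median_crt = m1[1, ],
    reached_rt = as.logical(m0[2, ]), reached_crt = as.logical(m1[2, ])
  )
  out$ite <- out$median_crt - out$median_rt
  out$recommended <- as.integer(out$ite >= 0)
  if (!is.null(actual)) {
    stopifnot(length(actual) == n)
    out$actual <- as.integer(actual)
    out$consistent <- as.integer(out$recommended == out$actual)
  }
  class(out) <- c("ite_result", "data.frame")
  out
}

#' Consistency and recommendation-group counts
#'
#' Splits patients into consistent (actual treatment equals the recommended
#' one) versus inconsistent groups, and into recommended-RT (RRT) versus
#' recommended-CRT (RCRT) groups.
#'
#' @param recommended vector of recommended arms (0/1).
#' @param actual vector of actually received arms (0/1).
#' @return list with `consistent` (0/1 per patient) and `counts`
#'   (n_consis, n_inconsis, n_rrt, n_rcrt).
#' @export
label_consistency <- function(recommended, actual) {
  if (length(recommended) != length(actual)) {
    stop("label_consistency: length mismatch")
  }
  consis <- as.integer(recommended == actual)
  list(consistent = consis,
       counts = c(n_consis = sum(consis), n_inconsis = sum(1 - consis),
                  n_rrt = sum(recommended == 0), n_rcrt = sum(recommended == 1)))
}

#' Oracle counterfactual model from generator ground truth
#'
#' Wraps the generator's analytic Weibull curves as a `svt_cfmodel`, so the
#' evaluation suite can be exercised against a recommender that knows the
#' truth. Labelled synthetic: it exists only for validation of the pipeline.
#'
#' @param params the [generator_params()] the cohort was drawn from.
#' @param grid evaluation grid (months).
#' @return a `svt_cfmodel` of kind `"oracle"`.
#' @export
oracle_model <- function(params, grid = seq(0.5, params$horizon, by = 0.5)) {
  structure(list(params = params, grid = grid, kind = "oracle"),
            class = c("svt_oracle_model", "svt_cfmodel"))
}

#' @export
predict_counterfactual_curves.svt_oracle_model <- function(model, covariates) {
  p <- model$params
  lp_rt <- gen_lp(p, covariates, p$coef_rt)
  lp_crt <- gen_lp(p, covariates, p$coef_crt)
  med_rt <- p$scale_rt * (log(2) / exp(lp_rt))^(1 / p$shape_rt)
  med_crt <- p$scale_crt * (log(2) / exp(lp_crt))^(1 / p$shape_crt)
  mk <- function(lp, shape, scale, extra) {
    lapply(seq_along(lp), function(i) {
      # refine the grid at this patient's analytic medians so the first
      # crossing of 0.5 recovers the true median to ~1e-6 months
      g <- sort(unique(c(model$grid, extra[i], extra[i] + 1e-6)))
      g <- g[g > 0]
      survival_curve(g, exp(-(g / scale)^shape * exp(lp[i])))
    })
  }
  list(rt = mk(lp_rt, p$shape_rt, p$scale_rt, med_rt),
       crt = mk(lp_crt, p$shape_crt, p$scale_crt, med_crt))
}

#' @export
surv_matrix.svt_oracle_model <- function(model, covariates, arm, times) {
  p <- model$params
  lp <- gen_lp(p, covariates, if (arm == 0) p$coef_rt else p$coef_crt)
  shape <- if (arm == 0) p$shape_rt else p$shape_crt
  scale <- if (arm == 0) p$scale_rt else p$scale_crt
  exp(-outer(exp(lp), (times / scale)^shape))
}

#' @export
predict_arm_risk.svt_oracle_model <- function(model, covariates, arm) {
  p <- model$params
  gen_lp(p, covariates, if (arm == 0) p$coef_rt else p$coef_crt)
}
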