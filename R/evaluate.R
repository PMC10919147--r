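#' Recommendation-effect report
#'
#' The headline evaluation of a recommender on an evaluation split: compares
#' patients whose actual treatment was consistent with the recommendation
#' against inconsistent patients.
#'
#' * `hr`: hazard ratio for the consistency indicator from an unweighted Cox
#'   fit (reference = inconsistent, so hr < 1 means following the
#'   recommendation is protective), Wald 95\% CI;
#' * `hr_adjusted`: the same model weighted by IPTW weights estimated with
#'   the consistency indicator as the "treatment" and all encoded covariates
#'   in the propensity model; robust sandwich variance for the CI;
#' * `drmst`: 5-year restricted-mean-survival-time difference between the
#'   consistent and inconsistent Kaplan-Meier curves, bootstrap percentile CI;
#' * `nnt`: RMST(consistent) / dRMST (the average-life-gain construction of
#'   number needed to treat), bootstrap percentile CI; flagged not-defined
#'   when dRMST <= 0.
#'
#' @param cohort evaluation `svt_cohort`.
#' @param ite an `ite_result` with `recommended` for the same rows.
#' @param tau restriction time in months (default 60 = 5 years).
#' @param n_boot bootstrap resamples for the dRMST / NNT CIs.
#' @param seed bootstrap seed.
#' @param encoder optional encoder for the IPTW propensity design; defaults
#'   to one built on the evaluation covariates.
#' @return list of class `recommendation_report`.
#' @export
recommendation_effect <- function(cohort, ite, tau = 60, n_boot = 1000,
                                  seed = 1L, encoder = NULL) {
  stopifnot(inherits(cohort, "svt_cohort"), tau > 0)
  n <- cohort_size(cohort)
  stopifnot(nrow(ite) == n)
  lab <- label_consistency(ite$recommended, cohort$treatment)
  consis <- lab$consistent
  if (sum(consis) == 0 || sum(1 - consis) == 0) {
    stop("recommendation_effect: a consistency group is empty")
  }
  time <- cohort$time; event <- cohort$event

  Xc <- matrix(consis, ncol = 1, dimnames = list(NULL, "consistent"))
  cf <- fit_cox(Xc, time, event)
  hr <- exp(cf$beta[1])
  hr_ci <- exp(cf$beta[1] + c(-1.96, 1.96) * cf$se[1])

  if (is.null(encoder)) encoder <- build_encoder(cohort$covariates)
  Xcov <- encode_covariates(encoder, cohort$covariates)
  w <- iptw_weights(Xcov, consis)
  cfw <- fit_cox(Xc, time, event, weights = w$weights, robust = TRUE)
  hra <- exp(cfw$beta[1])
  hra_ci <- exp(cfw$beta[1] + c(-1.96, 1.96) * cfw$se[1])

  point <- drmst_nnt(time, event, consis, tau)
  set.seed(seed)
  boot <- replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(consis[idx]) == 0 || sum(1 - consis[idx]) == 0) {
      c(NA_real_, NA_real_)
    } else {
      b <- drmst_nnt(time[idx], event[idx], consis[idx], tau)
      c(b$drmst, b$nnt)
    }
  })
  drmst_ci <- stats::quantile(boot[1, ], c(0.025, 0.975), na.rm = TRUE)
  nnt_ci <- stats::quantile(boot[2, ], c(0.025, 0.975), na.rm = TRUE)

  structure(list(
    hr = unname(hr), hr_ci = unname(hr_ci),
    hr_adjusted = unname(hra), hr_adjusted_ci = unname(hra_ci),
    drmst = point$drmst, drmst_ci = unname(drmst_ci),
    rmst_consis = point$rmst_consis, rmst_inconsis = point$rmst_inconsis,
    nnt = point$nnt, nnt_defined = point$nnt_defined, nnt_ci = unname(nnt_ci),
    counts = lab$counts, tau = tau, smd = w$smd
  ), class = "recommendation_report")
}

drmst_nnt <- function(time, event, consis, tau) {
  km_c <- kaplan_meier(time[consis == 1], event[consis == 1])
  km_i <- kaplan_meier(time[consis == 0], event[consis == 0])
  r_c <- rmst_from_curve(km_c, tau)
  r_i <- rmst_from_curve(km_i, tau)
  d <- r_c - r_i
  defined <- d > 0
  list(rmst_consis = r_c, rmst_inconsis = r_i, drmst = d,
       nnt = if (defined) r_c / d else NA_real_, nnt_defined = defined)
}

#' @export
print.recommendation_report <- function(x, ...) {
  cat(sprintf("<recommendation_report> tau = %g months\n", x$tau))
  cat(sprintf("  HR  %.3f (%.3f-%.3f) | HRa %.3f (%.3f-%.3f)\n",
              x$hr, x$hr_ci[1], x$hr_ci[2],
              x$hr_adjusted, x$hr_adjusted_ci[1], x$hr_adjusted_ci[2]))
  cat(sprintf("  dRMST %.2f (%.2f-%.2f) months | NNT %s (%.2f-%.2f)\n",
              x$drmst, x$drmst_ci[1], x$drmst_ci[2],
              if (x$nnt_defined) sprintf("%.2f", x$nnt) else "not defined",
              x$nnt_ci[1], x$nnt_ci[2]))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Within-recommendation-group treatment comparisons
#'
#' Inside the recommended-RT and recommended-CRT groups separately: the
#' Kaplan-Meier curves of patients who actually received RT versus CRT and
#' the log-rank p-value. A group whose patients all received one arm is
#' flagged untestable instead of tested.
#'
#' @param cohort evaluation `svt_cohort`.
#' @param ite matching `ite_result`.
#' @return named list (`rrt`, `rcrt`) of lists: `n`, `testable`, `km_rt`,
#'   `km_crt`, `log_rank_p`.
#' @export
within_group_comparison <- function(cohort, ite) {
  out <- lapply(c(rrt = 0L, rcrt = 1L), function(rec_arm) {
    idx <- which(ite$recommended == rec_arm)
    if (length(idx) == 0L) {
      return(list(n = 0L, testable = FALSE, reason = "empty group"))
    }
    sub_t <- cohort$time[idx]; sub_e <- cohort$event[idx]
    sub_a <- cohort$treatment[idx]
    if (length(unique(sub_a)) < 2L) {
      return(list(n = length(idx), testable = FALSE,
                  reason = "only one actual arm present"))
    }
    lr <- log_rank_test(sub_a, sub_t, sub_e)
    list(n = length(idx), testable = TRUE,
         km_rt = kaplan_meier(sub_t[sub_a == 0], sub_e[sub_a == 0]),
         km_crt = kaplan_meier(sub_t[sub_a == 1], sub_e[sub_a == 1]),
         log_rank_stat = lr$statistic, log_rank_p = lr$p_value)
  })
  out
}

#' Per-arm discrimination and calibration of a counterfactual model
#'
#' Within each actual-treatment arm of the evaluation split: Harrell's
#' C-index of the model's predicted risk for that arm (bootstrap CI) and the
#' IPCW integrated Brier score of its predicted curves (bootstrap CI). The
#' IBS grid is the arm's event times up to the 95th percentile of follow-up.
#'
#' @param model a `svt_cfmodel`.
#' @param cohort evaluation `svt_cohort` (both arms present).
#' @param n_boot bootstrap resamples for the CIs.
#' @param seed bootstrap seed.
#' @return list with `rt` and `crt`, each holding `c_index` and `ibs`
#'   (`estimate`, `lower`, `upper`) and `n`.
#' @export
performance_by_arm <- function(model, cohort, n_boot = 200, seed = 1L) {
  stopifnot(inherits(cohort, "svt_cohort"))
  if (length(unique(cohort$treatment)) < 2L) {
    stop("performance_by_arm: both arms must be present")
  }
  out <- lapply(c(rt = 0L, crt = 1L), function(a) {
    idx <- which(cohort$treatment == a)
    cov_a <- cohort$covariates[idx, , drop = FALSE]
    t_a <- cohort$time[idx]; e_a <- cohort$event[idx]
    risk <- predict_arm_risk(model, cov_a, a)
    ci <- concordance_ci(risk, t_a, e_a, n_boot = n_boot, seed = seed)
    curves <- predict_counterfactual_curves(model, cov_a)[[if (a == 0) "rt" else "crt"]]
    grid <- sort(unique(t_a[e_a == 1]))
    grid <- grid[grid <= stats::quantile(t_a, 0.95)]
    if (length(grid) == 0L) grid <- sort(unique(t_a[e_a == 1]))
    ibs <- ibs_ci(curves, t_a, e_a, grid, n_boot = n_boot, seed = seed)
    list(n = length(idx), c_index = ci, ibs = ibs)
  })
  out
}

#' Cohort descriptive summary
#'
#' Median (IQR) for continuous covariates and counts (percent) per
#' categorical level, overall and per treatment arm, with chi-square
#' comparisons between arms for categorical variables; per-arm and overall
#' cancer-specific mortality percentages and arm shares.
#'
#' @param cohort a `svt_cohort`.
#' @return list of class `cohort_summary` with `arms` (counts and percent
#'   shares), `mortality` (per-arm / overall percentages and chi-square p),
#'   `continuous` and `categorical` tables.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "svt_cohort"))
  cov <- cohort$covariates
  arm <- cohort$treatment; event <- cohort$event
  n <- length(arm); n0 <- sum(arm == 0); n1 <- sum(arm == 1)

  arms <- data.frame(arm = c("rt", "crt"), n = c(n0, n1),
                     pct = 100 * c(n0, n1) / n)

  d0 <- sum(event[arm == 0]); d1 <- sum(event[arm == 1])
  mort_tab <- rbind(c(n0 - d0, d0), c(n1 - d1, d1))
  chi <- if (all(rowSums(mort_tab) > 0) && all(colSums(mort_tab) > 0)) {
    chi_square_2x2(t(mort_tab))
  } else list(statistic = NA_real_, p_value = NA_real_)
  mortality <- list(
    pct_rt = 100 * d0 / n0, pct_crt = 100 * d1 / n1,
    pct_overall = 100 * (d0 + d1) / n,
    chisq_statistic = chi$statistic, chisq_p = chi$p_value)

  is_num <- vapply(cov, is.numeric, logical(1))
  cont <- do.call(rbind, lapply(names(cov)[is_num], function(v) {
    qs <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75))
    q_all <- qs(cov[[v]]); q0 <- qs(cov[[v]][arm == 0]); q1 <- qs(cov[[v]][arm == 1])
    data.frame(variable = v,
               overall = sprintf("%.1f (%.1f-%.1f)", q_all[1], q_all[2], q_all[3]),
               rt = sprintf("%.1f (%.1f-%.1f)", q0[1], q0[2], q0[3]),
               crt = sprintf("%.1f (%.1f-%.1f)", q1[1], q1[2], q1[3]))
  }))

  cat_vars <- names(cov)[!is_num]
  catg <- do.call(rbind, lapply(cat_vars, function(v) {
    lv <- levels(factor(cov[[v]]))
    rows <- do.call(rbind, lapply(lv, function(l) {
      k_all <- sum(cov[[v]] == l); k0 <- sum(cov[[v]][arm == 0] == l)
      k1 <- sum(cov[[v]][arm == 1] == l)
      data.frame(variable = v, level = l,
                 overall_n = k_all, overall_pct = 100 * k_all / n,
                 rt_n = k0, rt_pct = 100 * k0 / max(n0, 1),
                 crt_n = k1, crt_pct = 100 * k1 / max(n1, 1))
    }))
    rows
  }))
  cat_tests <- do.call(rbind, lapply(cat_vars, function(v) {
    tab <- table(factor(arm, levels = 0:1), cov[[v]])
    p <- tryCatch(
      stats::chisq.test(tab, correct = FALSE)$p.value,
      error = function(e) NA_real_, warning = function(w) {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      })
    data.frame(variable = v, chisq_p = p)
  }))

  structure(list(n = n, arms = arms, mortality = mortality,
                 continuous = cont, categorical = catg,
                 categorical_tests = cat_tests),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n, "\n")
  print(x$arms)
  cat(sprintf("  mortality: RT %.1f%% vs CRT %.1f%% (overall %.1f%%), chi-square p = %.3g\n",
              x$mortality$pct_rt, x$mortality$pct_crt, x$mortality$pct_overall,
              x$mortality$chisq_p))
  invisible(x)
}
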