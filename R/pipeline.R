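#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the cohort source (generator
#' parameters or a CSV path), which model families to fit, the 80/20
#' train/test split, evaluation horizon, hyperparameters, seeds and the
#' output directory. A config can also be loaded from JSON via
#' [read_run_config()].
#'
#' @param generator a [generator_params()] object, or NULL when
#'   `cohort_path` is given.
#' @param cohort_path path to a cohort CSV (see [read_cohort()]).
#' @param kinds model families to run: subset of
#'   `c("cph", "tree", "rsf", "deepsurv", "bites")`.
#' @param split_fraction training fraction (default 0.8), stratified by arm.
#' @param tau evaluation horizon in months (default 60).
#' @param hyper named list of per-kind hyperparameter lists.
#' @param cv_grid optional list of hyper lists for [cv_select()] on the
#'   balanced network (NULL = skip selection, use `hyper$bites`).
#' @param cv_folds folds for cv_select (default 3).
#' @param seed master seed; all stage seeds derive from it.
#' @param n_boot bootstrap resamples for evaluation CIs.
#' @param attribution list: `kinds` (families to explain), `n_patients`,
#'   `n_perm`, `background_size`.
#' @param out_dir output directory.
#' @return object of class `svt_run_config`.
#' @export
run_config <- function(generator = generator_params(),
                       cohort_path = NULL,
                       kinds = c("cph", "bites"),
                       split_fraction = 0.8,
                       tau = 60,
                       hyper = list(),
                       cv_grid = NULL,
                       cv_folds = 3L,
                       seed = 1L,
                       n_boot = 1000L,
                       attribution = list(kinds = character(0),
                                          n_patients = 20L, n_perm = 25L,
                                          background_size = 100L),
                       out_dir = tempfile("svt_run_")) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("run_config: split_fraction must lie in (0, 1)")
  }
  if (tau <= 0) stop("run_config: tau must be positive")
  if (cv_folds < 2L) stop("run_config: cv_folds must be >= 2")
  valid <- c("cph", "tree", "rsf", "deepsurv", "bites")
  if (length(kinds) == 0L || !all(kinds %in% valid)) {
    stop("run_config: kinds must be a non-empty subset of ",
         paste(valid, collapse = "/"))
  }
  if (is.null(generator) && is.null(cohort_path)) {
    stop("run_config: need generator params or a cohort path")
  }
  structure(list(generator = generator, cohort_path = cohort_path,
                 kinds = kinds, split_fraction = split_fraction, tau = tau,
                 hyper = hyper, cv_grid = cv_grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), n_boot = as.integer(n_boot),
                 attribution = attribution, out_dir = out_dir),
            class = "svt_run_config")
}

#' @rdname run_config
#' @param path JSON config file; fields mirror the `run_config()` arguments
#'   (generator parameters as a nested object).
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- if (!is.null(js$generator)) {
    ga <- js$generator
    do.call(generator_params, ga[names(ga) %in% names(formals(generator_params))])
  } else if (is.null(js$cohort_path)) generator_params() else NULL
  args <- js[names(js) %in% setdiff(names(formals(run_config)), "generator")]
  do.call(run_config, c(list(generator = gen), args))
}

#' Stratified train/test split indices
#'
#' Splits by treatment arm so the minority radiotherapy arm is represented in
#' both splits; indices are a deterministic function of the seed.
#'
#' @param cohort a `svt_cohort`.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @return list with `train` and `test` integer index vectors (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(cohort, fraction = 0.8, seed = 1L) {
  set.seed(seed)
  train <- sort(unlist(lapply(0:1, function(a) {
    ia <- which(cohort$treatment == a)
    sample(ia, round(fraction * length(ia)))
  })))
  list(train = train, test = setdiff(seq_len(cohort_size(cohort)), train))
}

log_line <- function(con, stage, msg, ...) {
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage = stage, message = sprintf(msg, ...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  message("[", stage, "] ", rec$message)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' generate/load -> split -> fit every requested model family -> recommend on
#' the held-out test split -> evaluate -> interpret, writing all outputs as
#' CSV/JSON under the configured directory. Rerunning with an identical
#' config reproduces every CSV byte-identically.
#'
#' Outputs: `cohort.csv` (+ `ground_truth.csv`), `split.csv`,
#' `ite_<kind>.csv` per model, `report.csv` (one row per model: HR, adjusted
#' HR, dRMST, NNT, per-arm C-index and IBS), `report.json`,
#' `km_<kind>_<group>.csv` Kaplan-Meier exports, `odds_ratios_<kind>.csv`,
#' `attributions_<kind>.csv` / `rank_matrix_<kind>.csv` when configured, a
#' JSON-lines `log.jsonl`, and `config.json`.
#'
#' @param config a [run_config()].
#' @return the output directory path, invisibly; the parsed report is
#'   attached as attribute `"report"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "svt_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(config$out_dir, "log.jsonl"), open = "wt")
  on.exit(close(logcon), add = TRUE)

  set.seed(config$seed)
  seeds <- as.list(sample.int(.Machine$integer.max - 1L, 8L))
  names(seeds) <- c("split", "fit", "eval", "interpret", "cv", "bg", "unused1", "unused2")
  log_line(logcon, "config", "seed=%d kinds=%s", config$seed,
           paste(config$kinds, collapse = ","))

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_path)) {
      log_line(logcon, "cohort", "reading %s", config$cohort_path)
      read_cohort(config$cohort_path)
    } else {
      log_line(logcon, "cohort", "generating n=%d (generator seed=%d)",
               config$generator$n, config$generator$seed)
      generate_cohort(config$generator)
    }
  })
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"),
               file.path(config$out_dir, "ground_truth.csv"))

  sp <- stage("split", split_cohort(cohort, config$split_fraction, seeds$split))
  utils::write.csv(
    data.frame(index = seq_len(cohort_size(cohort)),
               split = ifelse(seq_len(cohort_size(cohort)) %in% sp$train,
                              "train", "test")),
    file.path(config$out_dir, "split.csv"), row.names = FALSE)
  train <- cohort_subset(cohort, sp$train)
  test <- cohort_subset(cohort, sp$test)
  log_line(logcon, "split", "train=%d test=%d (split seed=%d)",
           length(sp$train), length(sp$test), seeds$split)

  encoder <- build_encoder(train$covariates)

  report_rows <- list()
  json_report <- list()
  for (kind in config$kinds) {
    hy <- if (!is.null(config$hyper[[kind]])) config$hyper[[kind]] else list()
    model <- stage(paste0("fit_", kind), {
      log_line(logcon, paste0("fit_", kind), "fitting (fit seed=%d)", seeds$fit)
      if (kind == "bites") {
        if (!is.null(config$cv_grid)) {
          sel <- cv_select(train, config$cv_grid, folds = config$cv_folds,
                           seed = seeds$cv)
          hy <- sel$best
          log_line(logcon, "cv_select", "selected grid point %d", sel$best_index)
        }
        fit_bites(train, hyper = hy, seed = seeds$fit, encoder = encoder)
      } else {
        fit_tlearner(kind, train, hyper = hy, seed = seeds$fit,
                     encoder = encoder)
      }
    })

    ite <- stage(paste0("recommend_", kind), {
      compute_ite_and_recommend(model, test$covariates, horizon = config$tau,
                                actual = test$treatment)
    })
    ite_out <- cbind(id = sp$test, ite)
    utils::write.csv(format_num_df(ite_out),
                     file.path(config$out_dir, paste0("ite_", kind, ".csv")),
                     row.names = FALSE)

    ev <- stage(paste0("evaluate_", kind), {
      rep <- recommendation_effect(test, ite, tau = config$tau,
                                   n_boot = config$n_boot, seed = seeds$eval,
                                   encoder = encoder)
      wg <- within_group_comparison(test, ite)
      pf <- performance_by_arm(model, test, n_boot = min(config$n_boot, 200L),
                               seed = seeds$eval)
      list(rep = rep, wg = wg, pf = pf)
    })
    log_line(logcon, paste0("evaluate_", kind),
             "HR=%.3f HRa=%.3f dRMST=%.2f NNT=%s",
             ev$rep$hr, ev$rep$hr_adjusted, ev$rep$drmst,
             if (ev$rep$nnt_defined) sprintf("%.2f", ev$rep$nnt) else "NA")

    for (grp in c("consis", "inconsis")) {
      sel <- ite$consistent == as.integer(grp == "consis")
      if (!any(sel)) next
      km <- kaplan_meier(test$time[sel], test$event[sel])
      utils::write.csv(
        format_num_df(data.frame(time = km$times, surv = km$surv, group = grp)),
        file.path(config$out_dir, paste0("km_", kind, "_", grp, ".csv")),
        row.names = FALSE)
    }

    orr <- stage(paste0("odds_ratios_", kind), {
      behavior_odds_ratios(test$covariates, ite$recommended, encoder = encoder)
    })
    if (orr$estimable) {
      utils::write.csv(format_num_df(orr$or_table),
                       file.path(config$out_dir, paste0("odds_ratios_", kind, ".csv")),
                       row.names = FALSE)
    } else {
      writeLines(jsonlite::toJSON(list(estimable = FALSE, reason = orr$reason),
                                  auto_unbox = TRUE),
                 file.path(config$out_dir, paste0("odds_ratios_", kind, ".json")))
    }

    if (kind %in% config$attribution$kinds) {
      stage(paste0("interpret_", kind), {
        att_cfg <- config$attribution
        set.seed(seeds$bg)
        bg_idx <- sample(seq_len(cohort_size(train)),
                         min(att_cfg$background_size, cohort_size(train)))
        pat_idx <- sample(seq_len(cohort_size(test)),
                          min(att_cfg$n_patients, cohort_size(test)))
        bg <- train$covariates[bg_idx, , drop = FALSE]
        atts <- lapply(seq_along(pat_idx), function(k) {
          survshap_t(model, test$covariates[pat_idx[k], , drop = FALSE], bg,
                     arm = 1, mode = "sampled", n_perm = att_cfg$n_perm,
                     seed = seeds$interpret + k)
        })
        long <- do.call(rbind, lapply(seq_along(atts), function(k) {
          a <- atts[[k]]
          data.frame(patient = sp$test[pat_idx[k]],
                     feature = rep(rownames(a$phi), each = length(a$grid)),
                     time = rep(a$grid, times = nrow(a$phi)),
                     value = as.vector(t(a$phi)))
        }))
        utils::write.csv(format_num_df(long),
                         file.path(config$out_dir, paste0("attributions_", kind, ".csv")),
                         row.names = FALSE)
        rm <- aggregate_rankings(atts)
        utils::write.csv(cbind(feature = rownames(rm), as.data.frame(rm)),
                         file.path(config$out_dir, paste0("rank_matrix_", kind, ".csv")),
                         row.names = FALSE)
      })
    }

    report_rows[[kind]] <- data.frame(
      model = kind,
      hr = ev$rep$hr, hr_low = ev$rep$hr_ci[1], hr_high = ev$rep$hr_ci[2],
      hra = ev$rep$hr_adjusted, hra_low = ev$rep$hr_adjusted_ci[1],
      hra_high = ev$rep$hr_adjusted_ci[2],
      drmst = ev$rep$drmst, drmst_low = ev$rep$drmst_ci[1],
      drmst_high = ev$rep$drmst_ci[2],
      nnt = ev$rep$nnt, nnt_low = ev$rep$nnt_ci[1], nnt_high = ev$rep$nnt_ci[2],
      c_index_rt = ev$pf$rt$c_index$estimate, ibs_rt = ev$pf$rt$ibs$estimate,
      c_index_crt = ev$pf$crt$c_index$estimate, ibs_crt = ev$pf$crt$ibs$estimate,
      n_consis = ev$rep$counts[["n_consis"]],
      n_inconsis = ev$rep$counts[["n_inconsis"]],
      n_rrt = ev$rep$counts[["n_rrt"]], n_rcrt = ev$rep$counts[["n_rcrt"]])
    json_report[[kind]] <- list(
      recommendation = ev$rep[c("hr", "hr_ci", "hr_adjusted", "hr_adjusted_ci",
                                "drmst", "drmst_ci", "nnt", "nnt_defined",
                                "nnt_ci", "rmst_consis")],
      counts = as.list(ev$rep$counts),
      within_group = lapply(ev$wg, function(g) {
        g[intersect(names(g), c("n", "testable", "reason", "log_rank_p"))]
      }),
      performance = lapply(ev$pf, function(a) {
        list(n = a$n, c_index = a$c_index, ibs = a$ibs)
      }))
  }

  report <- do.call(rbind, report_rows)
  utils::write.csv(format_num_df(report),
                   file.path(config$out_dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(json_report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE,
                              pretty = TRUE, digits = 10),
             file.path(config$out_dir, "config.json"))
  log_line(logcon, "done", "outputs in %s", config$out_dir)
  structure(invisible(config$out_dir), report = report)
}

# Round-trip-stable numeric formatting so CSV outputs are byte-identical
# across reruns regardless of print options.
format_num_df <- function(df) {
  df[] <- lapply(df, function(x) {
    if (is.numeric(x)) sprintf("%.10g", x) else x
  })
  df
}

config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$generator)) out$generator <- unclass(out$generator)
  out
}
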