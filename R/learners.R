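#' Per-arm survival learners
#'
#' Fits one survival model on a single treatment arm's data. Four families
#' share a common contract (predict a survival curve and a scalar risk score
#' for any encoded row):
#' * `cph` — Cox proportional hazards ([fit_cox()]) with Breslow baseline,
#'   S(t|x) = exp(-H0(t) exp(x'beta));
#' * `tree` — recursive binary partitioning choosing the split with the
#'   largest two-sample log-rank statistic, leaf prediction = leaf
#'   Kaplan-Meier curve;
#' * `rsf` — bootstrap ensemble of such trees with random feature subsets
#'   per split, prediction = ensemble-average cumulative hazard converted to
#'   survival;
#' * `deepsurv` — multilayer perceptron risk score trained by mini-batch
#'   minimization of the negative Cox partial log-likelihood with decoupled
#'   weight decay (AdamW), Breslow baseline on the training risk scores.
#'
#' @param kind one of `"cph"`, `"tree"`, `"rsf"`, `"deepsurv"`.
#' @param X encoded design matrix for the arm's subjects.
#' @param time,event outcome for the arm's subjects.
#' @param hyper named list of hyperparameters (see [default_hyper()]).
#' @param seed integer seed for any stochastic element.
#' @return an arm model (class `svt_arm_<kind>`).
#' @export
fit_arm_model <- function(kind, X, time, event, hyper = list(), seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("fit_arm_model: empty arm")
  if (sum(event) == 0) stop("fit_arm_model: no events in arm")
  hy <- utils::modifyList(default_hyper(kind), hyper)
  switch(kind,
    cph = {
      fit <- fit_cox(X, time, event)
      structure(list(fit = fit, hyper = hy, seed = seed),
                class = c("svt_arm_cph", "svt_arm"))
    },
    tree = {
      tr <- fit_surv_tree(X, time, event, min_leaf = hy$min_leaf,
                          max_depth = hy$max_depth,
                          n_thresholds = hy$n_thresholds, seed = seed)
      structure(list(tree = tr, hyper = hy, seed = seed),
                class = c("svt_arm_tree", "svt_arm"))
    },
    rsf = {
      fo <- fit_surv_forest(X, time, event, n_trees = hy$n_trees,
                            min_leaf = hy$min_leaf, max_depth = hy$max_depth,
                            n_thresholds = hy$n_thresholds, mtry = hy$mtry,
                            bootstrap = hy$bootstrap, seed = seed)
      structure(list(forest = fo, hyper = hy, seed = seed),
                class = c("svt_arm_rsf", "svt_arm"))
    },
    deepsurv = fit_deepsurv_arm(X, time, event, hy, seed),
    stop("fit_arm_model: unknown kind '", kind, "'")
  )
}

#' Default hyperparameters per learner family
#' @param kind learner kind (see [fit_arm_model()]; `"bites"` also allowed).
#' @export
default_hyper <- function(kind) {
  switch(kind,
    cph = list(),
    tree = list(min_leaf = 30, max_depth = 5, n_thresholds = 16),
    rsf = list(n_trees = 200, min_leaf = 30, max_depth = 5, n_thresholds = 16,
               mtry = NULL, bootstrap = TRUE),
    deepsurv = list(layers = c(64, 64), dropout = 0.1, lr = 0.01,
                    weight_decay = 1e-4, batch_size = 256, max_epochs = 100,
                    patience = 10, val_fraction = 0.2),
    bites = list(trunk = c(32, 32), heads = 16, ipm = "mmd_rbf", alpha = 1,
                 lr = 0.01, weight_decay = 1e-4, batch_size = 256,
                 max_epochs = 100, patience = 10, val_fraction = 0.2,
                 dropout = 0, trunk_activation = TRUE),
    stop("unknown kind '", kind, "'")
  )
}

fit_deepsurv_arm <- function(X, time, event, hy, seed) {
  n <- nrow(X)
  sizes <- c(ncol(X), hy$layers, 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  net <- mlp_init(sizes, seed = sub_seeds[1])
  set.seed(sub_seeds[2])
  n_val <- max(1L, round(hy$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (sum(event[tr_idx]) == 0 || length(tr_idx) < 2L) {
    tr_idx <- seq_len(n); val_idx <- seq_len(n)  # tiny data: no held-out val
  }
  Xtr <- X[tr_idx, , drop = FALSE]; Xva <- X[val_idx, , drop = FALSE]

  state <- adamw_init(net)
  best <- list(loss = Inf, net = net, epoch = 0L)
  set.seed(sub_seeds[3])
  log <- data.frame()
  for (epoch in seq_len(hy$max_epochs)) {
    perm <- sample.int(length(tr_idx))
    nb <- max(1L, floor(length(tr_idx) / hy$batch_size))
    batches <- chunk_indices(perm, nb)
    ep_loss <- 0
    for (bidx in batches) {
      rows <- tr_idx[bidx]
      fw <- mlp_forward(net, X[rows, , drop = FALSE],
                        dropout = hy$dropout, training = TRUE)
      cl <- cox_npll_grad(drop(fw$out), time[rows], event[rows])
      bk <- mlp_backward(net, fw$caches, matrix(cl$grad, ncol = 1))
      upd <- adamw_step(net, bk, state, lr = hy$lr,
                        weight_decay = hy$weight_decay)
      net <- upd$net; state <- upd$state
      ep_loss <- ep_loss + cl$loss
    }
    val_r <- drop(mlp_forward(net, Xva)$out)
    val_loss <- cox_npll_grad(val_r, time[val_idx], event[val_idx])$loss
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / length(batches),
                                 val_loss = val_loss))
    if (!is.finite(val_loss)) stop("fit_arm_model(deepsurv): loss diverged")
    if (val_loss < best$loss - 1e-6) best <- list(loss = val_loss, net = net, epoch = epoch)
    if (epoch - best$epoch >= hy$patience) break
  }
  net <- best$net
  risk <- drop(mlp_forward(net, X)$out)
  bl <- breslow_baseline(time, event, risk)
  structure(list(net = net, baseline = bl, hyper = hy, seed = seed, log = log),
            class = c("svt_arm_deepsurv", "svt_arm"))
}

# ---- arm-model contract: risk score and survival matrix on a grid ----

arm_risk <- function(model, X) UseMethod("arm_risk")
#' @export
arm_risk.svt_arm_cph <- function(model, X) {
  if (length(model$fit$beta) == 0L) return(rep(0, nrow(X)))
  drop(as.matrix(X) %*% model$fit$beta)
}
#' @export
arm_risk.svt_arm_deepsurv <- function(model, X) {
  drop(mlp_forward(model$net, as.matrix(X))$out)
}
#' @export
arm_risk.svt_arm_tree <- function(model, X) {
  S <- predict_tree_surv(model$tree, X)
  rowSums(-log(S))  # ensemble "mortality"-style score
}
#' @export
arm_risk.svt_arm_rsf <- function(model, X) {
  S <- predict_forest_surv(model$forest, X)
  rowSums(-log(pmax(S, 1e-12)))
}

# Survival matrix (rows of X by grid) evaluated on an arbitrary grid.
arm_surv <- function(model, X, grid) UseMethod("arm_surv")
#' @export
arm_surv.svt_arm_cph <- function(model, X, grid) {
  eta <- arm_risk(model, X)
  H <- stats::approx(c(0, model$fit$baseline_times),
                     c(0, model$fit$baseline_hazard),
                     xout = grid, method = "constant", rule = 2)$y
  exp(-outer(exp(eta), H))
}
#' @export
arm_surv.svt_arm_deepsurv <- function(model, X, grid) {
  eta <- arm_risk(model, X)
  H <- stats::approx(c(0, model$baseline$times), c(0, model$baseline$hazard),
                     xout = grid, method = "constant", rule = 2)$y
  exp(-outer(exp(eta), H))
}
#' @export
arm_surv.svt_arm_tree <- function(model, X, grid) {
  S <- predict_tree_surv(model$tree, X)
  idx <- findInterval(grid, model$tree$grid)
  cbind(1, S)[, idx + 1L, drop = FALSE]
}
#' @export
arm_surv.svt_arm_rsf <- function(model, X, grid) {
  S <- predict_forest_surv(model$forest, X)
  idx <- findInterval(grid, model$forest$grid)
  cbind(1, S)[, idx + 1L, drop = FALSE]
}

#' Fit a T-learner counterfactual model
#'
#' Fits one arm model per treatment arm, independently, on a shared encoded
#' design. The returned object predicts a survival curve for any in-schema
#' patient under both radiotherapy (arm 0) and chemoradiotherapy (arm 1).
#'
#' @param kind learner family (see [fit_arm_model()]).
#' @param cohort a `svt_cohort` (training data).
#' @param hyper hyperparameter list forwarded to both arm fits.
#' @param seed integer seed (per-arm sub-seeds are derived from it).
#' @param encoder optional pre-built [build_encoder()]; defaults to an
#'   encoder built on the training covariates.
#' @return an object of class `svt_cfmodel`.
#' @export
fit_tlearner <- function(kind, cohort, hyper = list(), seed = 1L,
                         encoder = NULL) {
  stopifnot(inherits(cohort, "svt_cohort"))
  arms <- sort(unique(cohort$treatment))
  if (!identical(as.integer(arms), c(0L, 1L))) {
    stop("fit_tlearner: both treatment arms must be present in training data")
  }
  if (is.null(encoder)) encoder <- build_encoder(cohort$covariates)
  X <- encode_covariates(encoder, cohort$covariates)
  set.seed(seed)
  arm_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  i0 <- cohort$treatment == 0L; i1 <- cohort$treatment == 1L
  m0 <- fit_arm_model(kind, X[i0, , drop = FALSE], cohort$time[i0],
                      cohort$event[i0], hyper, seed = arm_seeds[1])
  m1 <- fit_arm_model(kind, X[i1, , drop = FALSE], cohort$time[i1],
                      cohort$event[i1], hyper, seed = arm_seeds[2])
  grid <- eval_grid(cohort)
  structure(list(arm0 = m0, arm1 = m1, encoder = encoder, grid = grid,
                 kind = kind, seed = seed),
            class = "svt_cfmodel")
}

# Common evaluation grid: union of the two arms' training event times,
# truncated at the 99th percentile of follow-up.
eval_grid <- function(cohort) {
  ut <- sort(unique(cohort$time[cohort$event == 1]))
  cap <- stats::quantile(cohort$time, 0.99)
  g <- ut[ut <= cap]
  if (length(g) == 0L) g <- ut
  g
}

#' Predict counterfactual survival curves
#'
#' Two survival curves per patient, on the model's common evaluation grid:
#' one under radiotherapy alone (arm 0) and one under chemoradiotherapy
#' (arm 1).
#'
#' @param model a `svt_cfmodel`.
#' @param covariates data.frame of in-schema covariate rows.
#' @return list with `rt` and `crt`, each a list of [survival_curve()]s.
#' @export
predict_counterfactual_curves <- function(model, covariates) {
  UseMethod("predict_counterfactual_curves")
}

#' @export
predict_counterfactual_curves.svt_cfmodel <- function(model, covariates) {
  stopifnot(inherits(model, "svt_cfmodel"))
  X <- encode_covariates(model$encoder, covariates)
  S0 <- enforce_monotone(arm_surv(model$arm0, X, model$grid))
  S1 <- enforce_monotone(arm_surv(model$arm1, X, model$grid))
  list(rt = lapply(seq_len(nrow(X)), function(i) survival_curve(model$grid, S0[i, ])),
       crt = lapply(seq_len(nrow(X)), function(i) survival_curve(model$grid, S1[i, ])))
}

enforce_monotone <- function(S) {
  S <- matrix(pmin(pmax(S, 0), 1), nrow = nrow(S))
  if (ncol(S) <= 1L) return(S)
  t(apply(S, 1, cummin))
}

# Survival probability matrix (rows x times) for one arm, on an arbitrary
# time grid. Fast path used by the Shapley explainer (no per-row curve
# objects). The default route goes through predict_counterfactual_curves.
surv_matrix <- function(model, covariates, arm, times) {
  UseMethod("surv_matrix")
}

#' @export
surv_matrix.svt_cfmodel <- function(model, covariates, arm, times) {
  X <- encode_covariates(model$encoder, covariates)
  S <- enforce_monotone(arm_surv(if (arm == 0) model$arm0 else model$arm1,
                                 X, model$grid))
  idx <- findInterval(times, model$grid)
  matrix(cbind(1, S)[, idx + 1L], nrow = nrow(X))
}

#' @export
surv_matrix.default <- function(model, covariates, arm, times) {
  curves <- predict_counterfactual_curves(model, covariates)[[
    if (arm == 0) "rt" else "crt"]]
  S <- t(vapply(curves, function(cv) eval_curve(cv, times), numeric(length(times))))
  matrix(S, nrow = nrow(covariates))
}

#' Predicted risk scores under a given arm
#'
#' Scalar risk score (higher = worse prognosis) from the model component for
#' the requested arm; used for concordance evaluation.
#'
#' @param model a `svt_cfmodel`.
#' @param covariates data.frame of covariate rows.
#' @param arm 0 (RT) or 1 (CRT).
#' @export
predict_arm_risk <- function(model, covariates, arm) {
  UseMethod("predict_arm_risk")
}

#' @export
predict_arm_risk.svt_cfmodel <- function(model, covariates, arm) {
  stopifnot(inherits(model, "svt_cfmodel"), arm %in% c(0, 1))
  X <- encode_covariates(model$encoder, covariates)
  arm_risk(if (arm == 0) model$arm0 else model$arm1, X)
}

#' @export
print.svt_cfmodel <- function(x, ...) {
  cat("<svt_cfmodel> kind =", x$kind, "| grid:", length(x$grid), "times\n")
  invisible(x)
}
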