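#' Integral probability metric between two latent samples
#'
#' Distance between the two treatment arms' latent representation
#' distributions. `mmd_rbf` is the squared maximum mean discrepancy with an
#' RBF kernel and median-heuristic bandwidth (V-statistic form: non-negative,
#' zero on identical multisets, permutation-invariant);
#' `wasserstein_sinkhorn` is the entropic-regularized optimal-transport cost
#' with squared-Euclidean ground cost and uniform marginals.
#'
#' @param rep0,rep1 numeric matrices (rows = subjects, columns = latent
#'   dimensions) for arm 0 and arm 1.
#' @param kind `"mmd_rbf"` or `"wasserstein_sinkhorn"`.
#' @return non-negative scalar.
#' @export
ipm_distance <- function(rep0, rep1, kind = c("mmd_rbf", "wasserstein_sinkhorn")) {
  kind <- match.arg(kind)
  rep0 <- as.matrix(rep0); rep1 <- as.matrix(rep1)
  if (nrow(rep0) == 0L || nrow(rep1) == 0L) stop("ipm_distance: empty representation set")
  if (ncol(rep0) != ncol(rep1)) stop("ipm_distance: dimension mismatch")
  if (kind == "mmd_rbf") {
    max(mmd_rbf(rep0, rep1)$value, 0)
  } else {
    sinkhorn_distance(rep0, rep1)$value
  }
}

ipm_grad <- function(rep0, rep1, kind) {
  if (kind == "mmd_rbf") mmd_rbf(rep0, rep1, grad = TRUE)
  else sinkhorn_distance(rep0, rep1, grad = TRUE)
}

#' Fit the balanced twin-head survival network
#'
#' A shared feature-extraction trunk maps covariates to a latent
#' representation; two Cox-loss risk heads (one per treatment arm) map the
#' latent representation to a risk score; an integral-probability-metric
#' penalty aligns the latent distributions of the two arms. The total loss
#'
#'   L = NPLL_arm0 + NPLL_arm1 + alpha * IPM(phi(X0), phi(X1))
#'
#' (NPLL = negative Cox partial log-likelihood within each arm's mini-batch,
#' Breslow ties, normalized by batch events) is minimized end-to-end with
#' AdamW (decoupled weight decay). Batches are stratified so every batch
#' contains both arms; early stopping monitors the total loss on a held-out
#' validation fraction of the training data; per-arm Breslow baselines are
#' computed from the final risk scores on the training data.
#'
#' @param cohort a `svt_cohort` (training data; both arms, >= 1 event each).
#' @param hyper hyperparameter list, see [default_hyper()]`("bites")`:
#'   `trunk` (hidden sizes, the last is the latent dimension), `heads`
#'   (head hidden sizes), `ipm` kind, `alpha` (IPM weight, >= 0), `lr`,
#'   `weight_decay`, `batch_size`, `max_epochs`, `patience`, `dropout`,
#'   `val_fraction`.
#' @param seed integer seed driving initialization, the train/validation
#'   split and batch shuffling.
#' @param encoder optional shared [build_encoder()].
#' @return a `svt_cfmodel` whose arm components share the trained trunk; the
#'   training log (epoch, per-arm losses, IPM term, validation loss) is in
#'   `$log`.
#' @export
fit_bites <- function(cohort, hyper = list(), seed = 1L, encoder = NULL) {
  stopifnot(inherits(cohort, "svt_cohort"))
  hy <- utils::modifyList(default_hyper("bites"), hyper)
  if (hy$alpha < 0) stop("fit_bites: alpha must be >= 0")
  arms <- sort(unique(cohort$treatment))
  if (!identical(as.integer(arms), c(0L, 1L))) stop("fit_bites: an arm is missing")
  for (a in 0:1) {
    if (sum(cohort$event[cohort$treatment == a]) == 0) {
      stop("fit_bites: no events in arm ", a)
    }
  }
  if (is.null(encoder)) encoder <- build_encoder(cohort$covariates)
  X <- encode_covariates(encoder, cohort$covariates)
  n <- nrow(X)
  time <- cohort$time; event <- cohort$event; arm <- cohort$treatment

  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 1L, 4L)
  latent <- hy$trunk[length(hy$trunk)]
  trunk <- mlp_init(c(ncol(X), hy$trunk), seed = ss[1],
                    act_last = isTRUE(hy$trunk_activation))
  head0 <- mlp_init(c(latent, hy$heads, 1), seed = ss[2])
  head1 <- mlp_init(c(latent, hy$heads, 1), seed = ss[2] + 1L)

  # stratified validation split
  set.seed(ss[3])
  val_idx <- unlist(lapply(0:1, function(a) {
    ia <- which(arm == a)
    sample(ia, max(1L, round(hy$val_fraction * length(ia))))
  }))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (sum(event[tr_idx][arm[tr_idx] == 0]) == 0 ||
      sum(event[tr_idx][arm[tr_idx] == 1]) == 0) {
    tr_idx <- seq_len(n); val_idx <- seq_len(n)
  }

  st_tr <- adamw_init(trunk); st_h0 <- adamw_init(head0); st_h1 <- adamw_init(head1)
  nets <- list(trunk = trunk, head0 = head0, head1 = head1)
  best <- list(loss = Inf, nets = nets, epoch = 0L)
  log <- data.frame()

  val_loss_fn <- function(nets) {
    Z <- mlp_forward(nets$trunk, X[val_idx, , drop = FALSE])$out
    a_v <- arm[val_idx]
    r0 <- drop(mlp_forward(nets$head0, Z[a_v == 0, , drop = FALSE])$out)
    r1 <- drop(mlp_forward(nets$head1, Z[a_v == 1, , drop = FALSE])$out)
    l0 <- cox_npll_grad(r0, time[val_idx][a_v == 0], event[val_idx][a_v == 0])$loss
    l1 <- cox_npll_grad(r1, time[val_idx][a_v == 1], event[val_idx][a_v == 1])$loss
    ip <- if (hy$alpha > 0 && sum(a_v == 0) > 1 && sum(a_v == 1) > 1) {
      ipm_distance(Z[a_v == 0, , drop = FALSE], Z[a_v == 1, , drop = FALSE], hy$ipm)
    } else 0
    c(total = l0 + l1 + hy$alpha * ip, l0 = l0, l1 = l1, ipm = ip)
  }

  set.seed(ss[4])
  for (epoch in seq_len(hy$max_epochs)) {
    # arm-stratified batches: both arms represented in every batch
    i0 <- sample(which(arm[tr_idx] == 0)); i1 <- sample(which(arm[tr_idx] == 1))
    nb <- max(1L, floor(length(tr_idx) / hy$batch_size))
    nb <- min(nb, length(i0), length(i1))
    b0 <- chunk_indices(i0, nb)
    b1 <- chunk_indices(i1, nb)
    ep <- c(l0 = 0, l1 = 0, ipm = 0)
    for (b in seq_len(nb)) {
      rows <- tr_idx[c(b0[[b]], b1[[b]])]
      a_b <- arm[rows]
      fw_t <- mlp_forward(nets$trunk, X[rows, , drop = FALSE],
                          dropout = hy$dropout, training = TRUE)
      Z <- fw_t$out
      w0 <- which(a_b == 0); w1 <- which(a_b == 1)
      Z0 <- Z[w0, , drop = FALSE]; Z1 <- Z[w1, , drop = FALSE]
      fw0 <- mlp_forward(nets$head0, Z0, dropout = hy$dropout, training = TRUE)
      fw1 <- mlp_forward(nets$head1, Z1, dropout = hy$dropout, training = TRUE)
      c0 <- cox_npll_grad(drop(fw0$out), time[rows][w0], event[rows][w0])
      c1 <- cox_npll_grad(drop(fw1$out), time[rows][w1], event[rows][w1])
      bk0 <- mlp_backward(nets$head0, fw0$caches, matrix(c0$grad, ncol = 1))
      bk1 <- mlp_backward(nets$head1, fw1$caches, matrix(c1$grad, ncol = 1))
      dZ <- matrix(0, nrow(Z), ncol(Z))
      dZ[w0, ] <- bk0$gX
      dZ[w1, ] <- bk1$gX
      ipm_val <- 0
      if (hy$alpha > 0 && length(w0) > 1 && length(w1) > 1) {
        ig <- ipm_grad(Z0, Z1, hy$ipm)
        ipm_val <- ig$value
        dZ[w0, ] <- dZ[w0, ] + hy$alpha * ig$g0
        dZ[w1, ] <- dZ[w1, ] + hy$alpha * ig$g1
      }
      bk_t <- mlp_backward(nets$trunk, fw_t$caches, dZ)
      if (!is.finite(c0$loss + c1$loss + ipm_val)) {
        stop("fit_bites: loss diverged (non-finite)")
      }
      u <- adamw_step(nets$trunk, bk_t, st_tr, hy$lr, hy$weight_decay)
      nets$trunk <- u$net; st_tr <- u$state
      u <- adamw_step(nets$head0, bk0, st_h0, hy$lr, hy$weight_decay)
      nets$head0 <- u$net; st_h0 <- u$state
      u <- adamw_step(nets$head1, bk1, st_h1, hy$lr, hy$weight_decay)
      nets$head1 <- u$net; st_h1 <- u$state
      ep <- ep + c(c0$loss, c1$loss, ipm_val)
    }
    vl <- val_loss_fn(nets)
    if (!is.finite(vl["total"])) stop("fit_bites: loss diverged (non-finite)")
    log <- rbind(log, data.frame(
      epoch = epoch, loss_arm0 = ep[["l0"]] / nb, loss_arm1 = ep[["l1"]] / nb,
      ipm = ep[["ipm"]] / nb, val_total = vl[["total"]], val_ipm = vl[["ipm"]]))
    if (vl[["total"]] < best$loss - 1e-6) {
      best <- list(loss = vl[["total"]], nets = nets, epoch = epoch)
    }
    if (epoch - best$epoch >= hy$patience) break
  }
  nets <- best$nets

  Zall <- mlp_forward(nets$trunk, X)$out
  r_all0 <- drop(mlp_forward(nets$head0, Zall)$out)
  r_all1 <- drop(mlp_forward(nets$head1, Zall)$out)
  i0 <- arm == 0; i1 <- arm == 1
  bl0 <- breslow_baseline(time[i0], event[i0], r_all0[i0])
  bl1 <- breslow_baseline(time[i1], event[i1], r_all1[i1])

  mk_arm <- function(head, bl) {
    structure(list(trunk = nets$trunk, head = head, baseline = bl, hyper = hy),
              class = c("svt_arm_bites", "svt_arm"))
  }
  structure(list(arm0 = mk_arm(nets$head0, bl0), arm1 = mk_arm(nets$head1, bl1),
                 encoder = encoder, grid = eval_grid(cohort), kind = "bites",
                 seed = seed, hyper = hy, log = log),
            class = "svt_cfmodel")
}

#' @export
arm_risk.svt_arm_bites <- function(model, X) {
  Z <- mlp_forward(model$trunk, as.matrix(X))$out
  drop(mlp_forward(model$head, Z)$out)
}

#' @export
arm_surv.svt_arm_bites <- function(model, X, grid) {
  eta <- arm_risk(model, X)
  H <- stats::approx(c(0, model$baseline$times), c(0, model$baseline$hazard),
                     xout = grid, method = "constant", rule = 2)$y
  exp(-outer(exp(eta), H))
}

#' Latent representations from a fitted balanced network
#'
#' @param model a `svt_cfmodel` of kind `"bites"`.
#' @param covariates covariate rows.
#' @return matrix of latent representations.
#' @export
bites_representation <- function(model, covariates) {
  stopifnot(identical(model$kind, "bites"))
  X <- encode_covariates(model$encoder, covariates)
  mlp_forward(model$arm0$trunk, X)$out
}

#' Cross-validated hyperparameter selection for the balanced network
#'
#' 3-fold cross-validation stratified by treatment arm: each grid point is
#' trained on two folds and scored by the mean held-out concordance index
#' (computed per arm on the fold's subjects under their actual arm, then
#' averaged). Grid points whose training diverges are flagged and never
#' selected. Ties break toward smaller IPM weight `alpha`, then toward the
#' smaller network (total hidden units).
#'
#' @param cohort training `svt_cohort`.
#' @param grid list of hyperparameter lists (each as in [fit_bites()]).
#' @param folds number of folds (default 3).
#' @param seed integer seed; fold assignment is a deterministic function of it.
#' @return list with `best` (the winning hyper list) and `scores`
#'   (data.frame of per-point mean scores; NA = flagged).
#' @export
cv_select <- function(cohort, grid, folds = 3L, seed = 1L) {
  if (length(grid) == 0L) stop("cv_select: empty grid")
  n <- cohort_size(cohort)
  set.seed(seed)
  fold_id <- integer(n)
  for (a in 0:1) {
    ia <- which(cohort$treatment == a)
    fold_id[ia] <- sample(rep_len(seq_len(folds), length(ia)))
  }
  scores <- vapply(seq_along(grid), function(gi) {
    hy <- grid[[gi]]
    fold_scores <- vapply(seq_len(folds), function(f) {
      tr <- cohort_subset(cohort, fold_id != f)
      va <- cohort_subset(cohort, fold_id == f)
      fit <- tryCatch(fit_bites(tr, hyper = hy, seed = seed + f),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      cs <- vapply(0:1, function(a) {
        ia <- va$treatment == a
        if (sum(va$event[ia]) == 0) return(NA_real_)
        r <- predict_arm_risk(fit, va$covariates[ia, , drop = FALSE], a)
        tryCatch(concordance_index(r, va$time[ia], va$event[ia]),
                 error = function(e) NA_real_)
      }, numeric(1))
      mean(cs, na.rm = TRUE)
    }, numeric(1))
    if (any(is.na(fold_scores))) NA_real_ else mean(fold_scores)
  }, numeric(1))

  if (all(is.na(scores))) stop("cv_select: every grid point failed")
  alpha_of <- vapply(grid, function(h) {
    hh <- utils::modifyList(default_hyper("bites"), h); hh$alpha
  }, numeric(1))
  size_of <- vapply(grid, function(h) {
    hh <- utils::modifyList(default_hyper("bites"), h)
    sum(hh$trunk) + sum(hh$heads)
  }, numeric(1))
  ord <- order(-ifelse(is.na(scores), -Inf, scores), alpha_of, size_of)
  best_i <- ord[1]
  list(best = grid[[best_i]], best_index = best_i,
       scores = data.frame(point = seq_along(grid), score = scores,
                           alpha = alpha_of, size = size_of))
}
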