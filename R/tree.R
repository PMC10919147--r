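# Survival tree with log-rank splitting and leaf Kaplan-Meier estimates,
# plus the bootstrap ensemble (random survival forest) built on it.

# Two-sample log-rank chi-square for a candidate split, on rows pre-sorted
# by time. O(n) given the sort; used in the split search inner loop.
lr_stat_sorted <- function(time_s, event_s, member_s) {
  n <- length(time_s)
  first <- match(time_s, time_s)
  at_all <- n - first + 1
  at_grp <- rev(cumsum(rev(member_s)))[first]
  block <- first[event_s == 1]
  if (length(block) == 0L) return(0)
  d <- tabulate(block, nbins = n)
  d1 <- numeric(n)
  ev1 <- event_s == 1 & member_s
  if (any(ev1)) {
    t1 <- tabulate(first[ev1], nbins = n)
    d1 <- t1
  }
  ub <- unique(block)
  N <- at_all[ub]; N1 <- at_grp[ub]; dd <- d[ub]; dd1 <- d1[ub]
  O <- sum(dd1)
  E <- sum(dd * N1 / N)
  ok <- N > 1
  V <- sum((dd * (N1 / N) * (1 - N1 / N) * (N - dd) / (N - 1))[ok])
  if (V <= 0) 0 else (O - E)^2 / V
}

# Candidate thresholds for one column: midpoints of up to n_thresholds
# quantile cuts (a single 0.5 cut for 0/1 dummies).
split_candidates <- function(x, n_thresholds) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(numeric(0))
  if (length(ux) == 2L) return(mean(ux))
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  if (length(mids) > n_thresholds) {
    mids <- unique(stats::quantile(mids, probs = seq_len(n_thresholds) /
                                     (n_thresholds + 1), type = 1))
  }
  mids
}

grow_node <- function(X, time, event, depth, ctrl, rng_seed) {
  n <- nrow(X)
  km <- kaplan_meier(time, event)
  leaf <- function() {
    s <- pmax(eval_curve(km, ctrl$grid), 1e-12)
    list(is_leaf = TRUE, surv = s, n = n)
  }
  if (depth >= ctrl$max_depth || n < 2 * ctrl$min_leaf || sum(event) < 2) {
    return(leaf())
  }
  p <- ncol(X)
  feats <- seq_len(p)
  if (!is.null(ctrl$mtry) && ctrl$mtry < p) {
    set.seed(rng_seed)
    feats <- sort(sample.int(p, ctrl$mtry))
  }
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  best <- list(stat = 0, var = NA_integer_, val = NA_real_)
  for (j in feats) {
    xj <- X[, j]
    for (thr in split_candidates(xj, ctrl$n_thresholds)) {
      m <- xj <= thr
      nl <- sum(m)
      if (nl < ctrl$min_leaf || n - nl < ctrl$min_leaf) next
      s <- lr_stat_sorted(t_s, e_s, m[ord])
      if (s > best$stat + 1e-12) best <- list(stat = s, var = j, val = thr)
    }
  }
  if (is.na(best$var) || best$stat <= ctrl$min_split_stat) return(leaf())
  m <- X[, best$var] <= best$val
  list(is_leaf = FALSE, var = best$var, val = best$val, stat = best$stat, n = n,
       left = grow_node(X[m, , drop = FALSE], time[m], event[m],
                        depth + 1, ctrl, rng_seed * 2L %% 2147483629L + 1L),
       right = grow_node(X[!m, , drop = FALSE], time[!m], event[!m],
                         depth + 1, ctrl, rng_seed * 2L %% 2147483629L + 2L))
}

# Fit a survival tree. The tree stores leaf survival on the grid of distinct
# training event times; predictions route rows to leaves.
fit_surv_tree <- function(X, time, event, min_leaf = 30, max_depth = 5,
                          n_thresholds = 16, mtry = NULL, seed = 1L,
                          min_split_stat = 0) {
  X <- as.matrix(X)
  grid <- sort(unique(time[event == 1]))
  if (length(grid) == 0L) stop("fit_surv_tree: no events")
  ctrl <- list(min_leaf = min_leaf, max_depth = max_depth,
               n_thresholds = n_thresholds, mtry = mtry, grid = grid,
               min_split_stat = min_split_stat)
  root <- grow_node(X, time, event, 0L, ctrl, as.integer(seed))
  structure(list(root = root, grid = grid, p = ncol(X),
                 colnames = colnames(X)),
            class = "svt_tree")
}

tree_leaf_surv <- function(node, x) {
  while (!node$is_leaf) {
    node <- if (x[node$var] <= node$val) node$left else node$right
  }
  node$surv
}

# Survival matrix (rows x grid) for a fitted tree.
predict_tree_surv <- function(tree, X) {
  X <- as.matrix(X)
  S <- vapply(seq_len(nrow(X)),
              function(i) tree_leaf_surv(tree$root, X[i, ]),
              numeric(length(tree$grid)))
  matrix(t(S), nrow = nrow(X))
}

fit_surv_forest <- function(X, time, event, n_trees = 200, min_leaf = 30,
                            max_depth = 5, n_thresholds = 16, mtry = NULL,
                            bootstrap = TRUE, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, n_trees)
  grid <- sort(unique(time[event == 1]))
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    set.seed(tree_seeds[b])
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    tr <- fit_surv_tree(X[idx, , drop = FALSE], time[idx], event[idx],
                        min_leaf = min_leaf, max_depth = max_depth,
                        n_thresholds = n_thresholds, mtry = mtry,
                        seed = tree_seeds[b])
    trees[[b]] <- tr
  }
  structure(list(trees = trees, grid = grid, p = p, colnames = colnames(X)),
            class = "svt_forest")
}

# Ensemble-average cumulative hazard on the forest grid, converted back to
# survival: S = exp(-mean_b H_b(t)).
predict_forest_surv <- function(forest, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  Hsum <- matrix(0, n, length(forest$grid))
  for (tr in forest$trees) {
    S <- predict_tree_surv(tr, X)
    # each tree's own grid -> forest grid by step interpolation of H
    Htr <- -log(S)
    idx <- findInterval(forest$grid, tr$grid)
    H_on_grid <- cbind(0, Htr)[, idx + 1L, drop = FALSE]
    Hsum <- Hsum + H_on_grid
  }
  exp(-Hsum / length(forest$trees))
}
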