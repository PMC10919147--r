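# Minimal feed-forward network machinery for the Cox-loss learners.
# Everything is plain matrix algebra so that training is deterministic given
# the seed and portable (no compiled-framework dependency). Layers use
# SELU activations with Lecun-normal initialization; the final layer is
# linear unless act_last = TRUE (used for the representation trunk).

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
selu_grad <- function(x) SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))

mlp_init <- function(sizes, seed, act_last = FALSE) {
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  set.seed(seed)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = 1 / sqrt(sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes, act_last = act_last)
}

# Forward pass. Returns the output and the caches needed for backprop.
# Dropout is inverted dropout applied to activated layers while training;
# the caller controls the RNG stream.
mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  A <- X
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% net$W[[l]], 2, net$b[[l]], "+")
    activated <- l < L || net$act_last
    out <- if (activated) selu(Z) else Z
    mask <- NULL
    if (activated && training && dropout > 0) {
      mask <- matrix(stats::rbinom(length(out), 1, 1 - dropout) / (1 - dropout),
                     nrow = nrow(out))
      out <- out * mask
    }
    caches[[l]] <- list(A_in = A, Z = Z, activated = activated, mask = mask)
    A <- out
  }
  list(out = A, caches = caches)
}

# Backward pass from dOut (gradient of the loss wrt the network output).
mlp_backward <- function(net, caches, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    cc <- caches[[l]]
    if (cc$activated) {
      if (!is.null(cc$mask)) dA <- dA * cc$mask
      dZ <- dA * selu_grad(cc$Z)
    } else dZ <- dA
    gW[[l]] <- crossprod(cc$A_in, dZ)
    gb[[l]] <- colSums(dZ)
    dA <- dZ %*% t(net$W[[l]])
  }
  list(gW = gW, gb = gb, gX = dA)
}

adamw_init <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0),
       t = 0L)
}

# One AdamW step: Adam moments on the gradients, weight decay applied
# directly to the weights (decoupled; biases are not decayed).
adamw_step <- function(net, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * ((state$mW[[l]] / bc1) /
      (sqrt(state$vW[[l]] / bc2) + eps) + weight_decay * net$W[[l]])
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / bc1) /
      (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

# Negative Cox partial log-likelihood (Breslow ties) of risk scores r on a
# batch, normalized by the number of events, with its gradient wrt r.
cox_npll_grad <- function(r, time, event) {
  d <- sum(event)
  if (d == 0) return(list(loss = 0, grad = numeric(length(r))))
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]; r_s <- r[o]
  er <- exp(r_s)
  tail_sum <- rev(cumsum(rev(er)))
  first_idx <- match(t_s, t_s)            # first row of each tied time block
  S <- tail_sum[first_idx]                # risk-set sum at each row's time
  loss <- -sum(e_s * (r_s - log(S))) / d
  last_idx <- findInterval(t_s, t_s)      # last row with time <= this row's
  H <- cumsum(e_s / S)                    # event-driven cumulative 1/S
  cum <- H[last_idx]
  g_s <- (er * cum - e_s) / d
  grad <- numeric(length(r))
  grad[o] <- g_s
  list(loss = loss, grad = grad)
}

# Split a (permuted) index vector into nb contiguous chunks.
chunk_indices <- function(v, nb) {
  nb <- max(1L, min(nb, length(v)))
  grp <- rep(seq_len(nb), each = ceiling(length(v) / nb))[seq_along(v)]
  unname(split(v, grp))
}

pairwise_sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

# Median-heuristic RBF bandwidth on the pooled sample (sigma^2 = median
# pairwise squared distance / 2, floored away from zero).
mmd_bandwidth <- function(Z0, Z1) {
  Z <- rbind(Z0, Z1)
  n <- nrow(Z)
  if (n > 400) Z <- Z[round(seq(1, n, length.out = 400)), , drop = FALSE]
  d2 <- pairwise_sqdist(Z, Z)
  m <- stats::median(d2[upper.tri(d2)])
  max(m / 2, 1e-12)
}

# Squared MMD with RBF kernel, optionally with gradients wrt the two
# representation matrices (bandwidth treated as a constant). The default is
# the V-statistic (full-mean) estimator: it is non-negative, vanishes
# exactly on identical multisets in any order, and is a pure set function --
# the properties the balancing penalty and its tests rely on. The U-statistic
# variant (off-diagonal within-means) is available via unbiased = TRUE but
# can be negative and is not zero on identical multisets.
mmd_rbf <- function(Z0, Z1, sigma2 = NULL, grad = FALSE, unbiased = FALSE) {
  n0 <- nrow(Z0); n1 <- nrow(Z1)
  if (is.null(sigma2)) sigma2 <- mmd_bandwidth(Z0, Z1)
  K00 <- exp(-pairwise_sqdist(Z0, Z0) / (2 * sigma2))
  K11 <- exp(-pairwise_sqdist(Z1, Z1) / (2 * sigma2))
  K01 <- exp(-pairwise_sqdist(Z0, Z1) / (2 * sigma2))
  if (unbiased) {
    w00 <- if (n0 > 1) 1 / (n0 * (n0 - 1)) else 0
    w11 <- if (n1 > 1) 1 / (n1 * (n1 - 1)) else 0
    value <- w00 * (sum(K00) - sum(diag(K00))) +
             w11 * (sum(K11) - sum(diag(K11))) -
             2 * mean(K01)
  } else {
    w00 <- 1 / n0^2
    w11 <- 1 / n1^2
    value <- w00 * sum(K00) + w11 * sum(K11) - 2 * mean(K01)
  }
  if (!grad) return(list(value = value, sigma2 = sigma2))
  diag(K00) <- 0; diag(K11) <- 0  # diagonal gradient terms vanish anyway
  g0 <- (2 * w00 / sigma2) * (K00 %*% Z0 - rowSums(K00) * Z0) -
        (2 / (n0 * n1 * sigma2)) * (K01 %*% Z1 - rowSums(K01) * Z0)
  g1 <- (2 * w11 / sigma2) * (K11 %*% Z1 - rowSums(K11) * Z1) -
        (2 / (n0 * n1 * sigma2)) * (t(K01) %*% Z0 - colSums(K01) * Z1)
  list(value = value, sigma2 = sigma2, g0 = g0, g1 = g1)
}

# Entropic-regularized (Sinkhorn) transport cost between two point clouds
# with uniform marginals and squared-Euclidean ground cost. The gradient is
# the envelope gradient at the converged plan.
sinkhorn_distance <- function(Z0, Z1, epsilon = 0.1, max_iter = 200,
                              tol = 1e-9, grad = FALSE) {
  n0 <- nrow(Z0); n1 <- nrow(Z1)
  C <- pairwise_sqdist(Z0, Z1)
  K <- exp(-C / epsilon)
  a <- rep(1 / n0, n0); b <- rep(1 / n1, n1)
  u <- rep(1, n0)
  v <- rep(1, n1)
  for (it in seq_len(max_iter)) {
    u_new <- a / pmax(K %*% v, 1e-300)
    v_new <- b / pmax(t(K) %*% u_new, 1e-300)
    if (max(abs(u_new - u)) < tol && max(abs(v_new - v)) < tol) {
      u <- u_new; v <- v_new; break
    }
    u <- u_new; v <- v_new
  }
  P <- diag(as.numeric(u)) %*% K %*% diag(as.numeric(v))
  value <- sum(P * C)
  if (!grad) return(list(value = value))
  # d/dZ0_i sum_j P_ij |z_i - y_j|^2 = 2 (z_i sum_j P_ij - sum_j P_ij y_j)
  g0 <- 2 * (rowSums(P) * Z0 - P %*% Z1)
  g1 <- 2 * (colSums(P) * Z1 - t(P) %*% Z0)
  list(value = value, g0 = g0, g1 = g1)
}
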