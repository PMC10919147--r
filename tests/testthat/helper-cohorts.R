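# Shared fixture builders. Everything is generated in code at test time.

# A minimal two-covariate cohort with a simple exponential PH law:
# lambda(x, arm) = exp(b_a * a + b_b * b + off * arm) / 12. Used where the
# full registry schema would only slow the test down.
make_simple_cohort <- function(n = 500, seed = 1, b_a = 0.8, b_b = 0,
                               crt_offset = -0.5, cens_prob = 0.15,
                               p_crt = 0.5) {
  set.seed(seed)
  cov <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
  arm <- stats::rbinom(n, 1, p_crt)
  lp <- b_a * cov$a + b_b * cov$b + crt_offset * arm
  tme <- stats::rexp(n, exp(lp) / 12)
  ev <- stats::rbinom(n, 1, 1 - cens_prob)
  structure(list(covariates = cov, treatment = arm,
                 time = pmax(tme, 1e-4), event = ev, ground_truth = NULL),
            class = "svt_cohort")
}

# The worked 3-subject censored example: times 2 (event), 4 (censored),
# 6 (event); product-limit gives S(2) = 2/3, S(6) = 1/3.
km_hand_example <- function() {
  list(time = c(2, 4, 6), event = c(1, 0, 1))
}

# Small default-schema cohort (registry generator) shared across tests.
small_registry_cohort <- function(n = 1500, seed = 42) {
  generate_cohort(generator_params(n = n, seed = seed))
}

# Brute-force Harrell concordance: explicit double loop over ordered pairs,
# independent of the package's vectorized implementation.
cindex_bruteforce <- function(risk, time, event) {
  conc <- 0; tot <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      tot <- tot + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / tot
}

# Cox partial log-likelihood (Breslow ties) evaluated directly from its
# definition; used by the grid-search oracle.
cox_pll_direct <- function(beta, x, time, event) {
  eta <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    ll <- ll + eta[i] - log(sum(exp(eta[time >= time[i]])))
  }
  ll
}
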