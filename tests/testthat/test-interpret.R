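# Fixture: small 3-covariate cohort and a Cox T-learner over it.
shap_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(61)
      n <- 500
      cov <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
      arm <- rbinom(n, 1, 0.5)
      lp <- 0.9 * cov$a + 0.4 * cov$b + 0 * cov$c - 0.4 * arm
      co <- structure(list(covariates = cov, treatment = arm,
                           time = pmax(rexp(n, exp(lp) / 12), 1e-4),
                           event = rbinom(n, 1, 0.85), ground_truth = NULL),
                      class = "svt_cohort")
      m <- fit_tlearner("cph", co, seed = 62)
      cache <<- list(co = co, m = m)
    }
    cache
  }
})

test_that("exact survshap satisfies local accuracy and nulls ignored features", {
  fx <- shap_fixture()
  m <- fx$m
  # make feature c a provable null player: zero its coefficient in both arms
  m$arm0$fit$beta["c"] <- 0
  m$arm1$fit$beta["c"] <- 0
  x <- fx$co$covariates[1, , drop = FALSE]
  bg <- fx$co$covariates[2:51, ]
  att <- survshap_t(m, x, bg, arm = 1, mode = "exact")
  resid <- att$baseline + colSums(att$phi) - att$prediction
  expect_lt(max(abs(resid)), 1e-6)
  expect_true(all(att$phi["c", ] == 0))
  expect_gt(max(abs(att$phi["a", ])), 0)
})

test_that("exact mode matches brute-force coalition enumeration (2 features)", {
  set.seed(63)
  n <- 300
  cov <- data.frame(a = rnorm(n), b = rnorm(n))
  arm <- rbinom(n, 1, 0.5)
  lp <- 0.8 * cov$a - 0.5 * cov$b
  co <- structure(list(covariates = cov, treatment = arm,
                       time = pmax(rexp(n, exp(lp) / 12), 1e-4),
                       event = rep(1L, n), ground_truth = NULL),
                  class = "svt_cohort")
  m <- fit_tlearner("cph", co, seed = 64)
  x <- cov[1, , drop = FALSE]
  bg <- cov[2:31, ]
  grid <- c(3, 9, 18)
  att <- survshap_t(m, x, bg, arm = 1, mode = "exact", grid = grid)

  # independent enumeration of all 4 coalitions straight from the definition
  v <- function(members) {
    df <- bg
    for (f in members) df[[f]] <- rep(x[[f]], nrow(bg))
    colMeans(survite:::surv_matrix(m, df, 1, grid))
  }
  v00 <- v(character(0)); vA <- v("a"); vB <- v("b"); vAB <- v(c("a", "b"))
  phi_a <- 0.5 * (vA - v00) + 0.5 * (vAB - vB)
  phi_b <- 0.5 * (vB - v00) + 0.5 * (vAB - vA)
  expect_equal(unname(att$phi["a", ]), unname(phi_a), tolerance = 1e-12)
  expect_equal(unname(att$phi["b", ]), unname(phi_b), tolerance = 1e-12)
})

test_that("symmetric features receive identical attributions in exact mode", {
  fx <- shap_fixture()
  m <- fx$m
  # force a and b to play interchangeable roles
  m$arm1$fit$beta["a"] <- 0.5
  m$arm1$fit$beta["b"] <- 0.5
  x <- data.frame(a = 1.2, b = 1.2, c = 0.3)
  bg <- fx$co$covariates[2:41, ]
  bg$b <- bg$a  # identical marginal background distributions
  # symmetric players also need the same encoding scale
  m$encoder$spec$b <- m$encoder$spec$a
  att <- survshap_t(m, x, bg, arm = 1, mode = "exact")
  expect_equal(att$phi["a", ], att$phi["b", ], tolerance = 1e-10)
})

test_that("sampled attributions converge toward exact values", {
  fx <- shap_fixture()
  x <- fx$co$covariates[3, , drop = FALSE]
  bg <- fx$co$covariates[4:33, ]
  exact <- survshap_t(fx$m, x, bg, arm = 1, mode = "exact")
  err <- function(n_perm) {
    s <- survshap_t(fx$m, x, bg, arm = 1, mode = "sampled",
                    n_perm = n_perm, seed = 7)
    max(abs(s$phi - exact$phi))
  }
  e200 <- err(200); e800 <- err(800)
  expect_lt(e800, e200 + 1e-9)
  # sampled mode preserves local accuracy exactly (telescoping sums)
  s <- survshap_t(fx$m, x, bg, arm = 1, mode = "sampled", n_perm = 50, seed = 8)
  expect_lt(max(abs(s$baseline + colSums(s$phi) - s$prediction)), 1e-10)
})

test_that("survshap_t guards its preconditions", {
  fx <- shap_fixture()
  x <- fx$co$covariates[1, , drop = FALSE]
  expect_error(survshap_t(fx$m, x, fx$co$covariates[0, ]), "empty background")
  wide <- as.data.frame(matrix(rnorm(13), nrow = 1,
                               dimnames = list(NULL, paste0("f", 1:13))))
  expect_error(survshap_t(fx$m, wide, rbind(wide, wide), mode = "exact"),
               "at most 12")
})

test_that("aggregate_rankings tabulates one permutation per patient", {
  fx <- shap_fixture()
  bg <- fx$co$covariates[2:31, ]
  atts <- lapply(3:7, function(i) {
    survshap_t(fx$m, fx$co$covariates[i, , drop = FALSE], bg, arm = 1,
               mode = "sampled", n_perm = 20, seed = i)
  })
  M <- aggregate_rankings(atts)
  expect_equal(unname(colSums(M)), rep(5L, 3))
  expect_equal(unname(rowSums(M)), rep(5L, 3))
  # single patient: a permutation matrix
  M1 <- aggregate_rankings(atts[1])
  expect_true(all(M1 %in% c(0L, 1L)))
  expect_equal(unname(colSums(M1)), rep(1L, 3))
  # identical attributions concentrate each feature in one rank column
  M2 <- aggregate_rankings(list(atts[[2]], atts[[2]], atts[[2]]))
  expect_true(all(apply(M2, 1, max) == 3))
})

test_that("a dominant coefficient wins the first rank almost always", {
  set.seed(71)
  n <- 600
  cov <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  arm <- rbinom(n, 1, 0.5)
  lp <- 2.0 * cov$a + 0.2 * cov$b + 0.2 * cov$c
  co <- structure(list(covariates = cov, treatment = arm,
                       time = pmax(rexp(n, exp(lp) / 12), 1e-4),
                       event = rep(1L, n), ground_truth = NULL),
                  class = "svt_cohort")
  m <- fit_tlearner("cph", co, seed = 72)
  bg <- cov[1:30, ]
  atts <- lapply(31:130, function(i) {
    survshap_t(m, cov[i, , drop = FALSE], bg, arm = 1, mode = "sampled",
               n_perm = 10, seed = i)
  })
  M <- aggregate_rankings(atts)
  expect_gte(M["a", "rank1"], 95)
})

test_that("behavior_odds_ratios: null calibration, driver recovery, flags", {
  set.seed(81)
  n <- 5000
  cov <- data.frame(age = rnorm(n, 60, 10), size = rnorm(n, 45, 15),
                    sex = factor(sample(c("f", "m"), n, TRUE)))
  # recommendations independent of covariates
  rec <- rbinom(n, 1, 0.5)
  br <- behavior_odds_ratios(cov, rec)
  expect_true(br$estimable)
  covered <- with(br$or_table, or_low <= 1 & 1 <= or_high)
  expect_gte(mean(covered), 0.9)

  # age-thresholded recommender: age OR < 1 excluding 1, others cover 1
  rec2 <- as.integer(cov$age < 65)
  # add noise so the fit is not separated
  flip <- rbinom(n, 1, 0.1) == 1
  rec2[flip] <- 1L - rec2[flip]
  br2 <- behavior_odds_ratios(cov, rec2)
  tab <- br2$or_table
  expect_lt(tab$or_high[tab$term == "age"], 1)
  others <- tab[tab$term != "age", ]
  expect_true(all(others$or_low <= 1 & 1 <= others$or_high))

  # degenerate: everyone recommended CRT
  br3 <- behavior_odds_ratios(cov, rep(1L, n))
  expect_false(br3$estimable)
})
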