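test_that("a null propensity model has chance-level discrimination", {
  set.seed(1)
  n <- 5000
  x <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.4))
  tr <- rbinom(n, 1, 0.1)
  fit <- fit_propensity(x, tr)
  expect_lt(abs(fit$in_sample_auc - 0.5), 0.05)
  expect_true(all(fit$scores > 0 & fit$scores < 1))
})

test_that("one strong covariate drives near-perfect discrimination", {
  set.seed(2)
  n <- 2000
  x <- data.frame(a = rnorm(n))
  tr <- rbinom(n, 1, plogis(-2 + 4 * x$a))
  fit <- fit_propensity(x, tr)
  expect_gt(fit$in_sample_auc, 0.9)
})

test_that("logistic coefficients are recovered within 2 SE at n = 20,000", {
  set.seed(3)
  n <- 20000
  x <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.3), c = runif(n))
  beta <- c(`(Intercept)` = -2, a = 0.8, b = -0.5, c = 1.2)
  eta <- beta[1] + as.matrix(x) %*% beta[-1]
  tr <- rbinom(n, 1, plogis(eta))
  fit <- fit_propensity(x, tr)
  se <- sqrt(diag(vcov(fit$model)))
  expect_true(all(abs(fit$coefficients - beta) <= 2 * se))
})

test_that("degenerate propensity inputs are rejected", {
  x <- data.frame(a = c(1, 2, NA))
  expect_error(fit_propensity(x, c(0, 1, 0)), "missing")
  expect_error(fit_propensity(data.frame(a = 1:4), rep(1, 4)), "at least one")
  # aliased column reported by name
  x2 <- data.frame(a = rnorm(50), b = 0)
  x2$c <- x2$a * 2
  tr <- rep(c(0, 1), 25)
  expect_error(fit_propensity(x2, tr), "aliased")
})

test_that("nearest-neighbor matching picks the closest control", {
  # treated at 0.30 against controls 0.10 / 0.28 / 0.90 -> 0.28
  scores <- c(0.30, 0.10, 0.28, 0.90)
  tr <- c(1, 0, 0, 0)
  pairs <- match_nn_replacement(scores, tr)
  expect_equal(pairs$treated, 1)
  expect_equal(pairs$control, 3)
})

test_that("controls are reused under matching with replacement", {
  scores <- c(0.5, 0.5, 0.4)
  tr <- c(1, 1, 0)
  pairs <- match_nn_replacement(scores, tr)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$control, c(3, 3))
  expect_error(match_nn_replacement(c(0.5), c(1)), "no control")
})

test_that("equidistant controls resolve to the lowest index", {
  # 0.25 and 0.75 are exactly representable, so the distances to 0.5 tie
  pairs <- match_nn_replacement(c(0.5, 0.25, 0.75), c(1, 0, 0))
  expect_equal(pairs$control, 2)
  # swap the controls' positions: still the lowest index (now 0.75)
  pairs2 <- match_nn_replacement(c(0.5, 0.75, 0.25), c(1, 0, 0))
  expect_equal(pairs2$control, 2)
  # several controls sharing the nearest score: lowest index again
  pairs3 <- match_nn_replacement(c(0.5, 0.25, 0.25, 0.25), c(1, 0, 0, 0))
  expect_equal(pairs3$control, 2)
})

test_that("matching agrees with exhaustive search on small problems", {
  for (case in 1:40) {
    set.seed(case)
    n <- sample(3:12, 1)
    tr <- integer(n)
    tr[sample(n, sample(1:(n - 1), 1))] <- 1L
    if (all(tr == 1)) tr[1] <- 0L
    scores <- round(runif(n), 2)   # rounding forces frequent ties
    got <- match_nn_replacement(scores, tr)
    want <- oracle_nn_match(scores, tr)
    expect_equal(got$treated, want$treated)
    expect_equal(got$control, want$control)
  }
})

test_that("matching is idempotent on identical input", {
  set.seed(7)
  scores <- runif(300)
  tr <- rbinom(300, 1, 0.2)
  expect_identical(match_nn_replacement(scores, tr),
                   match_nn_replacement(scores, tr))
})

test_that("standardized differences reproduce reference balance values", {
  expect_equal(standardized_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  # continuous: age 76.5 (SD 6.8) vs 74.3 (SD 6.4) -> 0.33
  expect_equal(round(std_diff_moments(76.5, 6.8, 74.3, 6.4), 2), 0.33)
  # binary: rates 40.6% vs 43.8% -> -0.06
  expect_equal(round(std_diff_rates(0.406, 0.438), 2), -0.06)
  # sample-based path agrees with the moment formulas
  set.seed(8)
  xt <- rnorm(500, 1, 2)
  xc <- rnorm(400, 0.5, 2)
  expect_equal(standardized_difference(xt, xc),
               std_diff_moments(mean(xt), sd(xt), mean(xc), sd(xc)))
  bt <- rbinom(500, 1, 0.4)
  bc <- rbinom(400, 1, 0.3)
  expect_equal(standardized_difference(bt, bc),
               std_diff_rates(mean(bt), mean(bc)))
  # degenerate: equal constant samples -> 0; unequal constants -> error
  expect_equal(standardized_difference(c(2, 2), c(2, 2)), 0)
  expect_error(standardized_difference(c(2, 2), c(3, 3)), "degenerate")
})

test_that("the ATET point estimate is the mean matched-pair difference", {
  set.seed(9)
  scores <- runif(400)
  tr <- rbinom(400, 1, 0.25)
  los <- rlnorm(400, 2, 0.5) + 5 * tr
  pairs <- match_nn_replacement(scores, tr)
  est <- estimate_atet(pairs, los, n_boot = 100, seed = 1)
  expect_equal(est$point,
               mean(los[pairs$treated]) - mean(los[pairs$control]))
  expect_equal(est$n_pairs, sum(tr))
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
  # constant differences: point = c and a degenerate interval
  cp <- structure(data.frame(treated = 1:3, control = 4:6),
                  class = c("matched_pairs", "data.frame"))
  out <- c(10, 11, 12, 3, 4, 5)
  cest <- estimate_atet(cp, out, n_boot = 50, seed = 1)
  expect_equal(cest$point, 7)
  expect_equal(cest$ci_low, 7)
  expect_equal(cest$ci_high, 7)
})

test_that("matching reduces covariate imbalance on a confounded cohort", {
  coh <- generate_cohort(cohort_config(n_subjects = 20000,
                                       n_binary_covariates = 12,
                                       score_auc = NULL, seed = 10))
  fit <- fit_propensity(coh[covariate_columns(coh)], coh$fall)
  pairs <- match_nn_replacement(fit$scores, coh$fall)
  bal <- balance_report(coh, pairs)
  expect_equal(bal$covariate, covariate_columns(coh))
  expect_lt(max(abs(bal$std_diff_after)), max(abs(bal$std_diff_before)))
})

test_that("random treatment shows little imbalance before matching", {
  set.seed(11)
  coh <- make_toy_cohort(5000, seed = 11)
  coh$fall <- rbinom(5000, 1, 0.3)
  fit <- fit_propensity(coh[covariate_columns(coh)], coh$fall)
  pairs <- match_nn_replacement(fit$scores, coh$fall)
  bal <- balance_report(coh, pairs)
  expect_lt(max(abs(bal$std_diff_before)), 0.1)
})
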