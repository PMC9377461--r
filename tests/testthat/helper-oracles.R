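# Independent brute-force oracles used across the test suite. These are
# deliberately naive (enumeration / exhaustive search) and share no code
# with the package implementation.

# exact one-sided signed-rank P value under a biased sign model: each
# nonzero difference is positive with probability gamma/(1+gamma)
# independently; P(T* >= T_obs) by enumeration of all 2^n sign patterns.
# gamma = 1 gives the exact null distribution of the Wilcoxon test.
oracle_exact_signed_rank_p <- function(diffs, gamma = 1) {
  d <- diffs[diffs != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  p_plus <- gamma / (1 + gamma)
  total <- 0
  for (code in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(code)[1:n])
    t_sim <- sum(r[signs == 1])
    if (t_sim >= t_obs) {
      k <- sum(signs)
      total <- total + p_plus^k * (1 - p_plus)^(n - k)
    }
  }
  total
}

# classical Hodges-Lehmann estimate: median of the Walsh averages
oracle_walsh_median <- function(diffs) {
  n <- length(diffs)
  w <- c()
  for (i in 1:n) for (j in i:n) w <- c(w, (diffs[i] + diffs[j]) / 2)
  stats::median(w)
}

# exhaustive nearest-neighbor match with replacement; equidistant ties to
# the lowest control index
oracle_nn_match <- function(scores, treatment) {
  t_idx <- which(treatment == 1)
  c_idx <- which(treatment == 0)
  control <- integer(length(t_idx))
  for (i in seq_along(t_idx)) {
    d <- abs(scores[c_idx] - scores[t_idx[i]])
    control[i] <- min(c_idx[d == min(d)])
  }
  data.frame(treated = t_idx, control = control)
}

# AUC by direct enumeration of event/non-event pairs
oracle_auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  total <- 0
  for (a in s1) for (b in s0) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(s1) * length(s0))
}

# exhaustive Youden scan over all observed thresholds (rule: >= t)
oracle_youden <- function(scores, labels) {
  best_j <- -Inf
  best_t <- NA
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    # ascending scan + strict improvement keeps the lowest maximizer
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# small complete synthetic cohort built by hand (continuous x03 so both
# imputation paths get exercised)
make_toy_cohort <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    id = seq_len(n),
    age_scaled = runif(n),
    x01 = rbinom(n, 1, 0.3),
    x02 = rbinom(n, 1, 0.5),
    x03 = rnorm(n, mean = 5, sd = 2),
    fall = rbinom(n, 1, 0.2),
    los = rlnorm(n, 2, 0.5),
    risk_score = rnorm(n)
  )
  class(df) <- c("fall_cohort", "data.frame")
  df
}
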