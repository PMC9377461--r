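#' Fit a propensity score model
#'
#' Maximum-likelihood logistic regression of a binary treatment (here: the
#' fall indicator) on covariates. The fitted probabilities are the
#' propensity scores; the in-sample discrimination is reported as a
#' midrank Mann-Whitney AUC.
#'
#' @param covariates Numeric matrix or data frame, one row per subject, no
#'   missing cells (fit after imputation).
#' @param treatment Binary indicator vector (1 = treated/fallen).
#' @return An object of class `propensity_fit` with elements
#'   `coefficients`, `scores` and `in_sample_auc`.
#' @export
fit_propensity <- function(covariates, treatment) {
  x <- as.data.frame(covariates)
  if (anyNA(x)) stop("covariates contain missing cells; impute first")
  stopifnot(all(treatment %in% c(0, 1)))
  if (sum(treatment) == 0 || sum(treatment) == length(treatment)) {
    stop("need at least one treated and one control subject")
  }
  dat <- cbind(x, .treat = treatment)
  fit <- suppressWarnings(
    stats::glm(.treat ~ ., data = dat, family = stats::binomial())
  )
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  scores <- stats::fitted(fit)
  if (any(scores < 1e-12 | scores > 1 - 1e-12)) {
    warning("fitted probabilities at the 0/1 boundary; ",
            "possible (quasi-)separation")
  }
  structure(
    list(coefficients = beta, scores = scores,
         in_sample_auc = auc(scores, treatment), model = fit),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Propensity fit: %d subjects (%d treated), in-sample AUC %.3f\n",
              length(x$scores), sum(x$model$y), x$in_sample_auc))
  invisible(x)
}

#' One-to-one nearest-neighbor matching with replacement
#'
#' Pairs every treated subject with the control whose propensity score is
#' closest in absolute difference. Controls may be reused. Ties (two
#' controls equidistant, or several controls sharing the nearest score)
#' are broken toward the lowest control index, which makes the result
#' deterministic and stable under reordering of the treated units. An
#' optional caliper discards treated units with no control within the
#' given score distance.
#'
#' @param scores Propensity scores, one per subject.
#' @param treatment Binary indicator vector aligned with `scores`.
#' @param caliper Optional maximum |score difference|; default `NULL`
#'   (none).
#' @return An object of class `matched_pairs`: a data frame with columns
#'   `treated` and `control` (row indices into the original data), one row
#'   per matched treated subject.
#' @export
match_nn_replacement <- function(scores, treatment, caliper = NULL) {
  stopifnot(length(scores) == length(treatment),
            all(treatment %in% c(0, 1)))
  t_idx <- which(treatment == 1)
  c_idx <- which(treatment == 0)
  if (!length(c_idx)) stop("no control subjects to match against")
  ord <- order(scores[c_idx], c_idx)
  cs <- scores[c_idx][ord]
  cid <- c_idx[ord]
  m <- length(cs)

  # first index of the run of equal scores ending at (or containing) j;
  # within a run ids are ascending, so the run head carries the lowest id
  run_head <- function(j) {
    while (j > 1 && cs[j - 1] == cs[j]) j <- j - 1
    j
  }

  control <- integer(length(t_idx))
  dist <- numeric(length(t_idx))
  for (i in seq_along(t_idx)) {
    s <- scores[t_idx[i]]
    j <- findInterval(s, cs)        # last control with score <= s
    d_left <- if (j >= 1) s - cs[j] else Inf
    d_right <- if (j < m) cs[j + 1] - s else Inf
    if (d_left < d_right) {
      pick <- cid[run_head(j)]
      dist[i] <- d_left
    } else if (d_right < d_left) {
      pick <- cid[j + 1]
      dist[i] <- d_right
    } else {                        # equidistant: lowest id wins
      pick <- min(cid[run_head(j)], cid[j + 1])
      dist[i] <- d_left
    }
    control[i] <- pick
  }
  keep <- if (is.null(caliper)) rep(TRUE, length(t_idx)) else dist <= caliper
  pairs <- data.frame(treated = t_idx[keep], control = control[keep])
  class(pairs) <- c("matched_pairs", "data.frame")
  pairs
}

#' Treated-minus-control outcome differences for matched pairs
#'
#' @param pairs A [match_nn_replacement()] result.
#' @param outcomes Outcome vector (length of stay, days) indexed like the
#'   data the pairs refer to.
#' @return Numeric vector of per-pair differences, one per treated subject.
#' @export
pair_differences <- function(pairs, outcomes) {
  stopifnot(inherits(pairs, "matched_pairs"))
  outcomes[pairs$treated] - outcomes[pairs$control]
}

#' Standardized mean difference between two samples
#'
#' The two-sample Cohen-style balance diagnostic
#' \deqn{d = (\bar x_t - \bar x_c) / \sqrt{(s_t^2 + s_c^2)/2}}
#' with `n - 1` denominator variances for continuous variables and
#' `p(1 - p)` proportion variances when both samples are binary. By the
#' usual convention |d| < 0.1 indicates adequate balance.
#'
#' @param treated_values,control_values Non-empty numeric samples.
#' @return The standardized difference (treated minus control).
#' @seealso [std_diff_moments()], [std_diff_rates()] for the same quantity
#'   from summary statistics.
#' @export
standardized_difference <- function(treated_values, control_values) {
  stopifnot(length(treated_values) > 0, length(control_values) > 0)
  binary <- all(c(treated_values, control_values) %in% c(0, 1))
  m_t <- mean(treated_values)
  m_c <- mean(control_values)
  if (binary) {
    v_t <- m_t * (1 - m_t)
    v_c <- m_c * (1 - m_c)
  } else {
    v_t <- if (length(treated_values) > 1) stats::var(treated_values) else 0
    v_c <- if (length(control_values) > 1) stats::var(control_values) else 0
  }
  s <- sqrt((v_t + v_c) / 2)
  if (s == 0) {
    if (m_t == m_c) return(0)
    stop("degenerate input: zero variance in both samples, unequal means")
  }
  (m_t - m_c) / s
}

#' @rdname standardized_difference
#' @param mean_t,sd_t,mean_c,sd_c Group means and standard deviations.
#' @export
std_diff_moments <- function(mean_t, sd_t, mean_c, sd_c) {
  s <- sqrt((sd_t^2 + sd_c^2) / 2)
  if (s == 0) {
    if (mean_t == mean_c) return(0)
    stop("degenerate input: zero variance in both samples, unequal means")
  }
  (mean_t - mean_c) / s
}

#' @rdname standardized_difference
#' @param p_t,p_c Group event proportions of a binary variable.
#' @export
std_diff_rates <- function(p_t, p_c) {
  s <- sqrt((p_t * (1 - p_t) + p_c * (1 - p_c)) / 2)
  if (s == 0) {
    if (p_t == p_c) return(0)
    stop("degenerate input: zero variance in both samples, unequal means")
  }
  (p_t - p_c) / s
}

#' ATET from matched pairs with a bootstrap confidence interval
#'
#' The point estimate is the mean treated-minus-matched-control outcome
#' difference, identically the mean treated outcome minus the mean matched
#' control outcome (reused controls counted per use). The confidence
#' interval is a percentile bootstrap over treated units: each resample
#' redraws pairs (a treated subject together with its matched control)
#' with replacement.
#'
#' @param pairs A [match_nn_replacement()] result.
#' @param outcomes Outcome vector (days), indexed like the matched data.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `atet_estimate` with `point`, `ci_low`,
#'   `ci_high`, `n_pairs`.
#' @export
estimate_atet <- function(pairs, outcomes, n_boot = 1000L, level = 0.95,
                          seed = 1L) {
  diffs <- pair_differences(pairs, outcomes)
  if (!length(diffs)) stop("no matched pairs")
  stopifnot(n_boot >= 1)
  set.seed(seed)
  n <- length(diffs)
  boot <- vapply(seq_len(n_boot),
                 function(b) mean(diffs[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  structure(list(point = mean(diffs), ci_low = ci[1], ci_high = ci[2],
                 n_pairs = n),
            class = "atet_estimate")
}

#' @export
print.atet_estimate <- function(x, ...) {
  cat(sprintf("ATET: %.2f days (95%% CI %.2f-%.2f), %d matched pairs\n",
              x$point, x$ci_low, x$ci_high, x$n_pairs))
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Standardized differences per covariate: before matching, all treated
#' versus all controls; after matching, treated versus their matched
#' controls with multiplicity (a control reused for several treated
#' subjects contributes once per use).
#'
#' @param cohort A `fall_cohort` data frame (complete covariates).
#' @param pairs A [match_nn_replacement()] result on the same rows.
#' @return A data frame with columns `covariate`, `std_diff_before`,
#'   `std_diff_after`.
#' @export
balance_report <- function(cohort, pairs) {
  stopifnot(inherits(pairs, "matched_pairs"))
  covs <- covariate_columns(cohort)
  treated_all <- cohort$fall == 1
  rows <- lapply(covs, function(cl) {
    v <- cohort[[cl]]
    data.frame(
      covariate = cl,
      std_diff_before = standardized_difference(v[treated_all],
                                                v[!treated_all]),
      std_diff_after = standardized_difference(v[pairs$treated],
                                               v[pairs$control])
    )
  })
  do.call(rbind, rows)
}
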