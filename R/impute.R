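#' Specification for multiple imputation by chained equations
#'
#' @param m Number of completed datasets (default 20).
#' @param n_cycles Chained-equation sweeps per imputation (default 10).
#' @param pmm_k Number of donors for predictive mean matching (default 5).
#' @param seed Master seed; per-imputation seeds are derived as
#'   `seed + imputation index`, so individual imputations are reproducible
#'   in isolation.
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 20L, n_cycles = 10L, pmm_k = 5L, seed = 1L) {
  stopifnot(m >= 1, n_cycles >= 1, pmm_k >= 1)
  structure(list(m = as.integer(m), n_cycles = as.integer(n_cycles),
                 pmm_k = as.integer(pmm_k), seed = as.integer(seed)),
            class = "imputation_spec")
}

# drop aliased columns so conditional models are full rank
full_rank_columns <- function(x) {
  qx <- qr(x)
  sort(qx$pivot[seq_len(qx$rank)])
}

# tiny ridge to keep a near-singular posterior covariance factorizable
nearest_pd <- function(m) {
  m + diag(1e-10, nrow(m))
}

# posterior draw of logistic coefficients (approximate normal), then a
# Bernoulli draw for each missing entry
impute_binary_draw <- function(y_obs, x_obs, x_mis) {
  keep <- full_rank_columns(x_obs)
  x_obs <- x_obs[, keep, drop = FALSE]
  x_mis <- x_mis[, keep, drop = FALSE]
  fit <- suppressWarnings(
    stats::glm.fit(x_obs, y_obs, family = stats::binomial())
  )
  beta <- stats::coef(fit)
  xtwx <- crossprod(x_obs * sqrt(fit$weights))
  cov <- tryCatch(solve(xtwx), error = function(e) NULL)
  draw <- if (is.null(cov)) beta else {
    beta + drop(t(chol(nearest_pd(cov))) %*% stats::rnorm(length(beta)))
  }
  eta <- drop(x_mis %*% draw)
  stats::rbinom(length(eta), 1L, stats::plogis(eta))
}

# Bayesian linear regression draw + type-1 predictive mean matching
impute_pmm_draw <- function(y_obs, x_obs, x_mis, k) {
  keep <- full_rank_columns(x_obs)
  x_obs <- x_obs[, keep, drop = FALSE]
  x_mis <- x_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(x_obs, y_obs)
  beta_hat <- fit$coefficients
  df <- max(length(y_obs) - ncol(x_obs), 1L)
  sigma2_hat <- sum(fit$residuals^2) / df
  sigma2 <- sigma2_hat * df / stats::rchisq(1, df)
  xtx_inv <- solve(crossprod(x_obs))
  beta <- beta_hat + drop(t(chol(nearest_pd(sigma2 * xtx_inv))) %*%
                            stats::rnorm(length(beta_hat)))
  yhat_obs <- drop(x_obs %*% beta_hat)
  yhat_mis <- drop(x_mis %*% beta)
  vapply(yhat_mis, function(p) {
    d <- abs(yhat_obs - p)
    donors <- order(d)[seq_len(min(k, length(d)))]
    y_obs[sample(donors, 1L)]
  }, numeric(1))
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of a cohort with missing covariate values,
#' by iterating per-variable conditional models: a logistic posterior draw
#' for binary columns and Bayesian linear regression with predictive mean
#' matching (k donors) for continuous ones. Predictors are all other
#' covariates plus the fall indicator, so the covariate-outcome structure
#' the downstream propensity model relies on is preserved. Missing cells
#' are initialized by sampling observed values; observed cells are never
#' altered.
#'
#' @param cohort A `fall_cohort` data frame (missing entries as `NA`).
#' @param spec An [imputation_spec()].
#' @return A list of `m` completed cohorts (class `imputed_cohorts`).
#' @export
mice_impute <- function(cohort, spec = imputation_spec()) {
  stopifnot(inherits(spec, "imputation_spec"))
  covs <- covariate_columns(cohort)
  miss_cols <- covs[vapply(covs, function(cl) anyNA(cohort[[cl]]),
                           logical(1))]
  all_missing <- miss_cols[vapply(miss_cols,
                                  function(cl) all(is.na(cohort[[cl]])),
                                  logical(1))]
  if (length(all_missing)) {
    stop("column(s) with no observed values cannot be imputed: ",
         paste(all_missing, collapse = ", "))
  }
  if (!length(miss_cols)) {
    out <- replicate(spec$m, cohort, simplify = FALSE)
    class(out) <- c("imputed_cohorts", "list")
    return(out)
  }
  if (!any(!vapply(covs, function(cl) anyNA(cohort[[cl]]), logical(1)))) {
    stop("at least one fully observed covariate column is required")
  }
  is_binary <- vapply(miss_cols, function(cl) {
    v <- cohort[[cl]]
    all(v[!is.na(v)] %in% c(0, 1))
  }, logical(1))

  out <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    set.seed(spec$seed + i)
    comp <- cohort
    # initialize by drawing from each column's observed values
    for (cl in miss_cols) {
      na_idx <- which(is.na(comp[[cl]]))
      obs <- comp[[cl]][-na_idx]
      comp[[cl]][na_idx] <- sample(obs, length(na_idx), replace = TRUE)
    }
    for (cycle in seq_len(spec$n_cycles)) {
      for (j in seq_along(miss_cols)) {
        cl <- miss_cols[j]
        na_idx <- which(is.na(cohort[[cl]]))
        preds <- setdiff(covs, cl)
        xmat <- cbind(1, as.matrix(comp[c(preds, "fall")]))
        y_obs <- comp[[cl]][-na_idx]
        x_obs <- xmat[-na_idx, , drop = FALSE]
        x_mis <- xmat[na_idx, , drop = FALSE]
        drawn <- tryCatch(
          if (is_binary[j]) impute_binary_draw(y_obs, x_obs, x_mis)
          else impute_pmm_draw(y_obs, x_obs, x_mis, spec$pmm_k),
          error = function(e) sample(y_obs, length(na_idx), replace = TRUE)
        )
        comp[[cl]][na_idx] <- drawn
      }
    }
    out[[i]] <- comp
  }
  class(out) <- c("imputed_cohorts", "list")
  out
}

#' Pool a scalar estimate over imputations
#'
#' The arithmetic mean of per-imputation point estimates, the convention
#' used for every pooled quantity in this package (matched-pair effect
#' estimates, balance diagnostics, sensitivity bounds).
#'
#' @param estimates Non-empty numeric vector, one value per imputation.
#' @return The pooled (mean) estimate.
#' @export
pool_scalar_over_imputations <- function(estimates) {
  if (!length(estimates)) stop("no estimates to pool")
  mean(as.numeric(estimates))
}
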