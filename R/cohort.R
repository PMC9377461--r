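#' Configuration for a synthetic hospitalization cohort
#'
#' Describes the generative model for a cohort of elderly hospitalizations
#' with covariate-driven fall risk, a confounded right-skewed length of stay
#' (LOS), an additive stay extension among fallen subjects, and optional
#' binormal classifier risk scores.
#'
#' The fall indicator is drawn from a logistic model on the covariates whose
#' intercept is calibrated so the expected prevalence equals
#' `target_prevalence`. Baseline LOS is lognormal with marginal mean
#' `baseline_los_mean` and SD `baseline_los_sd`; its log-mean is shifted
#' linearly by the covariates (`los_coefficients`, centered so the marginal
#' moments are preserved), which makes the covariates genuine confounders:
#' they drive both fall risk and stay length. Fallen subjects receive an
#' additional `true_atet` days, so the average treatment effect on the
#' treated is `true_atet` by construction.
#'
#' Age is stored rescaled to `[0, 1]` over `age_range` (65-99 years by
#' default), the convention under which covariate log-odds are expressed.
#'
#' @param n_subjects Number of hospitalizations to simulate.
#' @param n_binary_covariates Number of binary covariates (default 48; with
#'   scaled age this gives the 49-variable structure of a fall-risk screen).
#' @param age_range Length-2 numeric, years; ages drawn uniformly and
#'   rescaled to `[0, 1]`.
#' @param fall_coefficients Log-odds per covariate (first element: scaled
#'   age; remainder: binaries). Recycled/validated to length
#'   `1 + n_binary_covariates`.
#' @param binary_prevalences Marginal Bernoulli rates of the binary
#'   covariates; defaults spread over 0.05-0.50.
#' @param target_prevalence Target fall prevalence in (0, 1); default 0.024.
#' @param true_atet Additive stay extension (days) among fallen subjects.
#' @param baseline_los_mean,baseline_los_sd Marginal mean and SD (days) of
#'   the baseline lognormal LOS; defaults 10.6 and 6.8.
#' @param los_coefficients Covariate effects on log-LOS; default
#'   `0.25 * fall_coefficients`, giving confounding between fall risk and
#'   stay length.
#' @param score_auc Target AUC of the generated risk scores in `[0.5, 1)`,
#'   or `NULL` to skip score generation.
#' @param missingness_rates Optional named rates passed to
#'   [apply_missingness()] by [run_pipeline()]; stored, not applied here.
#' @param mar Logical; stored alongside `missingness_rates` (MAR vs MCAR).
#' @param seed Integer seed; every draw is reproducible given it.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [apply_missingness()],
#'   [generate_risk_scores()]
#' @examples
#' cfg <- cohort_config(n_subjects = 2000, seed = 7)
#' coh <- generate_cohort(cfg)
#' mean(coh$fall)
#' @export
cohort_config <- function(n_subjects = 50000,
                          n_binary_covariates = 48,
                          age_range = c(65, 99),
                          fall_coefficients = NULL,
                          binary_prevalences = NULL,
                          target_prevalence = 0.024,
                          true_atet = 17.8,
                          baseline_los_mean = 10.6,
                          baseline_los_sd = 6.8,
                          los_coefficients = NULL,
                          score_auc = 0.851,
                          missingness_rates = NULL,
                          mar = FALSE,
                          seed = 1L) {
  k <- as.integer(n_binary_covariates)
  if (is.null(fall_coefficients)) {
    fall_coefficients <- c(1.5, rep(c(0.6, 0.3, 0, -0.3), length.out = k))
  }
  if (length(fall_coefficients) != k + 1L) {
    stop("fall_coefficients must have length 1 + n_binary_covariates")
  }
  if (any(!is.finite(fall_coefficients))) {
    stop("fall_coefficients must be finite")
  }
  if (is.null(binary_prevalences)) {
    binary_prevalences <- seq(0.05, 0.50, length.out = k)
  }
  if (is.null(los_coefficients)) {
    los_coefficients <- 0.25 * fall_coefficients
  }
  stopifnot(
    n_subjects >= 2,
    length(age_range) == 2, age_range[1] < age_range[2],
    target_prevalence > 0, target_prevalence < 1,
    true_atet >= 0,
    baseline_los_mean > 0, baseline_los_sd > 0,
    length(los_coefficients) == k + 1L,
    length(binary_prevalences) == k,
    all(binary_prevalences > 0 & binary_prevalences < 1)
  )
  if (!is.null(score_auc) && (score_auc < 0.5 || score_auc >= 1)) {
    stop("score_auc must lie in [0.5, 1)")
  }
  if (!is.null(missingness_rates) &&
      any(missingness_rates < 0 | missingness_rates > 1)) {
    stop("missingness_rates must lie in [0, 1]")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_binary_covariates = k,
      age_range = as.numeric(age_range),
      fall_coefficients = as.numeric(fall_coefficients),
      binary_prevalences = as.numeric(binary_prevalences),
      target_prevalence = target_prevalence,
      true_atet = true_atet,
      baseline_los_mean = baseline_los_mean,
      baseline_los_sd = baseline_los_sd,
      los_coefficients = as.numeric(los_coefficients),
      score_auc = score_auc,
      missingness_rates = missingness_rates,
      mar = isTRUE(mar),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d, covariates: %d (+ scaled age)\n",
              x$n_subjects, x$n_binary_covariates))
  cat(sprintf("  target fall prevalence: %.3f, true ATET: %.1f d\n",
              x$target_prevalence, x$true_atet))
  cat(sprintf("  baseline LOS: lognormal mean %.1f d (SD %.1f)\n",
              x$baseline_los_mean, x$baseline_los_sd))
  if (!is.null(x$score_auc)) {
    cat(sprintf("  risk-score target AUC: %.3f\n", x$score_auc))
  }
  invisible(x)
}

# lognormal (meanlog, sdlog) matching a target arithmetic mean and SD
lognormal_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Covariate column names of a cohort table
#'
#' The scaled-age column followed by the binary covariate columns
#' (`x01..xK`), in table order — the predictor set used by the propensity
#' and imputation models.
#'
#' @param cohort A `fall_cohort` data frame.
#' @return Character vector of column names.
#' @export
covariate_columns <- function(cohort) {
  c("age_scaled", grep("^x[0-9]+$", names(cohort), value = TRUE))
}

#' Generate a synthetic hospitalization cohort
#'
#' Draws a cohort under the model described in [cohort_config()]: uniform
#' ages rescaled to `[0, 1]`, independent binary covariates, a logistic
#' fall model with prevalence-calibrated intercept, lognormal baseline LOS
#' confounded by the same covariates, the configured additive extension for
#' fallen subjects, and (optionally) binormal risk scores at the configured
#' AUC.
#'
#' @param config A [cohort_config()] object.
#' @return A `fall_cohort` data frame with columns `id`, `age_scaled`,
#'   `x01..xK`, `fall`, `los`, and `risk_score` (NA when `score_auc` is
#'   `NULL`). The config is attached as attribute `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  k <- config$n_binary_covariates

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  age_scaled <- (age - config$age_range[1]) / diff(config$age_range)
  x <- matrix(stats::rbinom(n * k, 1L,
                            rep(config$binary_prevalences, each = n)),
              nrow = n, ncol = k)
  colnames(x) <- sprintf("x%02d", seq_len(k))

  eta <- drop(cbind(age_scaled, x) %*% config$fall_coefficients)
  # calibrate the intercept so the expected prevalence hits the target
  f <- function(a) mean(stats::plogis(a + eta)) - config$target_prevalence
  alpha <- tryCatch(
    stats::uniroot(f, lower = -40, upper = 20, tol = 1e-10)$root,
    error = function(e) stop("prevalence calibration failed: ",
                             conditionMessage(e))
  )
  fall <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))

  lp <- lognormal_params(config$baseline_los_mean, config$baseline_los_sd)
  shift <- drop(cbind(age_scaled, x) %*% config$los_coefficients)
  shift <- shift - mean(shift)
  # the covariate shift contributes to the log-scale variance; absorb it
  # into the total so the marginal mean/SD still hit their targets
  v_shift <- stats::var(shift)
  s2_total <- lp$sdlog^2
  if (v_shift > 0.9 * s2_total) {
    shift <- shift * sqrt(0.9 * s2_total / v_shift)
    v_shift <- 0.9 * s2_total
  }
  los <- stats::rlnorm(n, meanlog = lp$meanlog + shift,
                       sdlog = sqrt(s2_total - v_shift))
  los[fall == 1L] <- los[fall == 1L] + config$true_atet

  risk_score <- rep(NA_real_, n)
  if (!is.null(config$score_auc)) {
    risk_score <- generate_risk_scores(fall, config$score_auc,
                                       seed = config$seed + 1L)
  }

  cohort <- data.frame(id = seq_len(n), age_scaled = age_scaled, x,
                       fall = fall, los = los, risk_score = risk_score)
  class(cohort) <- c("fall_cohort", "data.frame")
  attr(cohort, "config") <- config
  cohort
}

#' Mask covariate values to emulate incompletely observed data
#'
#' Sets selected covariate entries to `NA`. Under MCAR each entry of a
#' column is masked independently at the column's rate. Under MAR the
#' masking probability depends only on always-observed fields (scaled age
#' and the fall indicator) through a logistic model whose intercept is
#' calibrated so the expected masked fraction equals the requested rate.
#' Observed values are never altered.
#'
#' @param cohort A `fall_cohort` data frame.
#' @param rates Either a single rate applied to every binary covariate
#'   column, or a named vector of rates whose names are covariate columns
#'   (blocks of columns sharing a rate are expressed by naming each).
#'   Scaled age, `fall` and `los` are never masked.
#' @param mechanism `"MCAR"` (default) or `"MAR"`.
#' @param seed Integer seed.
#' @return The cohort with masked entries set to `NA`.
#' @export
apply_missingness <- function(cohort, rates, mechanism = c("MCAR", "MAR"),
                              seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  binaries <- grep("^x[0-9]+$", names(cohort), value = TRUE)
  if (is.null(names(rates))) {
    if (length(rates) != 1L) {
      stop("unnamed rates must be a single value applied to all binary ",
           "covariate columns")
    }
    rates <- stats::setNames(rep(rates, length(binaries)), binaries)
  }
  unknown <- setdiff(names(rates), names(cohort))
  if (length(unknown)) {
    stop("rates name columns not in the cohort: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  n <- nrow(cohort)
  for (col in names(rates)) {
    rate <- rates[[col]]
    if (rate == 0) next
    if (mechanism == "MCAR") {
      mask <- stats::runif(n) < rate
    } else {
      eta <- 2 * cohort$age_scaled + 1 * cohort$fall
      if (rate >= 1) {
        mask <- rep(TRUE, n)
      } else {
        f <- function(a) mean(stats::plogis(a + eta)) - rate
        a <- stats::uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
        mask <- stats::runif(n) < stats::plogis(a + eta)
      }
    }
    if (rate >= 1) mask <- rep(TRUE, n)
    cohort[[col]][mask] <- NA
  }
  cohort
}

#' Generate binormal risk scores at a target AUC
#'
#' Non-events are standard normal; events are shifted by
#' `delta = sqrt(2) * qnorm(target_auc)` with equal variances, so the
#' expected area under the ROC curve equals `target_auc` exactly.
#'
#' @param labels Binary event indicators (0/1).
#' @param target_auc Target AUC in `[0.5, 1)`.
#' @param seed Integer seed.
#' @return Numeric scores, one per label.
#' @export
generate_risk_scores <- function(labels, target_auc, seed = 1L) {
  if (target_auc < 0.5 || target_auc >= 1) {
    stop("target_auc must lie in [0.5, 1)")
  }
  stopifnot(all(labels %in% c(0, 1)))
  set.seed(seed)
  delta <- sqrt(2) * stats::qnorm(target_auc)
  stats::rnorm(length(labels)) + delta * labels
}
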