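# FNV-1a hash of a string; used to fingerprint the configuration in the
# run manifest without external dependencies
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches only the low byte (b < 256)
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime, split to keep doubles exact
    h <- ((h %/% 65536 * p) %% 65536 * 65536 + (h %% 65536) * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Configuration of a full analysis run
#'
#' Bundles every stage parameter of the pipeline: cohort generation,
#' missingness, multiple imputation, propensity matching, sensitivity
#' analysis, classifier evaluation, and the decision model.
#'
#' @param cohort A [cohort_config()] (defines generation, missingness and
#'   risk-score parameters).
#' @param imputation An [imputation_spec()].
#' @param n_boot Bootstrap resamples for the ATET confidence interval.
#' @param gammas Hidden-bias levels for the sensitivity table.
#' @param stay A [stay_parameters()] object.
#' @param scenarios A list of [scenario()] objects.
#' @param stages Character vector of stages to run, in pipeline order;
#'   any subset of `c("simulate", "impute", "match", "sensitivity",
#'   "evaluate", "decide")`. Later stages require the earlier ones.
#' @param seed Master seed for stage-level randomness (bootstrap).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            imputation = imputation_spec(),
                            n_boot = 1000L,
                            gammas = c(1, 1.5, 2, 3, 5, 7),
                            stay = stay_parameters(),
                            scenarios = list(
                              scenario(17.8, 1, "scenario_1"),
                              scenario(17.8, 0.25, "scenario_2"),
                              scenario(8.6, 1, "scenario_3"),
                              scenario(8.6, 0.25, "scenario_4")
                            ),
                            stages = c("simulate", "impute", "match",
                                       "sensitivity", "evaluate", "decide"),
                            seed = 1L) {
  all_stages <- c("simulate", "impute", "match", "sensitivity",
                  "evaluate", "decide")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  structure(list(cohort = cohort, imputation = imputation,
                 n_boot = as.integer(n_boot), gammas = gammas,
                 stay = stay, scenarios = scenarios,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order — simulate a cohort (with
#' missingness and risk scores), impute, fit the propensity model and
#' match per imputed dataset, pool the matched-pair effect estimate and
#' balance, compute the Rosenbaum sensitivity table, evaluate the risk
#' scores at the Youden cutoff, and run the decision model on the
#' resulting confusion matrix — writing each artifact as delimited text
#' or JSON into `out_dir` together with a manifest (configuration
#' fingerprint, seeds, outputs). Reruns with an identical configuration
#' reproduce identical outputs. If `decide` runs without an `evaluate`
#' stage, the bundled worked-example confusion matrix is used.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if absent.
#' @param quiet Suppress per-stage log lines (default `FALSE`).
#' @return Invisibly, a list of in-memory stage results (elements
#'   `cohort`, `imputed`, `atet`, `balance`, `sensitivity`, `evaluation`,
#'   `decision`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else stage_log
  res <- list()
  outputs <- character(0)
  stages <- config$stages

  need <- function(stage, value, what) {
    if (is.null(value)) {
      stop("stage '", stage, "' requires upstream artifact: ", what)
    }
    value
  }

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(config$cohort)
    if (!is.null(config$cohort$missingness_rates)) {
      cohort <- apply_missingness(
        cohort, config$cohort$missingness_rates,
        mechanism = if (config$cohort$mar) "MAR" else "MCAR",
        seed = config$cohort$seed + 2L)
    }
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(unclass(config$cohort),
                         file.path(out_dir, "cohort_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    outputs <- c(outputs, "cohort.csv", "cohort_config.json")
    res$cohort <- cohort
    log("simulate", "n=%d, prevalence=%.4f, missing cells=%d",
        nrow(cohort), mean(cohort$fall),
        sum(is.na(cohort[covariate_columns(cohort)])))
  }

  if ("impute" %in% stages) {
    cohort <- need("impute", res$cohort, "cohort")
    res$imputed <- mice_impute(cohort, config$imputation)
    files <- sprintf("imputed_%02d.csv", seq_along(res$imputed))
    for (i in seq_along(res$imputed)) {
      write_cohort(res$imputed[[i]], file.path(out_dir, files[i]))
    }
    jsonlite::write_json(
      list(m = config$imputation$m, n_cycles = config$imputation$n_cycles,
           seed = config$imputation$seed, files = files),
      file.path(out_dir, "imputation_manifest.json"),
      auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, files, "imputation_manifest.json")
    log("impute", "m=%d completed datasets", length(res$imputed))
  }

  if ("match" %in% stages) {
    imputed <- need("match", res$imputed, "imputed datasets")
    per_imp <- lapply(imputed, function(ci) {
      covs <- ci[covariate_columns(ci)]
      fit <- fit_propensity(covs, ci$fall)
      pairs <- match_nn_replacement(fit$scores, ci$fall)
      list(fit = fit, pairs = pairs,
           diffs = pair_differences(pairs, ci$los),
           balance = balance_report(ci, pairs),
           atet = estimate_atet(pairs, ci$los, n_boot = config$n_boot,
                                seed = config$seed))
    })
    res$match <- per_imp
    res$atet <- list(
      point = pool_scalar_over_imputations(
        vapply(per_imp, function(p) p$atet$point, numeric(1))),
      ci_low = pool_scalar_over_imputations(
        vapply(per_imp, function(p) p$atet$ci_low, numeric(1))),
      ci_high = pool_scalar_over_imputations(
        vapply(per_imp, function(p) p$atet$ci_high, numeric(1))),
      n_pairs = per_imp[[1]]$atet$n_pairs,
      propensity_auc = pool_scalar_over_imputations(
        vapply(per_imp, function(p) p$fit$in_sample_auc, numeric(1)))
    )
    bal <- per_imp[[1]]$balance
    bal$std_diff_before <- rowMeans(
      vapply(per_imp, function(p) p$balance$std_diff_before,
             numeric(nrow(bal))))
    bal$std_diff_after <- rowMeans(
      vapply(per_imp, function(p) p$balance$std_diff_after,
             numeric(nrow(bal))))
    res$balance <- bal
    utils::write.csv(bal, file.path(out_dir, "balance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$atet, file.path(out_dir, "atet.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "balance.csv", "atet.json")
    log("match", "ATET=%.2f d (CI %.2f-%.2f), PS AUC=%.3f",
        res$atet$point, res$atet$ci_low, res$atet$ci_high,
        res$atet$propensity_auc)
  }

  if ("sensitivity" %in% stages) {
    per_imp <- need("sensitivity", res$match, "matched pairs")
    res$sensitivity <- sensitivity_table(lapply(per_imp, `[[`, "diffs"),
                                         config$gammas)
    utils::write.csv(as.data.frame(res$sensitivity),
                     file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "sensitivity.csv")
    log("sensitivity", "%d gamma levels, max_p(1)=%.3g",
        nrow(res$sensitivity), res$sensitivity$max_p[1])
  }

  if ("evaluate" %in% stages) {
    cohort <- need("evaluate", res$cohort, "cohort with risk scores")
    if (all(is.na(cohort$risk_score))) {
      stop("stage 'evaluate' requires risk scores in the cohort")
    }
    cut <- youden_cutoff(cohort$risk_score, cohort$fall)
    cm <- confusion_from_predictions(
      as.integer(cohort$risk_score >= cut$threshold), cohort$fall)
    metrics <- metrics_from_confusion(cm)
    res$evaluation <- list(auc = auc(cohort$risk_score, cohort$fall),
                           cutoff = cut, confusion = cm, metrics = metrics)
    jsonlite::write_json(
      list(auc = res$evaluation$auc, threshold = cut$threshold,
           youden_j = cut$j, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
           sensitivity = metrics$sensitivity,
           specificity = metrics$specificity,
           precision = metrics$precision, f1 = metrics$f1),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "evaluation.json")
    log("evaluate", "AUC=%.3f, Youden cutoff=%.3f, F1=%.3f",
        res$evaluation$auc, cut$threshold, metrics$f1)
  }

  if ("decide" %in% stages) {
    cm <- if (!is.null(res$evaluation)) res$evaluation$confusion
          else example_confusion_matrix()
    tab <- scenario_table(cm, config$stay, config$scenarios,
                          rounded = TRUE)
    res$decision <- tab
    utils::write.csv(tab, file.path(out_dir, "decision_table.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "decision_table.csv")
    log("decide", "%d scenarios, best net=%.3f days/day",
        nrow(tab), max(tab$net_per_day))
  }

  cfg_json <- jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  res$manifest <- list(config_hash = fnv1a(as.character(cfg_json)),
                       seed = config$seed,
                       cohort_seed = config$cohort$seed,
                       imputation_seed = config$imputation$seed,
                       stages = stages, outputs = outputs,
                       package_version =
                         as.character(utils::packageVersion("fallstay")))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

# strip S3 classes so a config serializes as plain JSON
unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else {
    x
  }
}
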