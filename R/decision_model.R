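#' Round half away from zero
#'
#' Reporting convention for the decision-model tables: days/day values to
#' 3 decimals, Yen to the nearest integer, halves rounded up. (Base R's
#' `round()` rounds halves to even.)
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Stay and cost parameters of the decision model
#'
#' @param mean_los_fallen Mean length of stay of fallen cases (days;
#'   default 30.3).
#' @param mean_los_unfallen Mean length of stay of unfallen cases (days;
#'   default 10.6).
#' @param daily_cost Hospitalization cost per day (default 40,000 Yen).
#' @return An object of class `stay_parameters`.
#' @export
stay_parameters <- function(mean_los_fallen = 30.3,
                            mean_los_unfallen = 10.6,
                            daily_cost = 40000) {
  stopifnot(mean_los_fallen > 0, mean_los_unfallen > 0, daily_cost > 0,
            mean_los_fallen > mean_los_unfallen)
  structure(list(mean_los_fallen = mean_los_fallen,
                 mean_los_unfallen = mean_los_unfallen,
                 daily_cost = daily_cost),
            class = "stay_parameters")
}

#' An intervention scenario
#'
#' @param atet Stay extension attributed to a fall (days); must lie in
#'   `(0, mean stay of fallen cases)`.
#' @param prevention_rate Proportion of predicted falls actually prevented
#'   by the intervention, in `[0, 1]`.
#' @param label Optional scenario name.
#' @return An object of class `scenario`.
#' @export
scenario <- function(atet, prevention_rate, label = NULL) {
  stopifnot(atet > 0, prevention_rate >= 0, prevention_rate <= 1)
  structure(list(atet = atet, prevention_rate = prevention_rate,
                 label = label),
            class = "scenario")
}

#' Counterfactual mean stay of fallen cases had they not fallen
#'
#' The fallen-group mean stay minus the assumed stay extension.
#'
#' @param params A [stay_parameters()] object.
#' @param atet Assumed stay extension (days), in
#'   `(0, mean_los_fallen)`.
#' @return Counterfactual mean stay (days).
#' @export
counterfactual_stay <- function(params, atet) {
  stopifnot(inherits(params, "stay_parameters"))
  if (atet < 0 || atet >= params$mean_los_fallen) {
    stop("atet must lie in [0, mean_los_fallen)")
  }
  params$mean_los_fallen - atet
}

#' Evaluate a fall-prevention scenario on a confusion matrix
#'
#' Converts a prediction model's confusion matrix into per-intervention-day
#' reduced, lost and net hospital days and cost savings. With
#' `L_f` / `L_u` the fallen / unfallen mean stays, `A` the assumed stay
#' extension and `r` the prevention rate, intervention days accrue over
#' every predicted-positive case:
#' \deqn{D = r \cdot TP (L_f - A) + (1 - r) TP \cdot L_f + FP \cdot L_u}
#' (prevented true positives stay `L_f - A` days, unprevented ones `L_f`,
#' false positives `L_u`). Reduced days are `r * TP * A`; days lost to
#' missed cases are `r * FN * A` (the stay reduction a perfect screen
#' would have realized on false negatives); net days and cost follow.
#'
#' @param cm A [confusion_matrix()].
#' @param params A [stay_parameters()] object.
#' @param sc A [scenario()].
#' @return An object of class `scenario_result` with `intervention_days`,
#'   `reduced_days`, `lost_days`, `net_days`, `reduced_per_day`,
#'   `lost_per_day`, `net_per_day`, `cost_per_day` (all unrounded).
#' @export
evaluate_scenario <- function(cm, params, sc) {
  stopifnot(inherits(cm, "confusion_matrix"),
            inherits(params, "stay_parameters"),
            inherits(sc, "scenario"))
  if (sc$atet >= params$mean_los_fallen) {
    stop("scenario atet must be below the fallen-group mean stay")
  }
  r <- sc$prevention_rate
  a <- sc$atet
  d <- r * cm$tp * (params$mean_los_fallen - a) +
    (1 - r) * cm$tp * params$mean_los_fallen +
    cm$fp * params$mean_los_unfallen
  if (d == 0) stop("empty intervention set: no predicted-positive days")
  reduced <- r * cm$tp * a
  lost <- r * cm$fn * a
  net <- reduced - lost
  structure(list(
    scenario = sc,
    intervention_days = d,
    reduced_days = reduced,
    lost_days = lost,
    net_days = net,
    reduced_per_day = reduced / d,
    lost_per_day = lost / d,
    net_per_day = net / d,
    cost_per_day = net / d * params$daily_cost
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "Scenario ATET %.1f d, prevention %.0f%%: net %.3f days/day, %.0f Yen/day\n",
    x$scenario$atet, 100 * x$scenario$prevention_rate,
    round_half_up(x$net_per_day, 3), round_half_up(x$cost_per_day)))
  invisible(x)
}

#' Confusion matrix of a treat-everyone policy
#'
#' Intervening on every case regardless of prediction: all fallen cases
#' are true positives, all unfallen cases false positives.
#'
#' @param n_fallen,n_unfallen Non-negative case counts.
#' @return A [confusion_matrix()] with `fn = tn = 0`.
#' @export
treat_all_matrix <- function(n_fallen, n_unfallen) {
  confusion_matrix(tp = n_fallen, fp = n_unfallen, fn = 0, tn = 0)
}

#' Evaluate several scenarios on one confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @param params A [stay_parameters()] object.
#' @param scenarios A list of [scenario()] objects.
#' @param rounded If `TRUE`, apply the reporting convention (days/day to
#'   3 decimals, Yen to the nearest integer, half up). Default `FALSE`.
#' @return A data frame, one row per scenario, columns `label`, `atet`,
#'   `prevention_rate`, `reduced_per_day`, `lost_per_day`, `net_per_day`,
#'   `cost_per_day`.
#' @export
scenario_table <- function(cm, params, scenarios, rounded = FALSE) {
  if (!length(scenarios)) {
    return(data.frame(label = character(), atet = numeric(),
                      prevention_rate = numeric(),
                      reduced_per_day = numeric(), lost_per_day = numeric(),
                      net_per_day = numeric(), cost_per_day = numeric()))
  }
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    res <- evaluate_scenario(cm, params, sc)
    data.frame(
      label = if (is.null(sc$label)) sprintf("scenario_%d", i) else sc$label,
      atet = sc$atet,
      prevention_rate = sc$prevention_rate,
      reduced_per_day = res$reduced_per_day,
      lost_per_day = res$lost_per_day,
      net_per_day = res$net_per_day,
      cost_per_day = res$cost_per_day
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(label = character(), atet = numeric(),
                      prevention_rate = numeric(),
                      reduced_per_day = numeric(), lost_per_day = numeric(),
                      net_per_day = numeric(), cost_per_day = numeric())
  }
  if (rounded && nrow(out)) {
    for (cl in c("reduced_per_day", "lost_per_day", "net_per_day")) {
      out[[cl]] <- round_half_up(out[[cl]], 3)
    }
    out$cost_per_day <- round_half_up(out$cost_per_day)
  }
  out
}

#' Cost curves over classification thresholds
#'
#' Sweeps every distinct observed score (plus `-Inf`, the treat-everyone
#' endpoint) as the threshold of the rule "score >= threshold predicts a
#' fall", keeps operating points with sensitivity at or above
#' `min_sensitivity`, and evaluates each scenario at each point.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary fall indicators (0/1); both classes must occur.
#' @param params A [stay_parameters()] object.
#' @param scenarios A list of [scenario()] objects.
#' @param min_sensitivity Minimum sensitivity retained (default 0.5).
#' @return A data frame sorted by sensitivity with columns `threshold`,
#'   `sensitivity`, `specificity`, `label`, `net_per_day`, `cost_per_day`.
#' @export
policy_sweep <- function(scores, labels, params, scenarios,
                         min_sensitivity = 0.5) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  tc <- threshold_counts(scores, labels)
  # -Inf sentinel: everyone predicted positive (treat-all endpoint)
  tc <- rbind(tc, data.frame(threshold = -Inf, tp = n1, fp = n0))
  # the lowest observed threshold already classifies everyone positive;
  # keep the -Inf sentinel as the canonical treat-all row
  tc <- tc[!duplicated(tc[c("tp", "fp")], fromLast = TRUE), ]
  tc$sensitivity <- tc$tp / n1
  tc$specificity <- (n0 - tc$fp) / n0
  tc <- tc[tc$sensitivity >= min_sensitivity, ]
  rows <- lapply(seq_len(nrow(tc)), function(i) {
    cm <- confusion_matrix(tp = tc$tp[i], fp = tc$fp[i],
                           fn = n1 - tc$tp[i], tn = n0 - tc$fp[i])
    tab <- scenario_table(cm, params, scenarios)
    cbind(threshold = tc$threshold[i], sensitivity = tc$sensitivity[i],
          specificity = tc$specificity[i],
          tab[c("label", "net_per_day", "cost_per_day")])
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$sensitivity, out$threshold, out$label), , drop = FALSE]
}
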