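#' Read and write cohort tables
#'
#' Cohorts are exchanged as comma-separated UTF-8 text with one header
#' row and columns `id`, `age_scaled`, `x01..xK`, `fall`, `los`,
#' `risk_score`; an empty field encodes a missing value. Writing then
#' reading returns an identical cohort (values and missingness).
#'
#' @param cohort A `fall_cohort` data frame.
#' @param path File path.
#' @return `read_cohort()` returns a `fall_cohort` data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = "", fileEncoding = "UTF-8")
  required <- c("id", "fall", "los")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    dup <- which(duplicated(df$id))[1]
    stop("duplicate id at row ", dup)
  }
  bad_fall <- which(!(df$fall %in% c(0, 1)))
  if (length(bad_fall)) {
    stop("non-binary fall indicator at row(s): ",
         paste(utils::head(bad_fall, 5), collapse = ", "))
  }
  bad_los <- which(is.na(df$los) | df$los <= 0)
  if (length(bad_los)) {
    stop("missing or non-positive los at row(s): ",
         paste(utils::head(bad_los, 5), collapse = ", "))
  }
  if (!"risk_score" %in% names(df)) df$risk_score <- NA_real_
  class(df) <- c("fall_cohort", "data.frame")
  df
}

#' Bundled worked-example decision-model inputs
#'
#' A confusion matrix, stay/cost parameters and four intervention
#' scenarios from a fall-screening evaluation on 10,386 hospitalizations
#' of elderly inpatients (228 fallen), shipped as plain-text JSON under
#' `inst/extdata/`. They drive the worked example in the README and the
#' package tests.
#'
#' @return `example_confusion_matrix()`: a [confusion_matrix()];
#'   `example_stay_parameters()`: a [stay_parameters()] object;
#'   `example_scenarios()`: a list of four [scenario()] objects.
#' @export
example_confusion_matrix <- function() {
  j <- jsonlite::read_json(
    system.file("extdata", "example_confusion.json", package = "fallstay"),
    simplifyVector = TRUE)
  confusion_matrix(tp = j$tp, fp = j$fp, fn = j$fn, tn = j$tn)
}

#' @rdname example_confusion_matrix
#' @export
example_stay_parameters <- function() {
  j <- jsonlite::read_json(
    system.file("extdata", "example_stay_parameters.json",
                package = "fallstay"),
    simplifyVector = TRUE)
  stay_parameters(mean_los_fallen = j$mean_los_fallen,
                  mean_los_unfallen = j$mean_los_unfallen,
                  daily_cost = j$daily_cost)
}

#' @rdname example_confusion_matrix
#' @export
example_scenarios <- function() {
  j <- jsonlite::read_json(
    system.file("extdata", "example_scenarios.json", package = "fallstay"),
    simplifyVector = TRUE)
  lapply(seq_len(nrow(j)), function(i) {
    scenario(atet = j$atet[i], prevention_rate = j$prevention_rate[i],
             label = j$label[i])
  })
}
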