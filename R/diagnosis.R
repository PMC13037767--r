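#' Combine the three lines of evidence into a mechanism verdict
#'
#' Operationalizes the decision logic for the missingness mechanism. Little's
#' test is consulted first because MCAR is the more restrictive hypothesis:
#' if its p-value is at or above `alpha`, the verdict is
#' `"MCAR-not-rejected"`. If MCAR is rejected and at least one classifier
#' shows covariate signal — out-of-bag random-forest AUC above its no-signal
#' band (default threshold 0.55, the upper edge of the MCAR simulation band),
#' or at least one significant GEE predictor — the verdict is
#' `"consistent-with-MAR"`. Otherwise the verdict is `"inconclusive"`. MNAR
#' is never asserted: this framework can only find evidence that missingness
#' is related to *observed* variables. A degenerate Little result (df = 0,
#' complete data) yields `"inconclusive"` with an explanation.
#'
#' @param little A [little_test()] result.
#' @param rf An [fit_rf()] result.
#' @param gee A [fit_gee()] (or [forward_select()]) result.
#' @param alpha Significance level shared by all rules (default 0.05).
#' @param auc_threshold OOB AUC above which the forest is called informative.
#' @return A `mechanism_diagnosis` with `verdict`, the evidence fields and a
#'   `narrative` character summary.
#' @export
diagnose <- function(little, rf, gee, alpha = 0.05, auc_threshold = 0.55) {
  stopifnot(inherits(little, "little_result"), inherits(rf, "rf_fit"),
            inherits(gee, "gee_fit"))
  sig_terms <- gee$coefficients |>
    dplyr::filter(.data$term != "(Intercept)", .data$p.value < alpha) |>
    dplyr::pull("term")
  rf_signal <- is.finite(rf$oob_auc) && rf$oob_auc > auc_threshold

  if (is.na(little$p_value)) {
    verdict <- "inconclusive"
    narrative <- paste(
      "Little's test is degenerate (a single missingness pattern, df = 0),",
      "so MCAR cannot be assessed; no mechanism verdict is possible.")
  } else if (little$p_value >= alpha) {
    verdict <- "MCAR-not-rejected"
    narrative <- sprintf(
      paste("Little's test does not reject MCAR (d2 = %.1f, df = %d,",
            "p = %.3f at alpha = %.2f); the data are consistent with",
            "missingness unrelated to observed or unobserved values."),
      little$d2, little$df, little$p_value, alpha)
  } else if (rf_signal || length(sig_terms) > 0) {
    verdict <- "consistent-with-MAR"
    narrative <- sprintf(
      paste("Little's test rejects MCAR (d2 = %.1f, df = %d, p = %.2g).",
            "The cluster-bootstrap random forest %s (OOB AUC = %.3f,",
            "threshold %.2f) and the GEE model %s%s.",
            "Missingness is systematically related to observed variables,",
            "consistent with MAR; MNAR cannot be ruled out or asserted by",
            "these diagnostics."),
      little$d2, little$df, little$p_value,
      if (rf_signal) "discriminates missing nights" else
        "shows no discrimination",
      rf$oob_auc, auc_threshold,
      if (length(sig_terms) > 0) "retains significant predictor(s): " else
        "retains no significant predictors",
      paste(sig_terms, collapse = ", "))
  } else {
    verdict <- "inconclusive"
    narrative <- sprintf(
      paste("Little's test rejects MCAR (p = %.2g) but neither classifier",
            "links missingness to the observed covariates (OOB AUC = %.3f,",
            "no significant GEE predictors): the evidence is inconclusive."),
      little$p_value, rf$oob_auc)
  }

  structure(list(
    verdict = verdict,
    little_p = little$p_value,
    little_d2 = little$d2,
    little_df = little$df,
    rf_auc = rf$auc,
    rf_oob_auc = rf$oob_auc,
    gee_significant_terms = sig_terms,
    alpha = alpha,
    auc_threshold = auc_threshold,
    narrative = narrative
  ), class = "mechanism_diagnosis")
}

#' @export
print.mechanism_diagnosis <- function(x, ...) {
  cat("mechanism verdict:", x$verdict, "\n\n")
  cat(strwrap(x$narrative, width = 78), sep = "\n")
  invisible(x)
}

#' Run the full missingness-diagnosis pipeline
#'
#' Executes the complete workflow on a dataset or a generator configuration:
#' missingness patterns and rate tables, Little's MCAR test on the wide table
#' (five stages by night plus the four covariates; stage durations
#' log1p-transformed for the normal-theory test), the cluster-bootstrap
#' random forest, GEE forward selection, cross-model agreement, and the
#' mechanism verdict. If the input has no missing nights the pipeline exits
#' early with a zero-missingness report. When `out_dir` is given, all tables
#' are written as CSV/JSON plus a human-readable `report.txt`.
#'
#' @param data A `sleep_data` tibble, a path to a long CSV, or `NULL` to
#'   generate data from `config`.
#' @param config A [generator_config()] used when `data` is `NULL`.
#' @param terms Forward-selection candidate order (default: night index,
#'   hr_present, employment, marital, education, household size).
#' @param corstr Working correlation for the GEE stage.
#' @param n_trees,rf_seed Random-forest ensemble size and seed.
#' @param alpha Shared significance level.
#' @param auc_threshold OOB AUC decision threshold (see [diagnose()]).
#' @param out_dir Optional output directory.
#' @return A `missingness_report` list with elements `data`, `patterns`,
#'   `rates_night`, `rates_site`, `little`, `rf`, `gee`, `agreement`,
#'   `diagnosis` (or `verdict = "no-missing-data"` for complete data).
#' @export
run_pipeline <- function(data = NULL, config = generator_config(),
                         terms = c("night_index", "hr_present", "employed",
                                   "married", "education_level",
                                   "household_size"),
                         corstr = "exchangeable", n_trees = 500L,
                         rf_seed = 1L, alpha = 0.05, auc_threshold = 0.55,
                         out_dir = NULL) {
  ds <- if (is.null(data)) {
    generate_sleep_data(config)
  } else if (is.character(data)) {
    read_long_csv(data)
  } else if (inherits(data, "sleep_data")) data else as_sleep_data(data)

  stage <- "patterns"
  res <- tryCatch({
    patterns <- enumerate_patterns(ds)
    rates_night <- missingness_rates(ds, by = "night_index")
    rates_site <- missingness_rates(ds, by = "site")

    if (sum(ds$missing) == 0) {
      out <- structure(list(
        data = ds, patterns = patterns, rates_night = rates_night,
        rates_site = rates_site, verdict = "no-missing-data",
        narrative = "No missing nights: nothing to diagnose."),
        class = "missingness_report")
      return(out)
    }

    stage <- "little"
    wide <- to_wide(ds)
    stage_cols <- grep("_s_n[0-9]+$", names(wide), value = TRUE)
    wide_t <- dplyr::mutate(wide,
                            dplyr::across(dplyr::all_of(stage_cols), log1p))
    little <- little_test(wide_t[setdiff(names(wide_t), "participant_id")])

    stage <- "random forest"
    rf <- fit_rf(ds, n_trees = n_trees, seed = rf_seed)

    stage <- "GEE"
    gee <- forward_select(ds, terms, alpha = alpha, corstr = corstr)

    stage <- "agreement"
    agreement <- compare_predictions(rf$predictions$pred,
                                     gee$predictions$pred)

    stage <- "diagnosis"
    dx <- diagnose(little, rf, gee, alpha = alpha,
                   auc_threshold = auc_threshold)

    structure(list(
      data = ds, patterns = patterns, rates_night = rates_night,
      rates_site = rates_site, little = little, rf = rf, gee = gee,
      agreement = agreement, diagnosis = dx, verdict = dx$verdict),
      class = "missingness_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("== missingness diagnosis report ==\n")
  print(x$data)
  cat("\n-- per-night missingness --\n")
  print(tibble::as_tibble(x$rates_night), n = Inf)
  if (identical(x$verdict, "no-missing-data")) {
    cat("\n", x$narrative, "\n", sep = "")
    return(invisible(x))
  }
  cat("\n-- Little's MCAR test --\n"); print(x$little)
  cat("\n-- random forest --\n"); print(x$rf)
  cat("\n-- GEE (final model) --\n"); print(x$gee)
  cat("\n-- model agreement --\n"); print(x$agreement)
  cat("\n"); print(x$diagnosis)
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  readr::write_csv(tibble::as_tibble(report$patterns), fp("patterns.csv"))
  readr::write_csv(tibble::as_tibble(report$rates_night),
                   fp("rates_night.csv"))
  readr::write_csv(tibble::as_tibble(report$rates_site), fp("rates_site.csv"))
  if (!identical(report$verdict, "no-missing-data")) {
    jsonlite::write_json(glance(report$little), fp("little.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(
      list(auc = report$rf$auc, oob_auc = report$rf$oob_auc,
           confusion = unclass(report$rf$confusion),
           importance = as.list(report$rf$importance),
           n_trees = report$rf$n_trees, seed = report$rf$seed),
      fp("rf.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(report$rf$predictions, fp("rf_predictions.csv"))
    jsonlite::write_json(
      list(coefficients = tidy(report$gee), qic = report$gee$qic,
           alpha = report$gee$alpha, corstr = report$gee$corstr,
           confusion = unclass(report$gee$confusion)),
      fp("gee.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(report$gee$predictions, fp("gee_predictions.csv"))
    jsonlite::write_json(unclass(report$agreement), fp("agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      unclass(report$diagnosis), fp("diagnosis.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  writeLines(utils::capture.output(print(report)), fp("report.txt"))
  invisible(out_dir)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
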