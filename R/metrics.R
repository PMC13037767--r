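#' Confusion matrix for night-level missingness predictions
#'
#' Positive class is "night missing" (coded 1), so `tp` counts missing nights
#' predicted missing and `tn` observed nights predicted observed.
#'
#' @param truth,pred Binary 0/1 vectors of equal length.
#' @return A `confusion_matrix` object with fields `tn`, `fp`, `fn`, `tp`.
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(0, 1)), all(pred %in% c(0, 1)))
  structure(list(
    tn = sum(truth == 0 & pred == 0),
    fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0),
    tp = sum(truth == 1 & pred == 1)
  ), class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Sensitivity is the true-positive rate for the "missing" class; specificity
#' the true-negative rate for the "present" class. Metrics whose denominator
#' class is empty are returned as `NA` with a warning.
#'
#' @param cm A [confusion_matrix()], or a list/vector with `tn`, `fp`, `fn`,
#'   `tp`.
#' @return A one-row tibble with raw fractions (`accuracy`, `sensitivity`,
#'   `specificity`) and their 2-decimal renderings (`*_2dp`).
#' @export
confusion_metrics <- function(cm) {
  cm <- as.list(cm)
  stopifnot(all(c("tn", "fp", "fn", "tp") %in% names(cm)))
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sens <- if (cm$tp + cm$fn == 0) {
    warning("no positive (missing) nights: sensitivity undefined",
            call. = FALSE); NA_real_
  } else cm$tp / (cm$tp + cm$fn)
  spec <- if (cm$tn + cm$fp == 0) {
    warning("no negative (present) nights: specificity undefined",
            call. = FALSE); NA_real_
  } else cm$tn / (cm$tn + cm$fp)
  acc <- (cm$tn + cm$tp) / total
  tibble::tibble(accuracy = acc, sensitivity = sens, specificity = spec,
                 accuracy_2dp = round(acc, 2),
                 sensitivity_2dp = round(sens, 2),
                 specificity_2dp = round(spec, 2))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2,
              dimnames = list(predicted = c("0 (present)", "1 (missing)"),
                              truth = c("0 (present)", "1 (missing)")))
  print(m)
  invisible(x)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC: the probability that a randomly chosen positive
#' (missing) night receives a higher score than a randomly chosen negative
#' night, counting ties as 1/2.
#'
#' @param scores Numeric scores (e.g. predicted missingness probabilities).
#' @param labels Binary 0/1 labels; 1 = missing.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-tabulate two models' night-level predictions
#'
#' Aligns the random-forest and GEE predicted classes on (participant, night)
#' and cross-tabulates them, reporting the agreement fraction.
#'
#' @param rf_pred,gee_pred Either binary 0/1 vectors in the same night order,
#'   or prediction tibbles with `participant_id`, `night_index` and `pred`
#'   columns (as produced by [fit_rf()] and [fit_gee()]); tibbles are joined
#'   on the key columns and misaligned keys raise an error.
#' @return An `agreement_table` with `both_0`, `rf_only_1`, `gee_only_1`,
#'   `both_1`, `n`, `n_agree` and `agreement`.
#' @export
compare_predictions <- function(rf_pred, gee_pred) {
  if (is.data.frame(rf_pred) && is.data.frame(gee_pred)) {
    key <- c("participant_id", "night_index")
    a <- dplyr::arrange(tibble::as_tibble(rf_pred[c(key, "pred")]),
                        .data$participant_id, .data$night_index)
    b <- dplyr::arrange(tibble::as_tibble(gee_pred[c(key, "pred")]),
                        .data$participant_id, .data$night_index)
    if (!identical(a[key], b[key])) {
      stop("prediction tables are not aligned on (participant, night)",
           call. = FALSE)
    }
    rf_pred <- a$pred; gee_pred <- b$pred
  }
  stopifnot(length(rf_pred) == length(gee_pred),
            all(rf_pred %in% c(0, 1)), all(gee_pred %in% c(0, 1)))
  res <- list(
    both_0 = sum(rf_pred == 0 & gee_pred == 0),
    rf_only_1 = sum(rf_pred == 1 & gee_pred == 0),
    gee_only_1 = sum(rf_pred == 0 & gee_pred == 1),
    both_1 = sum(rf_pred == 1 & gee_pred == 1))
  res$n <- length(rf_pred)
  res$n_agree <- res$both_0 + res$both_1
  res$agreement <- res$n_agree / res$n
  structure(res, class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  m <- matrix(c(x$both_0, x$rf_only_1, x$gee_only_1, x$both_1), 2, 2,
              dimnames = list(`RF` = c("0", "1"), `GEE` = c("0", "1")))
  print(m)
  cat(sprintf("agreement: %d/%d (%.0f%%)\n", x$n_agree, x$n,
              100 * x$agreement))
  invisible(x)
}
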