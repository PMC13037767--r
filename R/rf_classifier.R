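RF_PREDICTORS <- c("night_index", "household_size", "education_level",
                   "employed", "married", "hr_present")

#' Cluster-adjusted bootstrap resample of a longitudinal dataset
#'
#' Draws participants (clusters) with replacement and assembles the resample
#' from *all* nights of each drawn participant, so within-subject correlation
#' is preserved and night rows are never split across draws. Participants
#' drawn more than once receive fresh identifiers (`<id>.b2`, `<id>.b3`, ...);
#' the original identifier is kept in `source_id`.
#'
#' @param ds A `sleep_data` tibble (or any long data frame with a
#'   `participant_id` column).
#' @param seed Optional integer seed.
#' @return A tibble with the same columns plus `source_id`; exactly
#'   `n_nights` rows per drawn cluster.
#' @export
cluster_bootstrap <- function(ds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- tibble::as_tibble(ds)
  rows <- split(seq_len(nrow(d)), d$participant_id)
  ids <- names(rows)
  draw <- sample(ids, length(ids), replace = TRUE)
  copy <- stats::ave(seq_along(draw), draw, FUN = seq_along)
  new_id <- ifelse(copy == 1, draw, paste0(draw, ".b", copy))
  sizes <- lengths(rows[draw])
  out <- d[unlist(rows[draw], use.names = FALSE), ]
  out$source_id <- out$participant_id
  out$participant_id <- rep(new_id, sizes)
  out
}

#' Random-forest missingness classifier with cluster-adjusted bootstrap
#'
#' Grows an ensemble of classification trees for the binary night-missingness
#' indicator from the six night-level predictors (night index, household
#' size, education level, employment, marital status, prior-day heart-rate
#' presence). Unlike a standard random forest, each tree's bootstrap sample
#' is a [cluster_bootstrap()] resample of whole participants, preserving
#' within-subject correlation. Each tree still samples `mtry` predictors at
#' every split. A night's predicted missingness probability is the fraction
#' of trees voting "missing"; AUC and the 0.5-threshold confusion matrix are
#' computed over all participant-nights, and an out-of-bag (OOB) AUC is
#' computed from, for each night, only the trees whose resample excluded that
#' night's participant.
#'
#' @param ds A `sleep_data` tibble.
#' @param n_trees Number of trees (default 500).
#' @param mtry Predictors sampled per split (default `floor(sqrt(6)) = 2`).
#' @param seed Integer seed for the ensemble.
#' @param predictors Predictor columns (default the six study predictors).
#' @return An `rf_fit` with `auc` (in-sample), `oob_auc`, `confusion`
#'   (in-sample, 0.5 votes threshold), `oob_confusion`, per-predictor
#'   `importance` (mean decrease in Gini summed over trees), and a
#'   `predictions` tibble (participant, night, vote fractions, classes).
#' @export
fit_rf <- function(ds, n_trees = 500L, mtry = 2L, seed = 1L,
                   predictors = RF_PREDICTORS) {
  d <- tibble::as_tibble(ds)
  absent <- setdiff(c(predictors, "missing", "participant_id"), names(d))
  if (length(absent) > 0) {
    stop("column(s) not in data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (dplyr::n_distinct(d$missing) < 2) {
    stop("outcome has a single class: AUC undefined", call. = FALSE)
  }
  d <- dplyr::arrange(d, .data$participant_id, .data$night_index)
  x_all <- as.data.frame(
    dplyr::mutate(d[predictors],
                  dplyr::across(dplyr::everything(), as.numeric)))
  y_all <- factor(d$missing, levels = c(0, 1))
  n <- nrow(d)

  set.seed(seed)
  votes <- matrix(0L, n, n_trees)
  inbag <- matrix(FALSE, n, n_trees)  # row's participant in tree's resample
  importance <- setNames(numeric(length(predictors)), predictors)
  ids <- d$participant_id
  rows <- split(seq_len(n), ids)
  uids <- names(rows)

  for (b in seq_len(n_trees)) {
    for (try in 1:20) {
      draw <- sample(uids, length(uids), replace = TRUE)
      idx <- unlist(rows[draw], use.names = FALSE)
      if (length(unique(y_all[idx])) == 2) break
    }
    tree <- randomForest::randomForest(
      x = x_all[idx, , drop = FALSE], y = y_all[idx],
      ntree = 1, mtry = mtry, replace = FALSE, sampsize = length(idx))
    votes[, b] <- as.integer(
      predict(tree, newdata = x_all, type = "response") == "1")
    inbag[, b] <- ids %in% draw
    imp <- randomForest::importance(tree)[, 1]
    importance[names(imp)] <- importance[names(imp)] + imp
  }

  prob_in <- rowMeans(votes)
  oob_trees <- !inbag
  n_oob <- rowSums(oob_trees)
  prob_oob <- rowSums(votes * oob_trees) / pmax(n_oob, 1)
  prob_oob[n_oob == 0] <- NA_real_

  truth <- as.integer(d$missing)
  pred_in <- as.integer(prob_in >= 0.5)
  ok <- !is.na(prob_oob)
  pred_oob <- as.integer(prob_oob[ok] >= 0.5)

  predictions <- tibble::tibble(
    participant_id = d$participant_id, night_index = d$night_index,
    truth = truth, prob = prob_in, pred = pred_in,
    prob_oob = prob_oob,
    pred_oob = ifelse(is.na(prob_oob), NA_integer_,
                      as.integer(prob_oob >= 0.5)))

  structure(list(
    auc = auc(prob_in, truth),
    oob_auc = auc(prob_oob[ok], truth[ok]),
    confusion = confusion_matrix(truth, pred_in),
    oob_confusion = confusion_matrix(truth[ok], pred_oob),
    importance = importance / n_trees,
    n_trees = n_trees, mtry = mtry, seed = seed,
    predictors = predictors,
    predictions = predictions
  ), class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf(
    "cluster-bootstrap random forest (%d trees, mtry %d)\n", x$n_trees,
    x$mtry))
  cat(sprintf("  in-sample AUC %.3f | OOB AUC %.3f\n", x$auc, x$oob_auc))
  print(confusion_metrics(x$confusion)[1:3])
  invisible(x)
}

#' One-row summary of a random-forest fit
#'
#' @param x An `rf_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the in-sample and OOB AUC, accuracy at the
#'   0.5 vote threshold, tree count and seed.
#' @method glance rf_fit
#' @export
glance.rf_fit <- function(x, ...) {
  m <- confusion_metrics(x$confusion)
  tibble::tibble(auc = x$auc, oob.auc = x$oob_auc, accuracy = m$accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 n.trees = x$n_trees, seed = x$seed)
}

#' Tidy variable importances of a random-forest fit
#'
#' @param x An `rf_fit`.
#' @param ... Unused.
#' @return A tibble of per-predictor mean decrease in Gini (per tree),
#'   descending.
#' @method tidy rf_fit
#' @export
tidy.rf_fit <- function(x, ...) {
  tibble::tibble(term = names(x$importance),
                 importance = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
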