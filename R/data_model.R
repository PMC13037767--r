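#' @importFrom rlang .data %||% :=
#' @importFrom stats plogis qlogis rbinom rlnorm rnorm runif predict setNames
#' @importFrom utils head
NULL

STAGE_COLS <- c("deep_s", "light_s", "rem_s", "awake_s", "unmeasurable_s")
COVARIATE_COLS <- c("household_size", "education_level", "employed",
                    "married", "n_children", "site")
#' Wide-format covariates used by the MCAR test and the reshaper
#' (marital status, household size, education, employment).
#' @noRd
WIDE_COVARIATES <- c("married", "household_size", "education_level", "employed")

#' Construct and validate a longitudinal sleep dataset
#'
#' A sleep dataset is a long-format tibble with one row per participant-night:
#' five sleep-stage durations in seconds (`deep_s`, `light_s`, `rem_s`,
#' `awake_s`, `unmeasurable_s`), a `night_index` in `1:n_nights`, a binary
#' `hr_present` flag (heart-rate data present for the day *before* the night),
#' and per-participant covariates (`household_size`, `education_level`,
#' `employed`, `married`, `n_children`, `site`) that are constant within
#' participant. The binary `missing` indicator (1 = night missing) is derived:
#' a night is missing if and only if its total sleep duration is absent, and a
#' night must be either fully observed (all five stages present) or fully
#' missing. Zero stage durations on observed nights are valid data, not
#' missingness; a zero for light sleep on an observed night triggers a warning
#' because devices record light sleep on every real observed night.
#'
#' @param data A data frame in long format (one row per participant-night).
#' @param n_nights Number of nights per participant (default 5).
#' @return A validated `sleep_data` tibble with a derived `missing` column and
#'   a derived `total_sleep_s` column (deep + light + REM + unmeasurable) on
#'   observed nights.
#' @export
as_sleep_data <- function(data, n_nights = 5L) {
  data <- tibble::as_tibble(data)
  required <- c("participant_id", "night_index", STAGE_COLS, "hr_present",
                COVARIATE_COLS)
  miss_cols <- setdiff(required, names(data))
  if (length(miss_cols) > 0) {
    stop("sleep data is missing required columns: ",
         paste(miss_cols, collapse = ", "), call. = FALSE)
  }

  dup <- data |>
    dplyr::count(.data$participant_id, .data$night_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (participant, night) rows, e.g. participant ",
         dup$participant_id[1], " night ", dup$night_index[1], call. = FALSE)
  }

  bad_night <- data |>
    dplyr::filter(!.data$night_index %in% seq_len(n_nights))
  if (nrow(bad_night) > 0) {
    stop("night_index outside 1..", n_nights, " for participant ",
         bad_night$participant_id[1], call. = FALSE)
  }

  counts <- data |> dplyr::count(.data$participant_id)
  if (any(counts$n != n_nights)) {
    off <- counts$participant_id[counts$n != n_nights][1]
    stop("every participant needs exactly ", n_nights,
         " night rows; participant ", off, " has ",
         counts$n[counts$participant_id == off], call. = FALSE)
  }

  stage_na <- as.matrix(is.na(data[STAGE_COLS]))
  n_absent <- rowSums(stage_na)
  mixed <- n_absent > 0 & n_absent < length(STAGE_COLS)
  if (any(mixed)) {
    i <- which(mixed)[1]
    stop("mixed partially-missing night: participant ",
         data$participant_id[i], " night ", data$night_index[i],
         " has some but not all stages recorded; nights must be fully ",
         "observed or fully missing", call. = FALSE)
  }
  data$missing <- as.integer(n_absent == length(STAGE_COLS))

  obs <- data$missing == 0L
  neg <- obs & (data$deep_s < 0 | data$light_s < 0 | data$rem_s < 0 |
                  data$awake_s < 0 | data$unmeasurable_s < 0)
  if (any(neg)) {
    stop("negative stage duration for participant ",
         data$participant_id[which(neg)[1]], call. = FALSE)
  }
  if (any(obs & data$light_s == 0)) {
    warning("observed night(s) with 0 s of light sleep: unusual for ",
            "device-scored sleep; values kept as recorded", call. = FALSE)
  }

  cov_bad <- data |>
    dplyr::summarise(dplyr::across(dplyr::all_of(COVARIATE_COLS),
                                   dplyr::n_distinct),
                     .by = "participant_id") |>
    dplyr::filter(dplyr::if_any(dplyr::all_of(COVARIATE_COLS), ~ .x > 1))
  if (nrow(cov_bad) > 0) {
    stop("covariates must be constant within participant; participant ",
         cov_bad$participant_id[1], " varies", call. = FALSE)
  }
  if (anyNA(data[COVARIATE_COLS])) {
    stop("covariates may not contain missing values", call. = FALSE)
  }
  if (anyNA(data$hr_present) || !all(data$hr_present %in% c(0, 1))) {
    stop("hr_present must be 0/1 with no missing values", call. = FALSE)
  }

  data$total_sleep_s <- ifelse(
    obs, data$deep_s + data$light_s + data$rem_s + data$unmeasurable_s,
    NA_real_)

  data <- data |>
    dplyr::arrange(.data$participant_id, .data$night_index)
  class(data) <- c("sleep_data", class(tibble::tibble()))
  attr(data, "n_nights") <- as.integer(n_nights)
  data
}

#' Read a long-format sleep CSV
#'
#' Reads a UTF-8 CSV with a header row, one row per participant-night, renames
#' columns according to `schema`, derives the night-level `missing` indicator
#' (a night is missing iff no sleep information was recorded for it), and
#' validates the whole-night missingness invariant.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(deep_s = "deepSleepSeconds")`. Unmapped canonical names are assumed to
#'   be present verbatim.
#' @param n_nights Nights per participant (default 5).
#' @return A validated [as_sleep_data()] tibble.
#' @export
read_long_csv <- function(path, schema = NULL, n_nights = 5L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent) > 0) {
      stop("schema names columns absent from file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(schema, names(schema)))
  }
  ds <- as_sleep_data(raw, n_nights = n_nights)
  message(sprintf(
    "read %d participants x %d nights (%d rows); %d missing nights of %d",
    dplyr::n_distinct(ds$participant_id), attr(ds, "n_nights"), nrow(ds),
    sum(ds$missing), nrow(ds)))
  ds
}

#' Write a sleep dataset to the canonical long CSV
#'
#' @param ds A `sleep_data` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(ds, path) {
  cols <- c("participant_id", "night_index", STAGE_COLS, "hr_present",
            COVARIATE_COLS, "missing")
  readr::write_csv(dplyr::select(tibble::as_tibble(ds),
                                 dplyr::all_of(cols)), path)
  invisible(path)
}

#' Reshape a sleep dataset to wide format
#'
#' One row per participant; one column per requested sleep stage and night
#' (`deep_s_n1` ... `unmeasurable_s_n5`), followed by the four covariates used
#' by the MCAR test (marital status, household size, education level,
#' employment status). Missing nights yield `NA` cells.
#'
#' @param ds A `sleep_data` tibble.
#' @param variables Stage columns to spread; default all five stages.
#' @return A tibble with `n_participants` rows.
#' @export
to_wide <- function(ds, variables = STAGE_COLS) {
  unknown <- setdiff(variables, STAGE_COLS)
  if (length(unknown) > 0) {
    stop("unknown stage variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  covs <- tibble::as_tibble(ds) |>
    dplyr::distinct(.data$participant_id,
                    dplyr::pick(dplyr::all_of(WIDE_COVARIATES)))
  wide <- tibble::as_tibble(ds) |>
    dplyr::select(dplyr::all_of(c("participant_id", "night_index", variables))) |>
    tidyr::pivot_wider(names_from = "night_index",
                       values_from = dplyr::all_of(variables),
                       names_glue = "{.value}_n{night_index}")
  dplyr::left_join(wide, covs, by = "participant_id")
}

#' Reshape a wide table produced by [to_wide()] back to long format
#'
#' @param wide A wide tibble with `<stage>_n<night>` columns.
#' @return A long tibble with `participant_id`, `night_index` and the stage
#'   columns present in `wide`.
#' @export
to_long <- function(wide) {
  stage_cols <- grep("^(deep|light|rem|awake|unmeasurable)_s_n[0-9]+$",
                     names(wide), value = TRUE)
  if (length(stage_cols) == 0) stop("no stage-by-night columns found",
                                    call. = FALSE)
  wide |>
    dplyr::select(dplyr::all_of(c("participant_id", stage_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(stage_cols),
                        names_to = c(".value", "night_index"),
                        names_pattern = "^(.*_s)_n([0-9]+)$") |>
    dplyr::mutate(night_index = as.integer(.data$night_index)) |>
    dplyr::arrange(.data$participant_id, .data$night_index)
}

#' @export
print.sleep_data <- function(x, ...) {
  cat(sprintf("<sleep_data> %d participants x %d nights; %d/%d nights missing (%.0f%%)\n",
              dplyr::n_distinct(x$participant_id), attr(x, "n_nights"),
              sum(x$missing), nrow(x), 100 * mean(x$missing)))
  NextMethod()
}
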