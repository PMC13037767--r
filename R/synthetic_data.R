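#' Configuration for the synthetic sleep-cohort generator
#'
#' Builds the configuration for [generate_sleep_data()]. Defaults emulate a
#' five-night wearable sleep study in a 299-woman cohort: the MAR deletion
#' model defaults to the fitted missingness logit
#' `intercept + slope * night_index + employment_effect * employed`
#' with coefficients (-1.8546, 0.2554, 0.6671), which yields ~30% overall
#' missingness rising across nights, and the covariate marginals default to
#' the cohort's (32% employed; children distribution 38/42/18/2%).
#'
#' @param n_participants Number of participants (default 299).
#' @param n_nights Nights per participant (default 5).
#' @param mechanism One of `"MCAR"`, `"MAR"`, `"MNAR"`, `"NONE"`.
#' @param mcar_prob Constant per-night deletion probability under MCAR.
#' @param mar_coefficients Named numeric: `intercept`, `night`, `employed` on
#'   the logit scale.
#' @param mnar_coefficient Additional logit effect of the night's own
#'   standardized (to-be-deleted) total sleep under MNAR.
#' @param employment_rate,married_rate Bernoulli covariate rates.
#' @param household_size_probs Probabilities over household sizes `1:length`.
#' @param education_probs Probabilities over ordinal education levels
#'   `1:length` (default: some primary / completed primary / secondary).
#' @param children_probs Probabilities over `0:(length-1)` children.
#' @param sites Site labels, assigned in (almost) equal blocks.
#' @param stage_meanlog,stage_sdlog Named per-stage lognormal parameters for
#'   the stage durations in seconds (names `deep_s`, `light_s`, `rem_s`,
#'   `awake_s`, `unmeasurable_s`).
#' @param unmeasurable_zero_prob Probability an observed night records 0 s of
#'   unmeasurable sleep (zeros are common and are valid data).
#' @param awake_zero_prob Probability an observed night records 0 s awake.
#' @param total_sleep_range_s Plausibility envelope for nightly total sleep
#'   (deep + light + REM + unmeasurable); nights outside it are redrawn.
#' @param hr_prob_observed P(hr_present = 1) for an observed night.
#' @param hr_prob_missing P(hr_present = 1) for a deleted night. `NULL`
#'   (default) resolves per mechanism: 0.6 under MAR/MNAR (heart-rate presence
#'   tracks device wear, so non-wear nights lose both), and equal to
#'   `hr_prob_observed` under MCAR/NONE (a mechanism that is MCAR with respect
#'   to the modeled predictors requires deletion independent of all of them,
#'   hr_present included).
#' @param complete_case_prob Probability a participant independently loses all
#'   nights regardless of covariates (device never recorded). Default 0: the
#'   MAR logit model alone already produces all-missing participants at its
#'   implied rate; raise this to emulate additional device-level failure.
#' @param seed Integer master seed; split internally into substreams for
#'   covariates, sleep values and deletion so that each component is
#'   reproducible in isolation.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_participants = 299L,
                             n_nights = 5L,
                             mechanism = c("MAR", "MCAR", "MNAR", "NONE"),
                             mcar_prob = 0.30,
                             mar_coefficients = c(intercept = -1.8546,
                                                  night = 0.2554,
                                                  employed = 0.6671),
                             mnar_coefficient = 1.0,
                             employment_rate = 0.32,
                             married_rate = 0.45,
                             household_size_probs = c(0.15, 0.25, 0.25,
                                                      0.18, 0.10, 0.07),
                             education_probs = c(0.42, 0.50, 0.08),
                             children_probs = c(0.381, 0.418, 0.184, 0.017),
                             sites = c("Banda", "Bwaise", "Makindye"),
                             stage_meanlog = c(deep_s = log(4500) - 0.45^2 / 2,
                                               light_s = log(14400) - 0.25^2 / 2,
                                               rem_s = log(5800) - 0.45^2 / 2,
                                               awake_s = log(1500) - 0.8^2 / 2,
                                               unmeasurable_s = log(400) - 0.9^2 / 2),
                             stage_sdlog = c(deep_s = 0.45, light_s = 0.25,
                                             rem_s = 0.45, awake_s = 0.8,
                                             unmeasurable_s = 0.9),
                             unmeasurable_zero_prob = 0.70,
                             awake_zero_prob = 0.03,
                             total_sleep_range_s = c(3600, 45000),
                             hr_prob_observed = 0.95,
                             hr_prob_missing = NULL,
                             complete_case_prob = 0,
                             seed = 1L) {
  mechanism <- match.arg(mechanism)
  probs <- c(mcar_prob, employment_rate, married_rate, hr_prob_observed,
             complete_case_prob, unmeasurable_zero_prob, awake_zero_prob,
             hr_prob_missing)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_nights < 1) stop("n_nights must be >= 1", call. = FALSE)
  for (d in list(household_size_probs, education_probs, children_probs)) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8) {
      stop("covariate marginals must be probability vectors summing to 1",
           call. = FALSE)
    }
  }
  if (is.null(hr_prob_missing)) {
    hr_prob_missing <- if (mechanism %in% c("MAR", "MNAR")) 0.6 else
      hr_prob_observed
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_nights = as.integer(n_nights),
    mechanism = mechanism,
    mcar_prob = mcar_prob,
    mar_coefficients = mar_coefficients,
    mnar_coefficient = mnar_coefficient,
    employment_rate = employment_rate,
    married_rate = married_rate,
    household_size_probs = household_size_probs,
    education_probs = education_probs,
    children_probs = children_probs,
    sites = sites,
    stage_meanlog = stage_meanlog,
    stage_sdlog = stage_sdlog,
    unmeasurable_zero_prob = unmeasurable_zero_prob,
    awake_zero_prob = awake_zero_prob,
    total_sleep_range_s = total_sleep_range_s,
    hr_prob_observed = hr_prob_observed,
    hr_prob_missing = hr_prob_missing,
    complete_case_prob = complete_case_prob,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Ground-truth mechanism of a generator configuration
#'
#' @param config A [generator_config()].
#' @return The configured mechanism label, for use as ground truth in
#'   mechanism-recovery studies.
#' @export
true_mechanism <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  config$mechanism
}

# deterministic substream seeds from the master seed (Lehmer step),
# kept below 2^31 so set.seed() accepts them
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483629)
}

#' Generate a synthetic longitudinal sleep dataset
#'
#' Draws complete sleep-stage durations for every participant-night first
#' (independent lognormals per stage, nightly totals redrawn into the
#' plausibility envelope), draws per-participant covariates from their
#' marginals, then deletes whole nights according to the configured mechanism:
#' MCAR with constant probability; MAR with probability
#' `plogis(intercept + slope * night_index + effect * employed)`; MNAR adding
#' `mnar_coefficient` times the night's own standardized total sleep to that
#' logit; NONE deletes nothing. Deletion always removes all five stage values
#' for the night, so generated data satisfy the whole-night missingness
#' invariant by construction. `hr_present` is drawn Bernoulli with a rate that
#' may differ between observed and deleted nights (see [generator_config()]).
#'
#' @param config A [generator_config()].
#' @return A validated `sleep_data` tibble; the config is attached as the
#'   `"generator_config"` attribute.
#' @export
generate_sleep_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  k <- config$n_nights

  # covariates substream
  set.seed(substream_seed(config$seed, 1L))
  covs <- tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    household_size = sample.int(length(config$household_size_probs), n,
                                replace = TRUE,
                                prob = config$household_size_probs),
    education_level = sample.int(length(config$education_probs), n,
                                 replace = TRUE,
                                 prob = config$education_probs),
    employed = rbinom(n, 1, config$employment_rate),
    married = rbinom(n, 1, config$married_rate),
    n_children = sample.int(length(config$children_probs), n,
                            replace = TRUE,
                            prob = config$children_probs) - 1L,
    site = config$sites[ceiling(seq_len(n) / (n / length(config$sites)))]
  )

  # sleep-value substream: complete data for every night
  set.seed(substream_seed(config$seed, 2L))
  nn <- n * k
  draw_stages <- function(m) {
    s <- tibble::tibble(
      deep_s = rlnorm(m, config$stage_meanlog["deep_s"],
                      config$stage_sdlog["deep_s"]),
      light_s = rlnorm(m, config$stage_meanlog["light_s"],
                       config$stage_sdlog["light_s"]),
      rem_s = rlnorm(m, config$stage_meanlog["rem_s"],
                     config$stage_sdlog["rem_s"]),
      awake_s = rlnorm(m, config$stage_meanlog["awake_s"],
                       config$stage_sdlog["awake_s"]) *
        rbinom(m, 1, 1 - config$awake_zero_prob),
      unmeasurable_s = rlnorm(m, config$stage_meanlog["unmeasurable_s"],
                              config$stage_sdlog["unmeasurable_s"]) *
        rbinom(m, 1, 1 - config$unmeasurable_zero_prob)
    )
    round(s)
  }
  stages <- draw_stages(nn)
  total <- stages$deep_s + stages$light_s + stages$rem_s +
    stages$unmeasurable_s
  lo <- config$total_sleep_range_s[1]; hi <- config$total_sleep_range_s[2]
  for (it in seq_len(50)) {
    out <- which(total < lo | total > hi)
    if (length(out) == 0) break
    redraw <- draw_stages(length(out))
    stages[out, ] <- redraw
    total[out] <- redraw$deep_s + redraw$light_s + redraw$rem_s +
      redraw$unmeasurable_s
  }

  records <- tibble::tibble(
    participant_id = rep(covs$participant_id, each = k),
    night_index = rep(seq_len(k), times = n)
  ) |>
    dplyr::bind_cols(stages) |>
    dplyr::left_join(covs, by = "participant_id")
  records$total_complete_s <- total

  # deletion substream
  set.seed(substream_seed(config$seed, 3L))
  p_del <- switch(config$mechanism,
    NONE = rep(0, nn),
    MCAR = rep(config$mcar_prob, nn),
    MAR = plogis(config$mar_coefficients["intercept"] +
                   config$mar_coefficients["night"] * records$night_index +
                   config$mar_coefficients["employed"] * records$employed),
    MNAR = plogis(config$mar_coefficients["intercept"] +
                    config$mar_coefficients["night"] * records$night_index +
                    config$mar_coefficients["employed"] * records$employed +
                    config$mnar_coefficient *
                      as.numeric(scale(records$total_complete_s)))
  )
  del <- rbinom(nn, 1, p_del) == 1
  if (config$complete_case_prob > 0) {
    lost <- covs$participant_id[
      rbinom(n, 1, config$complete_case_prob) == 1]
    del <- del | records$participant_id %in% lost
  }
  for (col in STAGE_COLS) records[[col]][del] <- NA_real_

  records$hr_present <- rbinom(
    nn, 1, ifelse(del, config$hr_prob_missing, config$hr_prob_observed))

  ds <- as_sleep_data(
    dplyr::select(records, -"total_complete_s"), n_nights = k)
  attr(ds, "generator_config") <- config
  ds
}

#' Write a generated dataset plus a JSON sidecar with its config
#'
#' @param ds A generated `sleep_data` tibble.
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_generated <- function(ds, path) {
  write_long_csv(ds, path)
  cfg <- attr(ds, "generator_config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
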