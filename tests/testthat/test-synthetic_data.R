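test_that("config validation and ground-truth mechanism labels", {
  expect_error(generator_config(mcar_prob = 1.3), "probabilities")
  expect_error(generator_config(n_nights = 0), "n_nights")
  expect_error(generator_config(children_probs = c(0.5, 0.6)), "summing to 1")
  expect_error(generator_config(mechanism = "MACR"), "arg")
  for (m in c("MCAR", "MAR", "MNAR", "NONE")) {
    expect_identical(true_mechanism(generator_config(mechanism = m)), m)
  }
})

test_that("mechanism NONE yields a complete dataset", {
  ds <- generate_sleep_data(generator_config(n_participants = 30L,
                                             mechanism = "NONE", seed = 2))
  expect_equal(sum(ds$missing), 0)
  expect_false(anyNA(ds$deep_s))
})

test_that("identical seeds reproduce the dataset bit for bit", {
  cfg <- generator_config(n_participants = 25L, seed = 123)
  expect_identical(tibble::as_tibble(generate_sleep_data(cfg)),
                   tibble::as_tibble(generate_sleep_data(cfg)))
  other <- generate_sleep_data(generator_config(n_participants = 25L,
                                                seed = 124))
  expect_false(identical(tibble::as_tibble(generate_sleep_data(cfg)),
                         tibble::as_tibble(other)))
})

test_that("seed substreams isolate components: deletion config leaves sleep values alone", {
  a <- generate_sleep_data(generator_config(n_participants = 20L,
                                            mechanism = "MCAR",
                                            mcar_prob = 0.2, seed = 7))
  b <- generate_sleep_data(generator_config(n_participants = 20L,
                                            mechanism = "MCAR",
                                            mcar_prob = 0.4, seed = 7))
  expect_identical(a$employed, b$employed)
  both <- a$missing == 0 & b$missing == 0
  expect_identical(a$light_s[both], b$light_s[both])
})

test_that("MCAR missing fraction lies in the exact binomial 99% interval", {
  cfg <- generator_config(mechanism = "MCAR", mcar_prob = 0.30, seed = 31)
  ds <- generate_sleep_data(cfg)
  n <- nrow(ds)
  expect_equal(n, 1495)
  bounds <- qbinom(c(0.005, 0.995), n, 0.30)
  expect_gte(sum(ds$missing), bounds[1])
  expect_lte(sum(ds$missing), bounds[2])
})

test_that("MAR defaults: per-night missingness rises across nights", {
  ds <- generate_sleep_data(generator_config(n_participants = 2000L,
                                             seed = 11))
  rate <- tibble::as_tibble(ds) |>
    dplyr::summarise(r = mean(missing), .by = night_index) |>
    dplyr::arrange(night_index)
  expect_true(all(diff(rate$r) > 0))
  # overall rate near the fitted model's implied ~30%
  expect_gt(mean(ds$missing), 0.25)
  expect_lt(mean(ds$missing), 0.35)
})

test_that("deleted nights never leave partial stage data", {
  for (m in c("MCAR", "MAR", "MNAR")) {
    ds <- generate_sleep_data(generator_config(n_participants = 40L,
                                               mechanism = m, seed = 5))
    stages <- as.matrix(tibble::as_tibble(ds)[c("deep_s", "light_s", "rem_s",
                                                "awake_s", "unmeasurable_s")])
    n_na <- rowSums(is.na(stages))
    expect_true(all(n_na %in% c(0, 5)))
  }
})

test_that("MNAR deletion is tilted toward the night's own sleep duration", {
  # with a large negative coefficient, short sleepers go missing; the
  # surviving observed nights should then be longer on average than under MAR
  base <- generator_config(n_participants = 400L, seed = 17)
  mnar <- generator_config(n_participants = 400L, mechanism = "MNAR",
                           mnar_coefficient = -2, seed = 17)
  t_mar <- mean(generate_sleep_data(base)$total_sleep_s, na.rm = TRUE)
  t_mnar <- mean(generate_sleep_data(mnar)$total_sleep_s, na.rm = TRUE)
  expect_gt(t_mnar, t_mar)
})

test_that("nightly totals respect the plausibility envelope", {
  ds <- generate_sleep_data(generator_config(n_participants = 200L,
                                             mechanism = "NONE", seed = 3))
  expect_true(all(ds$total_sleep_s >= 3600 & ds$total_sleep_s <= 45000))
})

test_that("complete-case deletion wipes whole participants independently", {
  cfg <- generator_config(n_participants = 200L, mechanism = "MCAR",
                          mcar_prob = 0, complete_case_prob = 0.15, seed = 8)
  ds <- generate_sleep_data(cfg)
  per <- tibble::as_tibble(ds) |>
    dplyr::summarise(m = sum(missing), .by = participant_id)
  expect_true(all(per$m %in% c(0, 5)))
  expect_gt(sum(per$m == 5), 0)
})

test_that("generated data CSV sidecar records the generating config", {
  ds <- generate_sleep_data(generator_config(n_participants = 10L, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_generated(ds, path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$mechanism, "MAR")
  expect_equal(side$seed, 4)
})
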